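# monosmrna

Small RNA transcriptome analysis of LPS-stimulated human monocytes, built
as a tested R package plus a numbered analysis workflow. It addresses a
question from innate immunity: which microRNAs do primary human monocytes
induce during acute LPS stimulation, and which stable tRNA-derived
fragments (tRFs) do they carry? The package is aimed at computational
biologists who want a transparent, fully reproducible re-implementation of
the analysis chain — from raw small RNA reads to signature miRNAs and
conserved tRFs — running entirely on synthetic data with known truth.

## What it computes

* **Read QC**: 3' adaptor stripping (TruSeq small RNA chemistry), mean
  Phred ≥ 30 filtering, insert length ≥ 13 nt, collapsing to unique
  sequences with counts. Read accounting is exact:
  `input = no_adaptor + low_quality + too_short + retained`.
* **Annotation and CPM**: exact sense-strand matching against a
  hierarchical reference (miRNA hairpins, tRNA loci ± 30-nt flanks,
  snoRNA/rRNA/Y-RNA); uniquely assigned sequences are normalized as
  `CPM = count × 10⁶ / mapped total`.
* **tRF screen**: at each tRNA locus, a fragment is accepted when its
  length ∈ [18, 30] nt, its mean abundance ≥ 500 CPM and
  `dominance = CPM / CPM₂ ≥ 100` against the second-highest sequence at
  that locus; accepted fragments are classified as 5'-end, 3'-end,
  middle, or 3'-trailer and merged across identical multi-copy loci.
* **Donor-paired DE**: per-donor ratios `r_d = log2((LPS_d + 1)/(med_d + 1))`
  on CPM, a two-tailed Student paired t-test of `mean(r_d)` against 0,
  and Benjamini–Hochberg q-values.
* **Evidence integration**: ΔΔCt relative quantification
  (`2^−ΔΔCt` against U6 and a calibrator), the signature rule (a mature
  miRNA is a signature when ≥ 2 independent methods support upregulation
  at *both* 6 h and 24 h), miRNA→target joins and absolute expression
  trajectories.
* **Synthetic data**: a generator for references embedding the 18
  conserved tRFs across their 50 tRNA loci, adaptored FASTQ libraries at
  chosen CPM targets with a sub-5-CPM degradation background, and
  donor-paired negative-binomial count matrices
  (`var = μ + 0.05 μ²`, 7 donors) spiked from the packaged DE tables.

## Worked example

```r
library(monosmrna)

study <- simulate_small_rna_study(n_samples = 2, total_reads = 3e5, seed = 101)
res <- run_small_rna_pipeline(study$fastq, study$samples, study$reference)
res$summary
#> $n_trfs
#> [1] 18
#> $n_loci
#> [1] 50
#> $n_types
#> [1] 16
#> $n_amino_acids
#> [1] 12
#> $positions
#>       5p       3p        M trailer3
#>        7        8        1        2

signature_mirnas(evidence_table3())
#> [1] "mir-146a" "mir-147b" "mir-155"  "mir-193a" "mir-9"
```

The screen returns exactly the 18 embedded conserved fragments, drawn
from 50 tRNA loci covering 12 amino acids, with 7 at the 5' end, 8 at the
3' end, 1 internal and 2 in the 3' trailer; the evidence grid yields the
five signature miRNAs validated by at least two methods at both
timepoints.

The numbered scripts under `analysis/` run the same workflow at study
scale (4 × 10⁶ reads) step by step — simulation, read QC, annotation,
tRF screen, paired DE recovery, evidence integration — writing their
tables under `results/`.

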