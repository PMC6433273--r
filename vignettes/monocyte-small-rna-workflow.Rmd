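---
title: "Methods: small RNA analysis of LPS-stimulated monocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA analysis of LPS-stimulated monocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monosmrna)
```

## Scope and model

`monosmrna` re-implements, as a tested pipeline over synthetic data, a
small RNA-seq analysis of primary human monocytes stimulated with LPS in a
donor-paired design: each donor contributes one LPS-treated and one
medium-only sample at 6 and/or 24 hours, so treatment effects are tested
within donors. The pipeline has five computational stages:

1. **Read QC** — 3' adaptor stripping (reads without the adaptor are
   discarded), base-quality filtering, length filtering, and collapsing to
   unique insert sequences with per-sample counts.
2. **Annotation** — exact, sense-strand, ungapped matching of each unique
   sequence against a hierarchical small-RNA reference (miRNA hairpins,
   tRNA gene loci padded with 30-nt genomic flanks, snoRNA, rRNA, Y RNA);
   only uniquely assigned sequences are retained and abundances are
   normalized to counts per million (CPM) over each sample's mapped total.
3. **tRF screen** — per-locus profiling of tRNA-mapped sequences and a
   conservation screen (length window, CPM floor, dominance ratio), with
   positional classification into 5' end, 3' end, middle, and 3' trailer
   fragments.
4. **Paired differential expression** — per-feature two-tailed Student
   paired t-test on per-donor log2 CPM ratios with Benjamini–Hochberg
   correction.
5. **Evidence integration** — the signature rule over a tri-state
   NGS/qPCR/RT-PCR evidence grid, delta-delta-Ct quantification, target
   joins and absolute expression trajectories.

Because no raw sequencing data are distributed, a first-class synthetic
module generates every input with the statistical structure the analysis
assumes; the packaged tables of conserved tRFs, differentially expressed
miRNAs and multi-method evidence are transcribed fixtures.

## The synthetic-data generator

### Reference sets

`build_reference()` creates one tRNA locus record per locus id in the
conserved-tRF table: a random mature body of 70–90 nt flanked by 30 random
nt on each side, with the fragment embedded at the coordinate its
positional code implies (5' fragments start at the body start; 3'
fragments end at the genomic body end; middle fragments sit at least
`tol + 1` nt clear of both termini; trailer fragments start at
`body_end + 1` inside the downstream flank). Mature bodies are synthetic
random sequences, not real tRNA genes: the screen depends only on
positional structure, so realism is limited to lengths, flanks and
placement. Records exclude the post-transcriptional 3' CCA, so 3'
placements are interpreted against the genomic body end. Decoy records
(miRNA hairpins, extra tRNA loci, snoRNA, rRNA, Y RNA) are rejection
sampled so that no conserved fragment occurs outside its designated loci,
and each embedded fragment occurs exactly once in its locus. The build is
a pure function of `(fixture, flank, decoys, seed)`.

### Reads

`simulate_reads()` emits `insert + 3' adaptor` records truncated at the
instrument read length (default 50 nt), with Sanger Phred+33 qualities
(constant Q40 by default, a per-position profile optional). The adaptor
defaults to the Illumina TruSeq small RNA 3' adaptor because that is the
library chemistry being emulated. Foreground inserts are allocated by a
single multinomial draw at their target CPM, so a 600-CPM sequence appears
~600 times per million reads with Poisson-scale fluctuation; the library
must be fully allocated (foreground CPM plus background fraction equal to
one million CPM), and infeasible specifications fail before any record is
emitted. Background degradation inserts are random 14–30-nt subfragments
of tRNA locus records with per-distinct-sequence counts capped below
5 CPM — the screen's dominance denominator is therefore bounded by
construction. This cap dictates the minimum useful library depth: below
~3e5 reads a single read already exceeds 5 CPM, so reduced-scale runs in
the tests use 3e5 reads per library and the study-scale runs use 1e6.
Sequencing error, PCR duplication and ligation bias are deliberately not
modelled; QC rejection paths are exercised by handcrafted reads in the
tests instead.

### Paired counts

`simulate_paired_counts()` draws negative-binomial counts with
`variance = mu + dispersion * mu^2` (`size = 1/dispersion`; zero or
negative dispersion degrades to Poisson), one LPS and one medium sample
per donor, with a log-normal per-donor multiplicative effect (default
`donor_sd = 0.5`, reflecting the strong donor-to-donor baseline
variability seen in monocytes) shared by both conditions of a donor.
Spiked features take their baseline mean and log2 fold change from the
packaged DE tables; null features draw log-normal baselines
(`meanlog = log(200)`, `sdlog = 1.5`, a five-orders-of-magnitude
abundance span). Counts are generated directly on the normalized
(CPM-like) scale of the printed tables; the paired analysis is invariant
to per-sample rescaling, so this choice only fixes the pseudocount's
relative weight.

## Numerical and design choices

* **Quality rule** — "Phred < 30" is read as *mean* base quality of the
  raw read below 30, inclusive at exactly 30; a per-base *minimum* mode is
  switchable (`quality_pass(method = "min")`). Mean is the least
  aggressive common reading. Reads containing `N` fail QC so downstream
  exact matching is unambiguous.
* **Stage order** — fixed as strip → quality → length; the quality stage
  uses the raw read's qualities.
* **Adaptor matching** — exact, leftmost full occurrence, or the longest
  terminal adaptor prefix of at least 6 nt. Zero mismatches keeps
  trimming deterministic and testable.
* **Unique mapping** — a sequence is retained when all of its exact hits
  fall in one reference category; hits across multiple records of that
  category (identical tRF context repeated across multi-copy tRNA loci)
  count as a single reference sequence keyed by the matched subsequence.
  Defining uniqueness at locus level instead would discard every
  multi-copy tRF and contradict the screen's own output. Cross-category
  hits are discarded; antisense matching is off (stranded libraries).
* **CPM denominator** — each sample's total retained mapped count across
  all categories, overridable via `totals`.
* **tRF screen** — defaults `min_cpm = 500` (mean CPM across samples),
  `min_dominance = 100`, length window **18–30 nt**. The window is two
  nucleotides wider at the short end than the nominal 20–30 because one
  known trailer fragment is 19 nt as printed and tRNA-derived inserts
  concentrate near 18 nt; the nominal window would reject a genuine
  fragment. A locus with no second sequence has infinite dominance and
  passes; two distinct sequences tied at the top give dominance 1 and
  both fail (conservative). The CPM floor applies to the mean across
  samples rather than per sample — with four samples this is the stabler
  reading and is configurable.
* **Positional classification** — tolerance `tol = 3` nt at each body
  terminus, with precedence trailer > 5' > 3' > middle; the tolerance is
  chosen so that canonical placements (start at body start, end at body
  end, interior with margin, start just past the body end) classify as
  named. Merged records whose loci disagree on class are flagged, never
  silently collapsed.
* **Paired DE** — pseudocount 1 on CPM before the log ratio; features
  with zero counts everywhere are dropped (the BH family shrinks
  accordingly); degenerate all-equal ratio rows return p = 1; BH q
  threshold defaults to `alpha = 0.05` (the printed analysis quotes both
  an adjusted-p threshold and a separate FDR figure; a single BH run
  cannot satisfy both, so the adjusted-p reading is the default and both
  are parameters).
* **Signature rule** — tri-state evidence (`not_tested`/`not_detected`
  distinct from `no`, never counted either way); at 6 h the independent
  methods are NGS, qPCR and the RT-PCR *mature* band (the precursor band
  is switchable via `count_precursor` and off by default — the default
  reproduces the printed validation column); at 24 h, NGS and qPCR.
  Evidence is pooled within a mature-miRNA group (mir-9-1/mir-9-2 →
  mir-9) because mature-level assays cannot distinguish the loci.
* **Trajectories** — the ±10% "flat" band on mean LPS CPM between
  timepoints is this package's own convention; the underlying direction
  calls are qualitative.

## What the simulations do and do not establish

The synthetic study embeds known truth, so passing tests establish that
the pipeline's logic is correct and self-consistent: reads are conserved
exactly across QC stages, the aligner agrees with a naive substring scan,
the screen recovers exactly the 18 embedded fragments with the expected
positional histogram (7/8/1/2), monotonicity and label-swap symmetries
hold, null p-values are calibrated, and the empirical FDR stays near its
level. They do not establish robustness to sequencing error, isomiR
heterogeneity, adaptor variants, mapping ambiguity against a real
genome-scale reference, or non-NB count noise — none of which the
generator emulates.

One power limitation is worth stating plainly. With 7 donors, NB
dispersion 0.05 and a per-feature paired t-test (6 degrees of freedom),
the per-donor log2-ratio noise is about
`sqrt(2 * (1/mu + 0.05)) / ln 2 ≈ 0.46` for abundant features, so spikes
with printed |log2FC| below about 1.3 sit near the BH significance
boundary when tested among 800 null features, and simulation recall of
the printed DE tables is typically 10–14 of 15 (6 h) and 11–13 of 13
(24 h) rather than complete. Complete recall of the weakest fold changes
at this sample size requires information pooling across features
(moderated variances or a shared NB dispersion), which this package
intentionally leaves out of scope; when all spiked features are tested
without the null background (a 15-feature family), recall is complete.

## Problem sizes

The packaged analyses use 4 libraries × 1e6 reads for the study-scale
screen (the acceptance script and one acceptance test), 2 × 3e5 reads for
the reduced end-to-end test, 800 null features × 7 donors × 2 conditions
for DE recovery, and 2000 null features for calibration checks. All
randomness flows from explicit integer seeds; two runs with the same seed
produce byte-identical FASTQ.
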