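#!/usr/bin/env Rscript

# Step 1: generate the study's inputs.
#
# Builds the synthetic small-RNA reference (50 tRNA loci embedding the 18
# conserved tRFs, plus miRNA-hairpin/snoRNA/rRNA/Y-RNA decoys) and
# simulates four 1e6-read adaptored FASTQ libraries: each tRF at
# 600-5000 CPM, a 5% degradation background below 5 CPM per distinct
# fragment, and the dominant remainder of each library drawn from mature
# miRNA arms. FASTQ files are large and go to scratch/; the reference and
# sample sheet go to results/.

suppressMessages(library(monosmrna))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/analysis", showWarnings = FALSE, recursive = TRUE)

study <- simulate_small_rna_study(n_samples = 4L, total_reads = 1e6,
                                  seed = 20260929L %% 100000L,
                                  dir = "scratch/analysis")

write_reference_fasta(study$reference, "results/reference.fa")
readr::write_tsv(study$samples, "results/samples.tsv")
readr::write_tsv(
  tibble::tibble(sample = rep(names(study$fastq),
                              vapply(study$foreground, nrow, 0L)),
                 dplyr::bind_rows(study$foreground)),
  "results/true_foreground_counts.tsv")

cat("Simulated", length(study$fastq), "libraries of 1e6 reads each under",
    "scratch/analysis/\n")
cat("Reference:", nrow(study$reference), "records (",
    sum(study$reference$category == "tRNA_locus"), "tRNA loci )\n")
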