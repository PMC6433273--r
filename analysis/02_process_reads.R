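#!/usr/bin/env Rscript

# Step 2: read QC.
#
# Strips the TruSeq small RNA 3' adaptor, drops reads without it, filters
# on mean base quality (Phred >= 30) and insert length (>= 13 nt), and
# collapses each library to unique sequences with counts. The QC report
# accounts for every input read exactly once.

suppressMessages(library(monosmrna))

samples <- readr::read_tsv("results/samples.tsv", show_col_types = FALSE)
fastq <- setNames(file.path("scratch/analysis",
                            paste0(samples$sample, ".fastq")),
                  samples$sample)
stopifnot(file.exists(fastq))

qc <- list()
for (s in samples$sample) {
  out <- process_fastq(fastq[[s]])
  write_collapsed(out$collapsed,
                  file.path("scratch/analysis", paste0(s, "_collapsed.tsv")))
  qc[[s]] <- tibble::tibble(sample = s, stage = names(out$qc),
                            reads = unname(out$qc))
}
qc <- dplyr::bind_rows(qc)
readr::write_tsv(qc, "results/qc_report.tsv")
jsonlite::write_json(split(setNames(qc$reads, qc$stage), qc$sample),
                     "results/qc_report.json", auto_unbox = FALSE)

wide <- tidyr::pivot_wider(qc, names_from = "stage", values_from = "reads")
print.data.frame(wide)
cat("\nRetained fraction:",
    sprintf("%.1f%%", 100 * mean(wide$retained / wide$input)), "\n")
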