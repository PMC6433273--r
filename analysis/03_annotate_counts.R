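#!/usr/bin/env Rscript

# Step 3: annotation and normalization.
#
# Aligns every collapsed unique sequence exactly (sense strand, ungapped)
# against the hierarchical reference, keeps sequences mapping to a single
# category (multi-copy tRNA hits count as one reference sequence), builds
# per-category count matrices, normalizes to CPM over each sample's mapped
# total, and reports the per-category read fractions and the share of the
# miRNA population held by the most abundant miRNAs.

suppressMessages(library(monosmrna))

samples <- readr::read_tsv("results/samples.tsv", show_col_types = FALSE)
reference <- read_reference_fasta("results/reference.fa")
collapsed <- lapply(setNames(samples$sample, samples$sample), function(s) {
  readr::read_tsv(file.path("scratch/analysis", paste0(s, "_collapsed.tsv")),
                  show_col_types = FALSE)
})

queries <- unique(unlist(lapply(collapsed, `[[`, "sequence")))
hits <- align_exact(queries, reference)
assignments <- assign_reads(hits, queries)
counts <- build_counts(collapsed, assignments, samples)
cpm <- to_cpm(counts)

readr::write_tsv(counts$fractions, "results/category_fractions.tsv")
saveRDS(list(hits = hits, assignments = assignments, counts = counts,
             cpm = cpm), "scratch/analysis/annotation.rds")

mir_cpm <- category_matrix(cpm, "miRNA_hairpin")
cat("Unique sequences:", length(queries), "| retained:",
    sum(assignments$status == "retained"), "| multimapped:",
    sum(assignments$status == "multimapped"), "| unmapped:",
    sum(assignments$status == "unmapped"), "\n")
fr <- counts$fractions
cat("miRNA share of mapped reads per sample:",
    paste(sprintf("%.1f%%", 100 * fr$fraction[fr$category == "miRNA_hairpin"]),
          collapse = ", "), "\n")
cat("Top-10 miRNAs hold",
    sprintf("%.1f%%", 100 * top_n_share(mir_cpm, 10)),
    "of the miRNA population (", nrow(mir_cpm), "miRNA features )\n")
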