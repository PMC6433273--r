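#!/usr/bin/env Rscript

# Step 4: tRF discovery screen.
#
# Profiles every tRNA locus with the distinct sequences mapping to it and
# accepts candidates that are 18-30 nt, reach 500 CPM (mean across
# samples) and dominate the locus at least 100-fold over the next
# sequence; accepted fragments are classified by position (5' end,
# 3' end, middle, 3' trailer) and merged across identical multi-copy loci.

suppressMessages(library(monosmrna))

ann <- readRDS("scratch/analysis/annotation.rds")
reference <- read_reference_fasta("results/reference.fa")

profiles <- build_profiles(ann$hits, ann$assignments, ann$cpm)
accepted <- screen_trfs(profiles, min_len = 18, max_len = 30,
                        min_cpm = 500, min_dominance = 100)
trfs <- merge_trfs(accepted, reference)
write_trfs(trfs, accepted, tsv_path = "results/trf_records.tsv",
           bed_path = "results/trf_records.bed")

s <- summarize_trfs(trfs)
cat("Accepted conserved tRFs:", s$n_trfs, "over", s$n_loci, "tRNA loci (",
    s$n_types, "isoacceptor types,", s$n_amino_acids, "amino acids )\n")
cat("Positional classes:",
    paste(names(s$positions), s$positions, sep = "=", collapse = " "), "\n")

# cross-check against the packaged conserved-fragment table
fix <- fixture_trfs()
cat("Sequences matching the packaged table:",
    length(intersect(trfs$sequence, fix$sequence)), "of", nrow(fix), "\n")
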