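#!/usr/bin/env Rscript

# Step 5: donor-paired differential expression recovery.
#
# Simulates the donor-paired design (7 donors, one LPS and one medium
# sample each) at both timepoints, spiking every miRNA from the printed
# 6 h and 24 h DE tables at its printed medium-condition mean and log2
# fold change among 800 null features (NB dispersion 0.05), then runs the
# paired t-test / BH pipeline and reports how many spiked miRNAs are
# recalled at q < 0.05.

suppressMessages(library(monosmrna))
dir.create("results", showWarnings = FALSE)

seed0 <- 20260929L %% 100000L
for (tp in c(6, 24)) {
  sp <- spike_specs(tp)
  cm <- simulate_paired_counts(sp, n_null = 800L, n_donors = 7L,
                               dispersion = 0.05, timepoint = tp,
                               seed = seed0 + tp)
  de <- run_paired_de(cm, alpha = 0.05)
  readr::write_tsv(de, sprintf("results/de_%dh.tsv", tp))
  calls <- call_de(de)
  called <- c(calls$up, calls$down)
  recovered <- intersect(called, sp$feature_id)
  fp <- setdiff(called, sp$feature_id)
  cat(sprintf("%2d h: %d of %d spiked miRNAs recalled at BH q<0.05 (%d up, %d down); %d false positive(s)\n",
              tp, length(recovered), nrow(sp),
              sum(recovered %in% calls$up), sum(recovered %in% calls$down),
              length(fp)))
  missed <- setdiff(sp$feature_id, recovered)
  if (length(missed)) {
    cat("     not recalled (modest printed fold changes):",
        paste(missed, collapse = ", "), "\n")
  }
}
cat("\nNote: recall of the weakest printed fold changes (|log2FC| ~< 1.3)\n",
    "is power-limited under a per-feature paired t-test with 7 donors and\n",
    "dispersion 0.05; see the methods vignette.\n")
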