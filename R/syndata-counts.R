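# Donor-paired negative-binomial count simulation.
#
# NB parameterization: variance = mu + dispersion * mu^2 (size =
# 1/dispersion), the convention of mainstream RNA-seq DE tools. Counts are
# drawn on a normalized (CPM-like) expression scale so spiked baseline
# means taken from printed normalized-expression tables keep their scale;
# the paired analysis is invariant to a global rescaling anyway.

#' Simulate a donor-paired count matrix with spiked treatment effects
#'
#' Generates `2 * n_donors` samples (one LPS and one medium per donor). A
#' per-donor multiplicative random effect is shared by both conditions of a
#' donor (donor-to-donor baseline variability); null features have log2
#' fold change zero; spiked features use their specified baseline mean and
#' fold change. Swapping the two conditions of every donor negates every
#' true fold change.
#'
#' @param spikes Optional tibble (`feature_id`, `baseline_mean`, `log2fc`),
#'   e.g. from [spike_specs()].
#' @param n_null Number of additional null features.
#' @param n_donors Number of donors (>= 2; the study layout is 7).
#' @param dispersion NB dispersion; zero or negative is handled as Poisson.
#' @param donor_sd Standard deviation of the donor log-normal effect.
#' @param null_meanlog,null_sdlog Log-normal parameters for null baseline
#'   means.
#' @param timepoint Timepoint label for the metadata (hours).
#' @param seed Integer seed.
#' @return A `count_matrix` (unit `"normalized"`) with a `truth` attribute:
#'   tibble of `feature`, `log2fc`, `spiked`.
#' @export
simulate_paired_counts <- function(spikes = NULL, n_null = 800L,
                                   n_donors = 7L, dispersion = 0.05,
                                   donor_sd = 0.5,
                                   null_meanlog = log(200),
                                   null_sdlog = 1.5,
                                   timepoint = 6, seed = NULL) {
  if (n_donors < 2L) stop("need at least 2 donors", call. = FALSE)
  if (!is.null(spikes)) {
    spikes <- tibble::as_tibble(spikes)
    if (any(spikes$baseline_mean <= 0)) {
      stop("negative or zero baseline means", call. = FALSE)
    }
  }
  run <- function() {
    mu0 <- c(spikes$baseline_mean,
             exp(rnorm(n_null, null_meanlog, null_sdlog)))
    lfc <- c(spikes$log2fc, rep(0, n_null))
    features <- c(spikes$feature_id, sprintf("null_%04d", seq_len(n_null)))
    donors <- sprintf("D%02d", seq_len(n_donors))
    d_eff <- exp(rnorm(n_donors, 0, donor_sd))
    draw <- function(mu) {
      if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else rpois(length(mu), mu)
    }
    cols <- list()
    samples <- list()
    for (j in seq_len(n_donors)) {
      for (trt in c("medium", "LPS")) {
        mu <- mu0 * d_eff[j] * if (trt == "LPS") 2^lfc else 1
        nm <- paste0(donors[j], "_", trt, "_", timepoint, "h")
        cols[[nm]] <- draw(mu)
        samples[[nm]] <- tibble::tibble(sample = nm, donor = donors[j],
                                        treatment = trt,
                                        timepoint = timepoint)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- features
    cm <- count_matrix(counts, dplyr::bind_rows(samples),
                       unit = "normalized")
    attr(cm, "truth") <- tibble::tibble(
      feature = features, log2fc = lfc,
      spiked = seq_along(features) <= length(spikes$feature_id %||% c()))
    cm
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
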