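# Donor-paired differential expression on normalized count matrices.
#
# The engine is a per-feature two-tailed Student paired t-test on per-donor
# log2 expression ratios (LPS vs medium), with Benjamini-Hochberg
# correction. This matches the paired design (~ donor + treatment) without
# re-implementing an NB GLM: shrunken fold changes and Wald statistics are
# deliberately out of scope, and the test is validated by simulation
# recovery instead.

#' Per-donor log2 fold changes from a paired count matrix
#'
#' @param x A `count_matrix` in CPM or normalized units.
#' @param timepoint Optional timepoint (hours) to subset to first. Every
#'   donor must contribute exactly one LPS and one medium sample at the
#'   analyzed timepoint.
#' @param pseudocount Added to both conditions before the log ratio
#'   (default 1).
#' @return A list with `ratios` (features x donors matrix of per-donor
#'   log2((LPS + pc) / (medium + pc))) and `log2fc` (row means).
#' @export
paired_log2fc <- function(x, timepoint = NULL, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  if (x$unit == "raw") {
    stop("normalize to CPM before paired analysis", call. = FALSE)
  }
  if (!is.null(timepoint)) x <- subset_timepoint(x, timepoint)
  s <- x$samples
  tab <- table(s$donor, s$treatment)
  bad <- rownames(tab)[tab[, "LPS"] != 1L | tab[, "medium"] != 1L]
  if (length(bad)) {
    stop("unpaired donors: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  donors <- sort(unique(s$donor))
  lps <- s$sample[s$treatment == "LPS"][match(donors,
                                              s$donor[s$treatment == "LPS"])]
  med <- s$sample[s$treatment == "medium"][match(donors,
                                                 s$donor[s$treatment == "medium"])]
  ratios <- log2((x$counts[, lps, drop = FALSE] + pseudocount) /
                   (x$counts[, med, drop = FALSE] + pseudocount))
  colnames(ratios) <- donors
  list(ratios = ratios, log2fc = rowMeans(ratios))
}

#' Two-tailed paired location test on per-donor log ratios
#'
#' One-sample Student t-test of the per-donor log2 ratios against zero, per
#' feature. Degenerate rows whose ratios are all equal return p = 1.
#'
#' @param ratios Features x donors matrix (or a single feature's vector) of
#'   per-donor log2 ratios; at least 3 donors.
#' @return Numeric vector of two-tailed p-values.
#' @export
paired_test <- function(ratios) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = 1L)
  if (ncol(ratios) < 3L) stop("paired test needs >= 3 donors", call. = FALSE)
  apply(ratios, 1L, function(r) {
    if (max(r) == min(r)) return(1)
    t.test(r)$p.value
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Validated wrapper over the step-up FDR procedure; output order matches
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Donor-paired differential expression
#'
#' Computes per-feature paired log2 fold changes, two-tailed paired t-test
#' p-values and BH q-values, and calls direction at level `alpha`. Features
#' with zero counts in every analyzed sample are dropped before testing.
#'
#' @inheritParams paired_log2fc
#' @param alpha BH q-value threshold for calling direction (default 0.05).
#' @return A tibble sorted by q: `feature`, `log2fc`, `p`, `q`, `direction`
#'   (`up` / `down` / `ns`).
#' @export
run_paired_de <- function(x, timepoint = NULL, alpha = 0.05,
                          pseudocount = 1) {
  if (!is.null(timepoint)) x <- subset_timepoint(x, timepoint)
  keep <- rowSums(x$counts) > 0
  x$counts <- x$counts[keep, , drop = FALSE]
  pr <- paired_log2fc(x, pseudocount = pseudocount)
  p <- paired_test(pr$ratios)
  q <- bh_adjust(p)
  res <- tibble::tibble(
    feature = rownames(pr$ratios) %||% as.character(seq_along(p)),
    log2fc = unname(pr$log2fc),
    p = unname(p),
    q = unname(q),
    direction = dplyr::case_when(
      q < alpha & unname(pr$log2fc) > 0 ~ "up",
      q < alpha & unname(pr$log2fc) < 0 ~ "down",
      TRUE ~ "ns"))
  dplyr::arrange(res, .data$q, .data$p)
}

#' Partition DE results into direction sets
#'
#' @param res Tibble from [run_paired_de()].
#' @param alpha BH q threshold.
#' @return A list of feature-id vectors: `up`, `down`, `ns`.
#' @export
call_de <- function(res, alpha = 0.05) {
  up <- res$feature[res$q < alpha & res$log2fc > 0]
  down <- res$feature[res$q < alpha & res$log2fc < 0]
  list(up = up, down = down,
       ns = setdiff(res$feature, c(up, down)))
}

#' Overlap between two feature sets
#'
#' @param a,b Character vectors of feature ids.
#' @return A list: `shared`, `union`, `n_shared`, `n_union`.
#' @export
de_overlap <- function(a, b) {
  shared <- intersect(a, b)
  u <- union(a, b)
  list(shared = shared, union = u,
       n_shared = length(shared), n_union = length(u))
}
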