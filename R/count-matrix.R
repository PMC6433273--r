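# Light container for features x samples count/CPM matrices with the
# donor-paired sample metadata the differential-expression step needs.

#' Construct a count matrix with sample metadata
#'
#' @param counts Numeric matrix, features in rows, samples in columns.
#'   Column names must match `samples$sample`.
#' @param samples Data frame with columns `sample`, `donor`, `treatment`
#'   (`"LPS"` or `"medium"`) and `timepoint` (hours).
#' @param unit `"raw"` for read counts, `"cpm"` for counts per million, or
#'   `"normalized"` for values already on a normalized expression scale
#'   (e.g. simulated at CPM scale).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, unit = c("raw", "cpm", "normalized")) {
  unit <- match.arg(unit)
  counts <- as.matrix(counts)
  samples <- tibble::as_tibble(samples)
  need <- c("sample", "donor", "treatment", "timepoint")
  if (!all(need %in% names(samples))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(samples[need])) {
    stop("sample metadata incomplete (NA entries)", call. = FALSE)
  }
  if (!all(samples$treatment %in% c("LPS", "medium"))) {
    stop("treatment must be 'LPS' or 'medium'", call. = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  missing <- setdiff(colnames(counts), samples$sample)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (any(counts < 0)) stop("negative entries in count matrix", call. = FALSE)
  structure(list(counts = counts, samples = samples, unit = unit),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples [", x$unit, "]\n", sep = "")
  cat("  donors: ", length(unique(x$samples$donor)),
      "; timepoints: ", paste(sort(unique(x$samples$timepoint)), collapse = ", "),
      " h\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to one timepoint
#' @param x A `count_matrix`.
#' @param timepoint Timepoint (hours) to keep.
#' @return A `count_matrix` restricted to the matching samples.
#' @export
subset_timepoint <- function(x, timepoint) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$samples$timepoint == timepoint
  if (!any(keep)) stop("no samples at timepoint ", timepoint, call. = FALSE)
  count_matrix(x$counts[, x$samples$sample[keep], drop = FALSE],
               x$samples[keep, ], unit = x$unit)
}

#' Convert raw counts to counts per million (CPM)
#'
#' Divides each column by its library total and scales to one million. For
#' annotated pipeline objects the denominator is the sample's total retained
#' mapped count across all RNA categories; a different denominator can be
#' supplied through `totals`.
#'
#' @param x A `count_matrix` (unit `"raw"`), a bare matrix, or an
#'   `smrna_counts` object from [build_counts()].
#' @param totals Optional named per-sample totals to use as denominators.
#' @return Same shape as the input with entries scaled to CPM.
#' @export
to_cpm <- function(x, totals = NULL) UseMethod("to_cpm")

#' @export
to_cpm.matrix <- function(x, totals = NULL) {
  totals <- totals %||% colSums(x)
  if (!is.null(names(totals)) && !is.null(colnames(x))) {
    totals <- totals[colnames(x)]
  }
  zero <- totals <= 0 | is.na(totals)
  if (any(zero)) {
    bad <- colnames(x)[zero] %||% which(zero)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(x, 2L, totals, "/") * 1e6
}

#' @export
to_cpm.count_matrix <- function(x, totals = NULL) {
  if (x$unit != "raw") stop("input already normalized (unit: ", x$unit, ")",
                            call. = FALSE)
  out <- x
  out$counts <- to_cpm(x$counts, totals)
  out$unit <- "cpm"
  out
}

#' Share of total abundance captured by the top-n features
#'
#' Ranks features by mean CPM across samples and reports the fraction of the
#' summed abundance contributed by the `n` most abundant features (e.g. the
#' share of the miRNA population held by the top 100 miRNAs).
#'
#' @param cpm A CPM matrix (features x samples) or a `count_matrix` in CPM.
#' @param n Number of top features (default 100).
#' @return A single fraction in (0, 1]. If `n` exceeds the feature count the
#'   full set is used and a warning is raised.
#' @export
top_n_share <- function(cpm, n = 100) {
  if (inherits(cpm, "count_matrix")) cpm <- cpm$counts
  cpm <- as.matrix(cpm)
  if (nrow(cpm) == 0L) stop("empty matrix", call. = FALSE)
  if (n > nrow(cpm)) {
    warning("n exceeds feature count; using all ", nrow(cpm), " features")
    n <- nrow(cpm)
  }
  mu <- rowMeans(cpm)
  sum(sort(mu, decreasing = TRUE)[seq_len(n)]) / sum(mu)
}

#' Write / read a count matrix as TSV
#'
#' The counts table has the feature id in the first column and one column
#' per sample; metadata is a separate four-column TSV.
#'
#' @param x A `count_matrix`.
#' @param counts_path,samples_path Output (or input) TSV paths.
#' @return `write_count_matrix()` returns `x` invisibly;
#'   `read_count_matrix()` returns a `count_matrix`.
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- tibble::as_tibble(x$counts, rownames = "feature")
  readr::write_tsv(tab, counts_path)
  readr::write_tsv(x$samples, samples_path)
  invisible(x)
}

#' @rdname write_count_matrix
#' @param unit Unit flag of the values on disk.
#' @export
read_count_matrix <- function(counts_path, samples_path,
                              unit = c("raw", "cpm", "normalized")) {
  tab <- readr::read_tsv(counts_path, col_types = readr::cols(
    feature = "c", .default = "d"), progress = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$feature
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(
    sample = "c", donor = "c", treatment = "c", timepoint = "d"),
    progress = FALSE)
  count_matrix(counts, samples, unit = match.arg(unit))
}
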