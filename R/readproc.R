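# Raw FASTQ -> per-sample collapsed unique-sequence count tables.
#
# Stage order is strip -> quality -> length; quality uses the raw read's
# base qualities (mean by default, minimum switchable), inclusive at the
# threshold. Adaptor matching is exact (zero mismatches): inserts are short
# and error-filtered, and exactness keeps the downstream unique-mapping
# rule well defined.

#' Strip the 3' adaptor from read sequences
#'
#' Returns the subsequence before the leftmost adaptor occurrence: either a
#' full match anywhere in the read, or a prefix of the adaptor of length
#' `>= min_overlap` terminating at the read's 3' end. Reads without any such
#' occurrence are rejected (`NA`).
#'
#' @param seqs Character vector of read sequences.
#' @param adaptor Adaptor sequence (non-empty).
#' @param min_overlap Minimum terminal adaptor-prefix length (default 6).
#' @return Character vector of inserts, `NA` where the adaptor was absent.
#' @export
strip_adaptor <- function(seqs, adaptor = truseq_small_rna_adapter,
                          min_overlap = 6L) {
  if (!nzchar(adaptor)) stop("adaptor must be non-empty", call. = FALSE)
  seqs <- toupper(seqs)
  adaptor <- toupper(adaptor)
  out <- rep(NA_character_, length(seqs))
  pos <- stringi::stri_locate_first_fixed(seqs, adaptor)[, 1L]
  hit <- !is.na(pos)
  out[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  # no full match: longest adaptor prefix ending exactly at the 3' end
  rest <- which(!hit)
  if (length(rest)) {
    n <- nchar(seqs[rest])
    found <- rep(NA_integer_, length(rest))
    k_hi <- min(nchar(adaptor) - 1L, max(n))
    for (k in if (k_hi >= min_overlap) seq(k_hi, min_overlap) else integer()) {
      idx <- which(is.na(found) & n >= k)
      if (!length(idx)) next
      pref <- substr(adaptor, 1L, k)
      ok <- endsWith(seqs[rest][idx], pref)
      found[idx[ok]] <- k
    }
    done <- !is.na(found)
    out[rest[done]] <- substr(seqs[rest][done], 1L,
                              n[done] - found[done])
  }
  out
}

# Per-read mean Phred score, computed in one pass over the concatenated
# quality strings (Sanger +33 encoding).
mean_phred <- function(quals) {
  w <- nchar(quals)
  if (!length(w)) return(numeric())
  codes <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  ends <- cumsum(w)
  csum <- c(0, cumsum(codes))
  (csum[ends + 1L] - csum[ends - w + 1L]) / w
}

min_phred <- function(quals) {
  purrr::map_dbl(quals, function(q) {
    if (!nzchar(q)) return(NA_real_)
    min(as.integer(charToRaw(q))) - 33
  })
}

#' Quality filter
#'
#' A read passes if its summary Phred score (mean by default; minimum
#' switchable) is at least `threshold`; the boundary is inclusive. Reads
#' with empty quality strings fail.
#'
#' @param quals Character vector of Phred+33 quality strings.
#' @param threshold Phred threshold (default 30).
#' @param method `"mean"` or `"min"` base-quality summary.
#' @return Logical vector.
#' @export
quality_pass <- function(quals, threshold = 30, method = c("mean", "min")) {
  method <- match.arg(method)
  score <- if (method == "mean") mean_phred(quals) else min_phred(quals)
  !is.na(score) & nchar(quals) > 0L & score >= threshold
}

#' Length filter
#'
#' @param seqs Character vector of insert sequences.
#' @param min_len Minimum retained insert length (default 13; inserts of
#'   12 nt or shorter are removed).
#' @return Logical vector.
#' @export
length_pass <- function(seqs, min_len = 13L) {
  !is.na(seqs) & nchar(seqs) >= min_len
}

#' Collapse inserts to unique sequences with counts
#'
#' @param inserts Character vector of QC-passed insert sequences.
#' @return A tibble with columns `sequence` and `count`, in lexicographic
#'   (C-locale) sequence order; counts sum to `length(inserts)`.
#' @export
collapse_reads <- function(inserts) {
  if (!length(inserts)) {
    return(tibble::tibble(sequence = character(), count = integer()))
  }
  tab <- dplyr::count(tibble::tibble(sequence = inserts), .data$sequence,
                      name = "count")
  tab[order(tab$sequence, method = "radix"), ]
}

#' Process a FASTQ file into a collapsed count table with a QC report
#'
#' Applies adaptor stripping, quality filtering (on the raw read), length
#' filtering and unique-sequence collapsing, in that order. Reads containing
#' non-ACGT characters fail the quality stage. The QC report accounts for
#' every input read exactly once.
#'
#' @param path FASTQ file (plain or gzip).
#' @param adaptor 3' adaptor sequence.
#' @param min_qual Phred threshold (default 30).
#' @param min_len Minimum insert length (default 13).
#' @param min_overlap Minimum terminal adaptor overlap (default 6).
#' @param qual_method `"mean"` or `"min"`.
#' @return A list with `collapsed` (tibble `sequence`, `count`) and `qc`
#'   (named integer vector: `input`, `no_adaptor`, `low_quality`,
#'   `too_short`, `retained`).
#' @export
process_fastq <- function(path, adaptor = truseq_small_rna_adapter,
                          min_qual = 30, min_len = 13L, min_overlap = 6L,
                          qual_method = c("mean", "min")) {
  qual_method <- match.arg(qual_method)
  parsed <- tryCatch({
    reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
    seqs <- as.character(reads)
    quals <- as.character(S4Vectors::mcols(reads)$qualities)
    if (length(quals) != length(seqs) || any(nchar(quals) != nchar(seqs))) {
      stop("sequence/quality length mismatch")
    }
    list(seqs = seqs, quals = quals)
  }, error = function(e) stop("malformed FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  seqs <- parsed$seqs
  quals <- parsed$quals

  inserts <- strip_adaptor(seqs, adaptor, min_overlap)
  has_adaptor <- !is.na(inserts)
  qc_ok <- has_adaptor &
    quality_pass(quals, min_qual, qual_method) &
    !stringi::stri_detect_regex(seqs, "[^ACGT]")
  len_ok <- qc_ok & length_pass(inserts, min_len)

  qc <- c(input = length(seqs),
          no_adaptor = sum(!has_adaptor),
          low_quality = sum(has_adaptor & !qc_ok),
          too_short = sum(qc_ok & !len_ok),
          retained = sum(len_ok))
  list(collapsed = collapse_reads(inserts[len_ok]), qc = qc)
}

#' Write a collapsed table as TSV (`sequence<TAB>count`)
#' @param collapsed Tibble from [collapse_reads()].
#' @param path Output path.
#' @export
write_collapsed <- function(collapsed, path) {
  readr::write_tsv(collapsed, path)
  invisible(path)
}
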