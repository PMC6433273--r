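# tRNA-derived fragment (tRF) discovery screen.
#
# Each tRNA locus is profiled with every distinct retained sequence that
# maps to it; a candidate is accepted when it is 18-30 nt, reaches 500 CPM
# (mean across samples) and is at least 100-fold more abundant than the
# second-highest distinct sequence at the same locus (the enrichment
# threshold against random degradation). The default length window is
# [18, 30] rather than the nominal 20-30: one known trailer fragment is
# 19 nt as printed and tRNA-derived inserts concentrate at 18 nt, so the
# stricter window would reject a genuine fragment.

#' Build per-locus sequence profiles
#'
#' @param hits Tibble from [align_exact()] (tRNA locus hits are selected).
#' @param assignments Tibble from [assign_reads()]; only sequences retained
#'   in the tRNA category are profiled.
#' @param cpm An `smrna_counts` object in CPM (or a sequences x samples CPM
#'   matrix with sequence rownames).
#' @return A tibble with one row per (locus, distinct sequence):
#'   `locus_id`, `sequence`, `offset` (1-based match start), `mean_cpm`.
#'   A sequence mapping to several loci appears in each locus profile with
#'   identical CPM.
#' @export
build_profiles <- function(hits, assignments, cpm) {
  mat <- if (inherits(cpm, "smrna_counts")) {
    stopifnot(cpm$unit == "cpm")
    cpm$counts
  } else as.matrix(cpm)
  keep <- assignments$sequence[assignments$status == "retained" &
                                 assignments$category == "tRNA_locus"]
  h <- hits[hits$category == "tRNA_locus" & hits$query %in% keep, ]
  h <- dplyr::slice_min(dplyr::group_by(h, .data$ref_id, .data$query),
                        .data$offset, n = 1L, with_ties = FALSE)
  h <- dplyr::ungroup(h)
  mean_cpm <- rowMeans(mat)[h$query]
  tibble::tibble(locus_id = h$ref_id, sequence = h$query,
                 offset = h$offset, mean_cpm = unname(mean_cpm))
}

#' Screen locus profiles for conserved tRF candidates
#'
#' @param profiles Tibble from [build_profiles()].
#' @param min_len,max_len Accepted fragment length window (default 18-30 nt).
#' @param min_cpm Minimum mean CPM across samples (default 500).
#' @param min_dominance Minimum ratio of the candidate's mean CPM to the
#'   second-highest distinct sequence at the same locus (default 100). With
#'   no second sequence the ratio is infinite and passes; two sequences tied
#'   at the top give dominance 1 and both fail.
#' @return Accepted candidates: `locus_id`, `sequence`, `offset`,
#'   `mean_cpm`, `second_cpm`, `dominance`.
#' @export
screen_trfs <- function(profiles, min_len = 18L, max_len = 30L,
                        min_cpm = 500, min_dominance = 100) {
  stopifnot(min_cpm > 0, min_dominance > 0)
  if (!nrow(profiles)) {
    return(tibble::tibble(locus_id = character(), sequence = character(),
                          offset = integer(), mean_cpm = numeric(),
                          second_cpm = numeric(), dominance = numeric()))
  }
  out <- profiles |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::mutate(
      second_cpm = purrr::map_dbl(seq_along(.data$mean_cpm), function(i) {
        others <- .data$mean_cpm[-i]
        if (length(others)) max(others) else 0
      }),
      dominance = ifelse(.data$second_cpm > 0,
                         .data$mean_cpm / .data$second_cpm, Inf)) |>
    dplyr::ungroup() |>
    dplyr::filter(nchar(.data$sequence) >= min_len,
                  nchar(.data$sequence) <= max_len,
                  .data$mean_cpm >= min_cpm,
                  .data$dominance >= min_dominance)
  dplyr::arrange(out, .data$locus_id, .data$sequence)
}

#' Classify a fragment's position within its tRNA locus
#'
#' Precedence: trailer (3' downstream) > 5' end > 3' end > middle. With
#' 1-based inclusive coordinates and tolerance `tol`: a fragment starting
#' after the mature body end is `trailer3`; one starting within `tol` of the
#' body start is `5p`; one ending within `tol` of the body end is `3p`;
#' anything else interior is `M`.
#'
#' @param offset 1-based match start(s) within the locus record.
#' @param width Fragment length(s).
#' @param body_start,body_end 1-based inclusive mature-body coordinates.
#' @param tol Positional tolerance in nt at each terminus (default 3).
#' @return Character vector over `c("5p", "3p", "M", "trailer3")`.
#' @export
classify_position <- function(offset, width, body_start, body_end, tol = 3L) {
  end <- offset + width - 1L
  if (any(offset < 1L | is.na(body_start))) {
    stop("match outside locus bounds or missing body coordinates",
         call. = FALSE)
  }
  dplyr::case_when(
    offset >= body_end + 1L ~ "trailer3",
    offset <= body_start + tol ~ "5p",
    end >= body_end - tol ~ "3p",
    TRUE ~ "M")
}

#' Merge accepted candidates into tRF records
#'
#' Identical sequences accepted at several loci are merged into one record
#' carrying the union of locus ids. Position classes must agree across loci;
#' disagreement is flagged (classes joined with `/`), never silently
#' collapsed.
#'
#' @param accepted Tibble from [screen_trfs()].
#' @param reference Reference tibble (for body coordinates).
#' @param tol Positional tolerance passed to [classify_position()].
#' @return A tibble of tRF records: `sequence`, `loci` (list), `n_loci`,
#'   `position`, `flagged`, `mean_cpm`, `dominance` (minimum across loci),
#'   `trna_type`, `amino_acid`.
#' @export
merge_trfs <- function(accepted, reference, tol = 3L) {
  if (!nrow(accepted)) {
    return(tibble::tibble(sequence = character(), loci = list(),
                          n_loci = integer(), position = character(),
                          flagged = logical(), mean_cpm = numeric(),
                          dominance = numeric(), trna_type = character(),
                          amino_acid = character()))
  }
  ref <- reference[match(accepted$locus_id, reference$id), ]
  accepted$position <- classify_position(accepted$offset,
                                         nchar(accepted$sequence),
                                         ref$body_start, ref$body_end,
                                         tol = tol)
  out <- accepted |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      loci = list(sort(unique(.data$locus_id))),
      n_loci = dplyr::n_distinct(.data$locus_id),
      flagged = dplyr::n_distinct(.data$position) > 1L,
      position = paste(sort(unique(.data$position)), collapse = "/"),
      mean_cpm = .data$mean_cpm[1L],
      dominance = min(.data$dominance),
      .groups = "drop")
  out$trna_type <- purrr::map_chr(out$loci, function(l) {
    types <- unique(sub("^tRNA[0-9]+-([A-Za-z]+)\\(.*$", "\\1", l))
    paste(types, collapse = "/")
  })
  out$amino_acid <- substr(out$trna_type, 1L, 3L)
  dplyr::arrange(out, .data$sequence)
}

#' Summarize a set of tRF records
#'
#' @param trfs Tibble of tRF records from [merge_trfs()] or
#'   [fixture_trfs()].
#' @return A list: `n_trfs`, `n_loci` (distinct locus ids), `n_types`
#'   (distinct tRNA type labels), `n_amino_acids`, and `positions`, a named
#'   count over `5p`, `3p`, `M`, `trailer3`.
#' @export
summarize_trfs <- function(trfs) {
  classes <- c("5p", "3p", "M", "trailer3")
  pos <- setNames(integer(length(classes)), classes)
  if (nrow(trfs)) {
    tab <- table(trfs$position)
    pos[names(tab)[names(tab) %in% classes]] <-
      as.integer(tab[names(tab) %in% classes])
  }
  list(n_trfs = nrow(trfs),
       n_loci = length(unique(unlist(trfs$loci))),
       n_types = length(unique(unlist(
         strsplit(trfs$trna_type, "/", fixed = TRUE)))),
       n_amino_acids = length(unique(substr(unlist(
         strsplit(trfs$trna_type, "/", fixed = TRUE)), 1L, 3L))),
       positions = pos)
}

#' tRF records directly from the packaged conserved-fragment table
#'
#' Maps positional codes (`5`, `3`, `M`, `3down`) to screen classes so the
#' printed table can flow through [summarize_trfs()] and be compared with
#' screen output.
#'
#' @param fixture Tibble from [trf_table4()].
#' @return A tibble shaped like [merge_trfs()] output, plus `trf_name` and
#'   `prior_id` (whether the name is a prior numeric identifier).
#' @export
fixture_trfs <- function(fixture = trf_table4()) {
  map <- c("5" = "5p", "3" = "3p", "M" = "M", "3down" = "trailer3")
  tibble::tibble(
    sequence = fixture$sequence,
    loci = fixture$loci,
    n_loci = lengths(fixture$loci),
    position = unname(map[fixture$position]),
    flagged = FALSE,
    mean_cpm = NA_real_,
    dominance = NA_real_,
    trna_type = fixture$trna_type,
    amino_acid = fixture$amino_acid,
    trf_name = fixture$trf_name,
    prior_id = grepl("^tRF-[0-9]+$", fixture$trf_name))
}

#' Write tRF records as TSV and BED
#'
#' The BED intervals are 0-based half-open in locus-record coordinates, one
#' line per (tRF, locus).
#'
#' @param trfs Records from [merge_trfs()].
#' @param accepted Accepted candidates from [screen_trfs()] (for offsets).
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @export
write_trfs <- function(trfs, accepted, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    flat <- trfs
    flat$loci <- purrr::map_chr(flat$loci, paste, collapse = ",")
    readr::write_tsv(flat, tsv_path)
  }
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(
      chrom = accepted$locus_id,
      start = accepted$offset - 1L,
      end = accepted$offset - 1L + nchar(accepted$sequence),
      name = accepted$sequence,
      score = round(accepted$mean_cpm),
      strand = "+")
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  invisible(trfs)
}
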