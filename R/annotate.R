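# Exact-match annotation of collapsed unique sequences against the
# hierarchical small-RNA reference, unique-assignment filtering, per-category
# count matrices and CPM normalization.
#
# The aligner is exact, sense-strand, ungapped, full-length substring
# matching: inserts are short and error-filtered, and exactness makes the
# unique-mapping rule well defined and testable. Antisense matching is off
# (TruSeq small RNA libraries are stranded).

#' Exact sense-strand alignment of queries to a reference set
#'
#' Finds every exact occurrence of each query as a substring of each
#' reference sequence.
#'
#' @param queries Character vector of query sequences (collapsed inserts).
#' @param reference Reference tibble (`id`, `category`, `sequence`, ...).
#' @return A tibble with one row per hit: `query`, `ref_id`, `category`,
#'   `offset` (1-based start of the match in the reference), ordered by
#'   query, then reference id, then offset.
#' @export
align_exact <- function(queries, reference) {
  queries <- toupper(unique(queries))
  hits <- purrr::map(seq_len(nrow(reference)), function(i) {
    loc <- stringi::stri_locate_all_fixed(reference$sequence[i], queries,
                                          overlap = TRUE)
    n <- purrr::map_int(loc, ~ sum(!is.na(.x[, 1L])))
    if (!sum(n)) return(NULL)
    tibble::tibble(
      query = rep.int(queries, n),
      ref_id = reference$id[i],
      category = reference$category[i],
      offset = as.integer(unlist(
        purrr::map(loc[n > 0L], ~ .x[!is.na(.x[, 1L]), 1L]))))
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    return(tibble::tibble(query = character(), ref_id = character(),
                          category = character(), offset = integer()))
  }
  dplyr::arrange(out, .data$query, .data$ref_id, .data$offset)
}

#' Resolve hits into unique assignments
#'
#' A sequence is retained when all of its hits fall in a single reference
#' category; hits to several reference records of that category (e.g. the
#' identical tRF context repeated across multi-copy tRNA loci) count as one
#' reference sequence, keyed by the matched subsequence, and all record ids
#' are kept. Cross-category hits are discarded as multi-mapped; sequences
#' without hits are unmapped.
#'
#' @param hits Tibble from [align_exact()].
#' @param queries All query sequences (to report unmapped ones).
#' @return A tibble with one row per query: `sequence`, `status`
#'   (`retained` / `multimapped` / `unmapped`), `category`, `feature_id`
#'   (single ref id, or sorted ids joined with `;`), `n_refs`, `ref_ids`
#'   (list-column).
#' @export
assign_reads <- function(hits, queries) {
  queries <- toupper(unique(queries))
  by_q <- dplyr::summarise(
    dplyr::group_by(hits, .data$query),
    n_cat = dplyr::n_distinct(.data$category),
    category = .data$category[1L],
    ref_ids = list(sort(unique(.data$ref_id))),
    .groups = "drop")
  out <- tibble::tibble(sequence = queries)
  out <- dplyr::left_join(out, by_q, by = c(sequence = "query"))
  out$status <- dplyr::case_when(
    is.na(out$n_cat) ~ "unmapped",
    out$n_cat > 1L ~ "multimapped",
    TRUE ~ "retained")
  out$category[out$status != "retained"] <- NA_character_
  out$ref_ids[out$status != "retained"] <- list(character())
  out$n_refs <- lengths(out$ref_ids)
  out$feature_id <- ifelse(
    out$status == "retained",
    purrr::map_chr(out$ref_ids, paste, collapse = ";"),
    NA_character_)
  out[, c("sequence", "status", "category", "feature_id", "n_refs",
          "ref_ids")]
}

#' Build per-category count matrices from collapsed samples
#'
#' Combines per-sample collapsed tables with the unique assignments into a
#' sequence-level count matrix (retained sequences only), per-category
#' feature-level matrices, and a per-sample category-fraction summary over
#' mapped (retained) reads.
#'
#' @param collapsed_list Named list (by sample id) of collapsed tibbles
#'   (`sequence`, `count`).
#' @param assignments Tibble from [assign_reads()].
#' @param samples Sample metadata (`sample`, `donor`, `treatment`,
#'   `timepoint`).
#' @return An `smrna_counts` object: list with `sequences` (row metadata:
#'   `sequence`, `category`, `feature_id`), `counts` (matrix sequences x
#'   samples), `samples`, `unit`, and `fractions` (per sample and category,
#'   share of mapped counts).
#' @export
build_counts <- function(collapsed_list, assignments, samples) {
  samples <- tibble::as_tibble(samples)
  missing <- setdiff(names(collapsed_list), samples$sample)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  retained <- assignments[assignments$status == "retained", ]
  counts <- matrix(0, nrow = nrow(retained), ncol = length(collapsed_list),
                   dimnames = list(retained$sequence, names(collapsed_list)))
  for (s in names(collapsed_list)) {
    tab <- collapsed_list[[s]]
    idx <- match(tab$sequence, retained$sequence)
    ok <- !is.na(idx)
    counts[idx[ok], s] <- tab$count[ok]
  }
  mapped <- colSums(counts)
  fractions <- tibble::as_tibble(counts) |>
    dplyr::mutate(category = retained$category) |>
    tidyr::pivot_longer(-"category", names_to = "sample",
                        values_to = "count") |>
    dplyr::group_by(.data$sample, .data$category) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  structure(list(
    sequences = retained[, c("sequence", "category", "feature_id")],
    counts = counts,
    samples = samples[match(names(collapsed_list), samples$sample), ],
    unit = "raw",
    mapped_totals = mapped,
    fractions = fractions),
    class = "smrna_counts")
}

#' @export
print.smrna_counts <- function(x, ...) {
  cat("<smrna_counts> ", nrow(x$counts), " retained sequences x ",
      ncol(x$counts), " samples [", x$unit, "]\n", sep = "")
  print(dplyr::count(x$sequences, .data$category))
  invisible(x)
}

#' @export
to_cpm.smrna_counts <- function(x, totals = NULL) {
  if (x$unit != "raw") stop("already normalized", call. = FALSE)
  out <- x
  out$counts <- to_cpm(x$counts, totals %||% x$mapped_totals)
  out$unit <- "cpm"
  out
}

#' Feature-level matrix for one reference category
#'
#' Aggregates the sequence-level matrix over `feature_id` within a category
#' (distinct sequences mapping to the same feature are summed).
#'
#' @param x An `smrna_counts` object.
#' @param category One of the reference categories.
#' @return A features x samples matrix on the same unit scale as `x`.
#' @export
category_matrix <- function(x, category) {
  stopifnot(inherits(x, "smrna_counts"))
  keep <- x$sequences$category == category
  if (!any(keep)) {
    return(matrix(0, 0L, ncol(x$counts),
                  dimnames = list(NULL, colnames(x$counts))))
  }
  rowsum(x$counts[keep, , drop = FALSE], x$sequences$feature_id[keep])
}
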