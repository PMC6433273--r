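# Multi-method evidence integration: the signature-miRNA decision rule,
# qPCR delta-delta-Ct quantification, miRNA-target joins and absolute
# expression trajectories.

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))`:
#' the target's abundance relative to a reference RNA (e.g. U6), normalized
#' to a calibrator sample.
#'
#' @param ct_target,ct_reference Ct values in the test sample.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return Relative quantity (vectorized).
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal) {
  stopifnot(all(is.finite(c(ct_target, ct_reference,
                            ct_target_cal, ct_reference_cal))))
  2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))
}

evidence_methods <- function(timepoint, count_precursor = FALSE) {
  if (as.character(timepoint) == "6") {
    c("ngs_6h", "qpcr_6h", "rtpcr_mature_6h",
      if (count_precursor) "rtpcr_precursor_6h")
  } else {
    c("ngs_24h", "qpcr_24h")
  }
}

#' Is a miRNA upregulated by at least two methods at a timepoint?
#'
#' Counts independent assay methods reporting "yes" at the timepoint: NGS
#' significance, qPCR upregulation, and (at 6 h) RT-PCR mature-band
#' upregulation. `not_tested` / `not_detected` entries contribute nothing
#' in either direction. Evidence is pooled within a mature-miRNA group
#' (loci sharing a mature product, e.g. mir-9-1/mir-9-2): mature-level
#' assays apply to the whole group and a method counts if any member locus
#' reports yes.
#'
#' @param evidence Evidence tibble from [evidence_table3()].
#' @param timepoint 6 or 24.
#' @param count_precursor Whether the RT-PCR precursor band counts as an
#'   additional method at 6 h (default `FALSE`; the default reproduces the
#'   printed validation column).
#' @return Logical vector aligned with the rows of `evidence` (each row
#'   carries its mature group's result).
#' @export
upregulated_at <- function(evidence, timepoint, count_precursor = FALSE) {
  cols <- evidence_methods(timepoint, count_precursor)
  yes <- sapply(cols, function(cl) evidence[[cl]] == "yes")
  if (is.null(dim(yes))) yes <- matrix(yes, nrow = 1L)
  group_yes <- rowsum(yes + 0, evidence$mature) > 0
  n_methods <- rowSums(group_yes)
  unname(n_methods[evidence$mature] >= 2L)
}

#' Signature miRNAs: validated at both timepoints
#'
#' Mature miRNA names whose locus group is upregulated by at least two
#' methods at both 6 h and 24 h.
#'
#' @inheritParams upregulated_at
#' @return Sorted character vector of mature miRNA names.
#' @export
signature_mirnas <- function(evidence, count_precursor = FALSE) {
  if (!nrow(evidence)) return(character())
  both <- upregulated_at(evidence, 6, count_precursor) &
    upregulated_at(evidence, 24, count_precursor)
  sort(unique(evidence$mature[both]))
}

#' Join differentially expressed genes with miRNA target links
#'
#' Inner join of DE calls (BH q < `alpha`) with a miRNA-to-target link
#' table; each gene appears once per timepoint with all of its regulating
#' miRNAs listed.
#'
#' @param de_results Named list of DE tibbles from [run_paired_de()], e.g.
#'   `list("6" = de6, "24" = de24)`.
#' @param links Link table from [target_links()].
#' @param alpha BH q threshold (default 0.05).
#' @return A tibble: `timepoint`, `gene`, `regulators` (comma-joined,
#'   sorted), `log2fc`, `direction`.
#' @export
join_targets <- function(de_results, links, alpha = 0.05) {
  if (!nrow(links)) {
    warning("empty link table: join is empty")
    return(tibble::tibble(timepoint = character(), gene = character(),
                          regulators = character(), log2fc = numeric(),
                          direction = character()))
  }
  empty <- tibble::tibble(timepoint = character(), gene = character(),
                          regulators = character(), log2fc = numeric(),
                          direction = character())
  purrr::imap(de_results, function(res, tp) {
    de <- res[res$q < alpha, ]
    hit <- dplyr::inner_join(links, de, by = c(gene = "feature"))
    if (!nrow(hit)) return(NULL)
    hit |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        regulators = paste(sort(unique(.data$mirna)), collapse = ","),
        log2fc = .data$log2fc[1L],
        direction = .data$direction[1L],
        .groups = "drop") |>
      dplyr::mutate(timepoint = tp, .before = 1L)
  }) |>
    dplyr::bind_rows() |>
    (\(x) if (nrow(x)) x else empty)()
}

#' Absolute expression trajectory between timepoints under LPS
#'
#' Classifies each gene's absolute trend from mean LPS CPM at 6 h to 24 h,
#' with a relative tolerance band for "flat" (default +/- 10 percent), and
#' carries the relative (LPS vs medium) DE directions when supplied.
#'
#' @param genes Genes to classify; must be present at both timepoints.
#' @param cpm6,cpm24 `count_matrix` objects in CPM (or normalized) units
#'   for the two timepoints.
#' @param de6,de24 Optional DE tibbles for the relative directions.
#' @param flat_tol Relative band half-width around equality (default 0.1).
#' @return A tibble: `gene`, `lps_cpm_6h`, `lps_cpm_24h`, `trend`
#'   (`decrease` / `flat` / `increase`), and when available `rel_6h`,
#'   `rel_24h`.
#' @export
trajectory_table <- function(genes, cpm6, cpm24, de6 = NULL, de24 = NULL,
                             flat_tol = 0.1) {
  mean_lps <- function(x) {
    keep <- x$samples$treatment == "LPS"
    rowMeans(x$counts[, x$samples$sample[keep], drop = FALSE])
  }
  m6 <- mean_lps(cpm6)
  m24 <- mean_lps(cpm24)
  missing <- genes[!(genes %in% names(m6)) | !(genes %in% names(m24))]
  if (length(missing)) {
    stop("gene(s) missing a timepoint: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- m6[genes]
  b <- m24[genes]
  trend <- dplyr::case_when(
    b < (1 - flat_tol) * a ~ "decrease",
    b > (1 + flat_tol) * a ~ "increase",
    TRUE ~ "flat")
  out <- tibble::tibble(gene = genes, lps_cpm_6h = unname(a),
                        lps_cpm_24h = unname(b), trend = trend)
  if (!is.null(de6)) {
    out$rel_6h <- de6$direction[match(genes, de6$feature)]
  }
  if (!is.null(de24)) {
    out$rel_24h <- de24$direction[match(genes, de24$feature)]
  }
  out
}
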