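# Packaged fixtures transcribed from the study's printed summary tables.

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "monosmrna")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture '", name, "' is missing", call. = FALSE)
  }
  path
}

#' Conserved tRF table (18 fragments over 50 tRNA loci)
#'
#' Loads the packaged table of conserved tRNA-derived fragments identified in
#' human monocytes: one row per fragment with its source tRNA isoacceptor
#' type, positional code, DNA sequence, fragment name and the tRNA gene loci
#' that can produce it.
#'
#' Positional codes: `"5"` (fragment starts at the mature tRNA 5' end),
#' `"3"` (fragment ends at the mature 3' end), `"M"` (internal), and
#' `"3down"` (trailer fragment starting immediately downstream of the mature
#' body, released during tRNA 3'-end processing).
#'
#' @return A tibble with columns `trna_type`, `amino_acid`, `anticodon`,
#'   `position`, `sequence` (uppercase DNA), `trf_name` and `loci`
#'   (list-column of locus ids).
#' @export
trf_table4 <- function() {
  tab <- readr::read_tsv(ext_file("table4_trfs.tsv"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("trna_type", "position", "sequence", "trf_name", "loci")
  if (!identical(names(tab), need)) {
    stop("corrupted tRF fixture: unexpected columns", call. = FALSE)
  }
  tab$sequence <- toupper(tab$sequence)
  tab$loci <- strsplit(tab$loci, ",", fixed = TRUE)
  ok <- nrow(tab) == 18L &&
    all(grepl("^[ACGT]+$", tab$sequence)) &&
    all(nchar(tab$sequence) >= 19L & nchar(tab$sequence) <= 21L) &&
    all(lengths(tab$loci) >= 1L) &&
    all(tab$position %in% c("5", "M", "3", "3down"))
  if (!ok) stop("corrupted tRF fixture: row validation failed", call. = FALSE)
  tab$amino_acid <- substr(tab$trna_type, 1L, 3L)
  tab$anticodon <- substr(tab$trna_type, 4L, 6L)
  tab[, c("trna_type", "amino_acid", "anticodon", "position",
          "sequence", "trf_name", "loci")]
}

#' Differentially expressed miRNA tables (6 h and 24 h)
#'
#' Packaged per-timepoint tables of miRNAs called differentially expressed
#' between LPS- and medium-treated monocytes: normalized mean expression in
#' each condition, log2 fold change, direction, and raw/BH-adjusted p-values.
#'
#' @param timepoint 6 or 24 (hours of stimulation).
#' @return A tibble with columns `gene`, `mean_medium`, `mean_lps`, `log2fc`,
#'   `direction`, `pvalue`, `padj`.
#' @export
mirna_de_table <- function(timepoint = c(6, 24)) {
  timepoint <- match.arg(as.character(timepoint[1]), c("6", "24"))
  file <- if (timepoint == "6") "table1_mirna_de_6h.tsv" else "table2_mirna_de_24h.tsv"
  tab <- readr::read_tsv(ext_file(file),
                         col_types = readr::cols(
                           gene = "c", mean_medium = "d", mean_lps = "d",
                           log2fc = "d", direction = "c",
                           pvalue = "d", padj = "d"),
                         progress = FALSE)
  if (anyNA(tab) || any(tab$mean_medium <= 0)) {
    stop("corrupted miRNA DE fixture", call. = FALSE)
  }
  tab
}

#' Spike-in specifications from a printed miRNA DE table
#'
#' Converts a differential-expression table into spike specifications for
#' [simulate_paired_counts()]: the medium-condition mean becomes the baseline
#' mean and the printed log2 fold change the simulated treatment effect.
#'
#' @inheritParams mirna_de_table
#' @return A tibble with columns `feature_id`, `baseline_mean`, `log2fc`.
#' @export
spike_specs <- function(timepoint = c(6, 24)) {
  tab <- mirna_de_table(timepoint)
  tibble::tibble(feature_id = tab$gene,
                 baseline_mean = tab$mean_medium,
                 log2fc = tab$log2fc)
}

#' Multi-method miRNA evidence grid
#'
#' Packaged tri-state evidence table: for each miRNA locus tested, whether
#' NGS, qPCR and tagged RT-PCR (precursor and mature bands) supported LPS
#' upregulation at 6 h and 24 h. `not_tested` / `not_detected` are distinct
#' from `no` and never count as evidence in either direction. The `mature`
#' column maps each locus to its mature miRNA name (the two mir-9 loci
#' collapse to mir-9). The printed `validated_*` and `signature` columns are
#' retained so the decision rule can be cross-checked against them.
#'
#' @return A tibble, one row per miRNA locus.
#' @export
evidence_table3 <- function() {
  tab <- readr::read_tsv(ext_file("table3_evidence.tsv"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  tri <- c("yes", "no", "not_tested", "not_detected")
  tri_cols <- c("ngs_6h", "qpcr_6h", "rtpcr_precursor_6h", "rtpcr_mature_6h",
                "ngs_24h", "qpcr_24h")
  ok <- all(tri_cols %in% names(tab)) &&
    all(unlist(tab[tri_cols]) %in% tri) &&
    !anyNA(tab$mature)
  if (!ok) stop("corrupted evidence fixture", call. = FALSE)
  tab
}

#' miRNA-to-target link table
#'
#' Reads a miRNA/target-gene link table (`mirna<TAB>gene<TAB>source`).
#' Without a path, loads the packaged synthetic fixture that stands in for a
#' functionally-validated target database; users supply their own TSV for
#' real analyses.
#'
#' @param path Optional path to a user-supplied TSV.
#' @return A tibble with columns `mirna`, `gene`, `source`; duplicate
#'   (miRNA, gene) pairs are dropped.
#' @export
target_links <- function(path = NULL) {
  path <- path %||% ext_file("synthetic_mirna_targets.tsv")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab))) {
    stop("link table needs 'mirna' and 'gene' columns", call. = FALSE)
  }
  if (is.null(tab$source)) tab$source <- NA_character_
  dplyr::distinct(tab, .data$mirna, .data$gene, .keep_all = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
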