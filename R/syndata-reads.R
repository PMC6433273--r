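# Small RNA read simulator: insert + 3' adaptor + constant-or-profiled
# quality string, emulating a TruSeq small RNA library. Sequencing error,
# PCR duplication and ligation bias are deliberately not modelled.

#' Specify a read simulation
#'
#' Validates the parameters of one simulated library. Foreground inserts are
#' drawn from designated reference subsequences at their target CPM;
#' background inserts are random subfragments (14-30 nt) of tRNA locus
#' records, each distinct background sequence held below `max_background_cpm`.
#' The library must be fully allocated: foreground CPM plus
#' `background_fraction * 1e6` must equal one million.
#'
#' @param foreground Data frame with columns `sequence` (designated insert)
#'   and `cpm` (target counts per million).
#' @param total_reads Number of records to emit (exactly).
#' @param background_fraction Fraction of reads drawn from the degradation
#'   background, in `[0, 1)`.
#' @param adaptor 3' adaptor sequence (>= 10 nt).
#' @param max_read_len Instrument read length; insert + adaptor is truncated
#'   to this many bases, so short inserts carry the full adaptor and long
#'   inserts a 3'-truncated prefix of it.
#' @param phred Constant Phred score, or an integer vector giving a
#'   per-position quality profile (recycled/truncated to the read length).
#' @param max_background_cpm Per-distinct-sequence background abundance cap
#'   (CPM, exclusive).
#' @param seed Integer seed; two runs with the same spec and seed emit
#'   byte-identical FASTQ.
#' @return A validated `read_sim_spec` object.
#' @export
read_sim_spec <- function(foreground, total_reads,
                          background_fraction = 0,
                          adaptor = truseq_small_rna_adapter,
                          max_read_len = 50L, phred = 40L,
                          max_background_cpm = 5, seed = NULL) {
  foreground <- tibble::as_tibble(foreground)
  stopifnot(all(c("sequence", "cpm") %in% names(foreground)),
            all(foreground$cpm > 0), total_reads >= 1,
            background_fraction >= 0, background_fraction < 1,
            nchar(adaptor) >= 10L, max_read_len >= 20L,
            all(phred >= 2), all(phred <= 41))
  foreground$sequence <- toupper(foreground$sequence)
  if (anyDuplicated(foreground$sequence)) {
    stop("duplicate foreground sequences", call. = FALSE)
  }
  if (sum(foreground$cpm) > 1e6 + 1e-6) {
    stop("infeasible CPM allocation: foreground exceeds one million CPM",
         call. = FALSE)
  }
  if (abs(sum(foreground$cpm) / 1e6 + background_fraction - 1) > 1e-6) {
    stop("infeasible CPM allocation: foreground CPM + background must ",
         "account for the whole library", call. = FALSE)
  }
  structure(list(foreground = foreground,
                 total_reads = as.integer(total_reads),
                 background_fraction = background_fraction,
                 adaptor = toupper(adaptor),
                 max_read_len = as.integer(max_read_len),
                 phred = as.integer(phred),
                 max_background_cpm = max_background_cpm,
                 seed = seed),
            class = "read_sim_spec")
}

# Distinct degradation fragments (14-30 nt subfragments of tRNA loci) with
# per-fragment counts capped so no distinct sequence reaches the CPM cap.
sample_background <- function(trna_seqs, n_reads, cap, exclude) {
  if (n_reads == 0L) {
    return(tibble::tibble(sequence = character(), count = integer()))
  }
  if (!length(trna_seqs)) stop("no tRNA loci to draw background from",
                               call. = FALSE)
  sizes_max <- max(1L, min(4L, cap))
  out <- tibble::tibble(sequence = character(), count = integer())
  need <- n_reads
  for (iter in 1:40) {
    if (need <= 0L) break
    n_parts <- ceiling(need / ((1 + sizes_max) / 2)) + 16L
    sizes <- sample.int(sizes_max, n_parts, replace = TRUE)
    keep <- cumsum(sizes) <= need
    sizes <- sizes[keep]
    deficit <- need - sum(sizes)
    if (deficit > 0L) sizes <- c(sizes, rep.int(1L, deficit))
    k <- length(sizes)
    locus <- sample.int(length(trna_seqs), k, replace = TRUE)
    len <- sample(14:30, k, replace = TRUE)
    maxstart <- nchar(trna_seqs)[locus] - len + 1L
    start <- 1L + floor(runif(k) * maxstart)
    frag <- substr(trna_seqs[locus], start, start + len - 1L)
    add <- tibble::tibble(sequence = frag, count = sizes)
    add <- add[!(add$sequence %in% exclude), , drop = FALSE]
    out <- dplyr::summarise(dplyr::group_by(
      dplyr::bind_rows(out, add), .data$sequence),
      count = sum(.data$count), .groups = "drop")
    over <- out$count > cap
    out$count[over] <- cap
    need <- n_reads - sum(out$count)
  }
  if (need > 0L) stop("could not allocate background reads under the ",
                      "per-sequence cap", call. = FALSE)
  out
}

#' Simulate an adaptored small RNA FASTQ library
#'
#' Draws `total_reads` inserts (foreground at their target CPM via a
#' multinomial allocation, the remainder as degradation background), appends
#' the 3' adaptor truncated at the instrument read length, and writes Sanger
#' Phred+33 FASTQ.
#'
#' @param reference Reference tibble from [build_reference()] (background
#'   fragments are drawn from its tRNA locus records).
#' @param spec A [read_sim_spec()].
#' @param path Output FASTQ path (plain text; `.gz` also works).
#' @return Invisibly, a list with `path`, `foreground` (tibble of realized
#'   per-sequence read counts) and `background` (same for background
#'   fragments).
#' @export
simulate_reads <- function(reference, spec, path) {
  stopifnot(inherits(spec, "read_sim_spec"))
  fg <- spec$foreground
  N <- spec$total_reads
  run <- function() {
    p <- c(fg$cpm / 1e6, max(0, 1 - sum(fg$cpm) / 1e6))
    counts <- as.vector(rmultinom(1L, N, p))
    fg_counts <- counts[seq_len(nrow(fg))]
    n_bg <- counts[length(counts)]
    cap <- max(1L, ceiling(spec$max_background_cpm * N / 1e6) - 1L)
    trna <- reference$sequence[reference$category == "tRNA_locus"]
    bg <- sample_background(trna, n_bg, cap, exclude = fg$sequence)
    inserts <- c(rep.int(fg$sequence, fg_counts),
                 rep.int(bg$sequence, bg$count))
    inserts <- inserts[sample.int(length(inserts))]
    reads <- substr(paste0(inserts, spec$adaptor), 1L, spec$max_read_len)
    widths <- nchar(reads)
    quals <- quality_strings(widths, spec$phred)
    ids <- sprintf("@read%07d", seq_along(reads))
    fastq <- rbind(ids, reads, "+", quals)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(as.vector(fastq), con, sep = "\n")
    list(path = path,
         foreground = tibble::tibble(sequence = fg$sequence,
                                     count = fg_counts),
         background = bg)
  }
  out <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  invisible(out)
}

quality_strings <- function(widths, phred) {
  if (length(phred) == 1L) {
    return(strrep(intToUtf8(phred + 33L), widths))
  }
  profile <- rep_len(phred, max(widths))
  full <- intToUtf8(profile + 33L, multiple = FALSE)
  substr(strrep(full, 1L), 1L, widths)
}
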