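# Synthetic small-RNA reference construction.
#
# Mature tRNA bodies are synthetic random sequences: the tRF screen depends
# only on positional structure (where a fragment sits relative to the mature
# body and its flanks), so realism is limited to body length, 30-nt genomic
# flanks, and exact fragment placement. Bodies exclude the post-
# transcriptional 3' CCA; 3'-fragment placements are interpreted against the
# genomic body end.

REF_CATEGORIES <- c("miRNA_hairpin", "tRNA_locus", "snoRNA", "rRNA", "yRNA")

random_dna <- function(n) {
  stringi::stri_rand_strings(length(n), n, pattern = "[ACGT]")
}

#' Build a synthetic small-RNA reference embedding the conserved tRFs
#'
#' Constructs one tRNA locus record per locus id in the tRF table: a random
#' mature body of 70-90 nt with the row's tRF sequence embedded at the
#' coordinate implied by its positional code (`5` at the body start, `3`
#' ending at the body 3' end, `M` interior with more than `tol` margin from
#' both termini, `3down` starting immediately after the body end inside the
#' downstream flank), padded by `flank` random nucleotides on each side.
#' Loci sharing a row carry the identical embedded tRF subsequence.
#' Additional decoy records (tRNA loci without embedded fragments, miRNA
#' hairpins, snoRNA, rRNA, Y RNA) contain no tRF sequence; this is enforced
#' by scanning and regenerating colliding records.
#'
#' @param fixture tRF table from [trf_table4()].
#' @param flank Flank width in nt (default 30); must cover the longest
#'   trailer fragment.
#' @param decoys Either a single integer (split across categories roughly
#'   60/15/10/10/5 percent) or a named integer vector over
#'   `miRNA_hairpin`, `tRNA_locus`, `snoRNA`, `rRNA`, `yRNA`.
#' @param seed Integer seed; the build is a pure function of
#'   `(fixture, flank, decoys, seed)`.
#' @param body_len Range of mature-body lengths in nt.
#' @param tol Positional tolerance the downstream classifier will use; the
#'   interior placement keeps at least `tol + 1` nt clear of both termini.
#' @return A tibble with columns `id`, `category`, `sequence`, `body_start`,
#'   `body_end` (1-based inclusive coordinates of the mature body; `NA` for
#'   non-tRNA records) and `flank`, with an `embedding` attribute recording
#'   the true placement (locus, sequence, offset, position) of every
#'   embedded fragment.
#' @export
build_reference <- function(fixture = trf_table4(), flank = 30L,
                            decoys = 60L, seed = 1L,
                            body_len = c(70L, 90L), tol = 3L) {
  flank <- as.integer(flank)
  body_len <- as.integer(body_len)
  tol <- as.integer(tol)
  stopifnot(flank >= 1L, body_len[1] >= 40L, body_len[2] >= body_len[1])
  trailer_w <- nchar(fixture$sequence[fixture$position == "3down"])
  if (length(trailer_w) && flank < max(trailer_w)) {
    stop("flank shorter than the longest trailer fragment", call. = FALSE)
  }
  if (max(nchar(fixture$sequence)) + 2L * (tol + 1L) > body_len[1]) {
    stop("tRF longer than the mature body allows", call. = FALSE)
  }
  if (is.null(names(decoys))) {
    n <- as.integer(decoys[1])
    decoys <- c(miRNA_hairpin = round(0.60 * n), tRNA_locus = round(0.15 * n),
                snoRNA = round(0.10 * n), rRNA = round(0.10 * n), yRNA = 0L)
    decoys["yRNA"] <- max(0L, n - sum(decoys))
  }
  stopifnot(all(names(decoys) %in% REF_CATEGORIES))

  placements <- tidyr::unnest(
    fixture[, c("position", "sequence", "loci")], "loci")
  if (anyDuplicated(placements$loci)) {
    stop("a locus id appears in more than one tRF row", call. = FALSE)
  }
  trf_seqs <- unique(fixture$sequence)

  withr::with_seed(seed, {
    # designated tRNA loci with one embedded fragment each
    loci <- purrr::pmap(placements, function(position, sequence, loci) {
      trf_seq <- sequence
      w <- nchar(trf_seq)
      repeat {
        L <- sample(seq(body_len[1], body_len[2]), 1L)
        body <- random_dna(L)
        f5 <- random_dna(flank)
        f3 <- random_dna(flank)
        offset <- switch(position,
          "5" = flank + 1L,
          "3" = flank + L - w + 1L,
          "M" = flank + sample(seq(tol + 2L, L - w + 1L - tol - 1L), 1L),
          "3down" = flank + L + 1L)
        if (position == "3down") {
          substr(f3, 1L, w) <- trf_seq
        } else {
          substr(body, offset - flank, offset - flank + w - 1L) <- trf_seq
        }
        full <- paste0(f5, body, f3)
        # the embedded fragment must occur exactly once, and no other tRF
        # may have been created by chance in the random context
        n_self <- stringi::stri_count_fixed(full, trf_seq)
        others <- setdiff(trf_seqs, trf_seq)
        if (n_self == 1L && !any(stringi::stri_detect_fixed(full, others))) {
          return(tibble::tibble(
            id = loci, category = "tRNA_locus", sequence = full,
            body_start = flank + 1L, body_end = flank + L,
            flank = flank, trf = trf_seq, offset = offset,
            position = position))
        }
      }
    })
    loci <- dplyr::bind_rows(loci)

    decoy_len <- c(miRNA_hairpin = 80L, tRNA_locus = 0L, snoRNA = 110L,
                   rRNA = 150L, yRNA = 100L)
    decoy_rows <- purrr::imap(decoys[decoys > 0], function(k, cat) {
      purrr::map(seq_len(k), function(i) {
        repeat {
          if (cat == "tRNA_locus") {
            L <- sample(seq(body_len[1], body_len[2]), 1L)
            seqs <- paste0(random_dna(flank), random_dna(L), random_dna(flank))
            bs <- flank + 1L; be <- flank + L; fl <- flank
          } else {
            seqs <- random_dna(decoy_len[[cat]])
            bs <- NA_integer_; be <- NA_integer_; fl <- NA_integer_
          }
          if (!any(stringi::stri_detect_fixed(seqs, trf_seqs))) {
            return(tibble::tibble(
              id = sprintf("syn-%s-%03d", sub("_.*", "", cat), i),
              category = cat, sequence = seqs,
              body_start = bs, body_end = be, flank = fl,
              trf = NA_character_, offset = NA_integer_,
              position = NA_character_))
          }
        }
      })
    })
    decoy_rows <- dplyr::bind_rows(purrr::flatten(decoy_rows))
  })

  ref <- dplyr::bind_rows(loci, decoy_rows)
  embedding <- ref[!is.na(ref$trf),
                   c("id", "trf", "offset", "position")]
  names(embedding) <- c("locus", "sequence", "offset", "position")
  ref <- ref[, c("id", "category", "sequence", "body_start", "body_end",
                 "flank")]
  attr(ref, "embedding") <- embedding
  ref
}

#' Write / read a reference set as FASTA
#'
#' Headers follow `id|category|body_start-body_end|flank=N` with 1-based
#' inclusive body coordinates; non-tRNA records carry only `id|category`.
#'
#' @param ref Reference tibble from [build_reference()].
#' @param path FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  headers <- ifelse(
    is.na(ref$body_start),
    paste(ref$id, ref$category, sep = "|"),
    paste0(ref$id, "|", ref$category, "|", ref$body_start, "-",
           ref$body_end, "|flank=", ref$flank))
  seqs <- Biostrings::DNAStringSet(setNames(ref$sequence, headers))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringi::stri_split_fixed(names(seqs), "|")
  coords <- purrr::map(parts, function(p) {
    if (length(p) >= 4L) {
      se <- as.integer(stringi::stri_split_fixed(p[3], "-")[[1]])
      fl <- as.integer(sub("flank=", "", p[4], fixed = TRUE))
      c(se, fl)
    } else c(NA_integer_, NA_integer_, NA_integer_)
  })
  tibble::tibble(
    id = purrr::map_chr(parts, 1),
    category = purrr::map_chr(parts, 2),
    sequence = unname(as.character(seqs)),
    body_start = purrr::map_int(coords, 1),
    body_end = purrr::map_int(coords, 2),
    flank = purrr::map_int(coords, 3))
}
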