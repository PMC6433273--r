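# Independent oracles kept deliberately naive: these re-derive expected
# values by brute force so the implementation under test never checks
# itself.

# O(n * m) substring scan over every (query, reference) pair.
naive_scan <- function(queries, reference) {
  rows <- list()
  for (q in queries) {
    for (i in seq_len(nrow(reference))) {
      s <- reference$sequence[i]
      w <- nchar(q)
      for (off in seq_len(max(0L, nchar(s) - w + 1L))) {
        if (substr(s, off, off + w - 1L) == q) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            query = q, ref_id = reference$id[i],
            category = reference$category[i], offset = off)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  dplyr::arrange(out, query, ref_id, offset)
}

# Exact two-sided sign-flip test on per-donor ratios: enumerate all 2^n
# sign assignments and compare |mean| against the observed one.
sign_flip_p <- function(r) {
  n <- length(r)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- abs(flips %*% abs(r)) / n
  mean(means >= abs(mean(r)) - 1e-12)
}

# Minimal FASTQ writer for handcrafted reads.
write_fastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals))
  lines <- as.vector(rbind(sprintf("@r%03d", seq_along(seqs)),
                           seqs, "+", quals))
  writeLines(lines, path)
  path
}

q40 <- function(n) strrep("I", n)  # Phred 40 in Sanger +33

# Tiny random reference set for alignment tests.
random_reference <- function(n = 6L, len = 60L, seed = 1L) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("ref%02d", seq_len(n)),
    category = rep(c("miRNA_hairpin", "snoRNA", "rRNA"), length.out = n),
    sequence = stringi::stri_rand_strings(n, len, pattern = "[ACGT]"),
    body_start = NA_integer_, body_end = NA_integer_,
    flank = NA_integer_))
}
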