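fixture <- trf_table4()

test_that("reference build embeds every fragment where its position code says", {
  ref <- build_reference(fixture, flank = 30, decoys = 20, seed = 11)
  trna <- ref[ref$category == "tRNA_locus", ]
  emb <- attr(ref, "embedding")

  expect_identical(sum(!is.na(emb$offset)), 50L)
  expect_identical(nrow(ref), 50L + 20L)

  # exhaustive substring scan: every fragment in >= 1 tRNA locus, 0 decoys
  decoy <- ref[ref$category != "tRNA_locus" | !(ref$id %in% emb$locus), ]
  for (s in fixture$sequence) {
    expect_true(any(grepl(s, trna$sequence, fixed = TRUE)))
    expect_false(any(grepl(s, decoy$sequence, fixed = TRUE)))
  }

  # a 5' fragment is a prefix of the mature body
  five <- emb[emb$position == "5", ][1, ]
  rec <- ref[ref$id == five$locus, ]
  expect_identical(
    substr(rec$sequence, rec$body_start,
           rec$body_start + nchar(five$sequence) - 1L),
    five$sequence)
  expect_identical(five$offset, rec$body_start)

  # the known trailer fragment starts at body_end + 1 of its serine locus
  tr <- emb[emb$sequence == "AAGCGGGTGCTCTTATTTT", ]
  expect_identical(tr$locus, "tRNA2-SerTGA(ch10)")
  rec <- ref[ref$id == tr$locus, ]
  expect_identical(tr$offset, rec$body_end + 1L)

  # 3' fragments end exactly at the genomic body end
  th <- emb[emb$position == "3", ][1, ]
  rec <- ref[ref$id == th$locus, ]
  expect_identical(th$offset + nchar(th$sequence) - 1L, rec$body_end)

  # loci sharing a row carry the identical embedded subsequence
  leu <- fixture[fixture$trna_type == "LeuCAG", ]
  leu_rec <- ref[ref$id %in% leu$loci[[1]], ]
  expect_true(all(grepl(leu$sequence, leu_rec$sequence, fixed = TRUE)))
})

test_that("reference build is a pure function of its arguments", {
  r1 <- build_reference(fixture, flank = 30, decoys = 10, seed = 3)
  r2 <- build_reference(fixture, flank = 30, decoys = 10, seed = 3)
  expect_identical(r1, r2)
  r3 <- build_reference(fixture, flank = 30, decoys = 10, seed = 4)
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("reference rejects a flank shorter than the longest trailer", {
  expect_error(build_reference(fixture, flank = 15, decoys = 5, seed = 1),
               "flank")
})

test_that("reference FASTA round-trips through the header convention", {
  ref <- build_reference(fixture, flank = 30, decoys = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".fa")
  write_reference_fasta(ref, path)
  back <- read_reference_fasta(path)
  expect_identical(back$id, ref$id)
  expect_identical(back$sequence, ref$sequence)
  expect_identical(back$body_start, ref$body_start)
  expect_identical(back$body_end, ref$body_end)
})

small_ref <- function(seed = 2) {
  build_reference(trf_table4(), flank = 30, decoys = 10, seed = seed)
}

test_that("read simulator hits CPM targets and honours its contracts", {
  ref <- small_ref()
  mature <- substr(ref$sequence[ref$category == "miRNA_hairpin"][1:2], 11, 32)
  fg <- tibble::tibble(sequence = c(mature[1], mature[2]),
                       cpm = c(600, 1e6 - 600))
  spec <- read_sim_spec(fg, total_reads = 2e5, background_fraction = 0,
                        seed = 9)
  path <- withr::local_tempfile(fileext = ".fastq")
  out <- simulate_reads(ref, spec, path)

  lines <- readLines(path)
  expect_identical(length(lines), 4L * 2e5L)
  # with no background, every insert maps to a designated sequence
  reads <- lines[seq(2, length(lines), by = 4)]
  inserts <- strip_adaptor(reads)
  expect_true(all(inserts %in% fg$sequence))
  # 600 CPM of 2e5 reads: ~120 occurrences, within Poisson fluctuation
  n1 <- sum(inserts == mature[1])
  expect_lt(abs(n1 - 120), 4 * sqrt(120))
  expect_identical(out$foreground$count[1], n1)
})

test_that("read simulation is byte-identical under a fixed seed", {
  ref <- small_ref()
  fg <- tibble::tibble(
    sequence = substr(ref$sequence[ref$category == "miRNA_hairpin"][1], 11, 32),
    cpm = 9e5)
  spec <- read_sim_spec(fg, total_reads = 3e4, background_fraction = 0.1,
                        seed = 21)
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(ref, spec, p1)
  simulate_reads(ref, spec, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("infeasible read specs fail before emission", {
  fg <- tibble::tibble(sequence = "ACGTACGTACGTACGTAC", cpm = 600)
  # unallocated library mass
  expect_error(read_sim_spec(fg, 1e5, background_fraction = 0),
               "infeasible")
  expect_error(read_sim_spec(tibble::tibble(sequence = "ACGT", cpm = 2e6),
                             1e5), "infeasible|exceed")
  expect_error(read_sim_spec(fg, 1e5, background_fraction = 0.9994,
                             adaptor = "ACGTT"), "adaptor")
})

test_that("paired count simulation recovers spiked means (Poisson limit)", {
  spikes <- tibble::tibble(feature_id = c("a", "b", "c"),
                           baseline_mean = c(500, 2000, 120),
                           log2fc = c(1.5, -1, 0.8))
  cm <- simulate_paired_counts(spikes, n_null = 0, n_donors = 400,
                               dispersion = 0, donor_sd = 0, seed = 13)
  lps <- cm$counts[, cm$samples$treatment == "LPS"]
  for (i in 1:3) {
    expected <- spikes$baseline_mean[i] * 2^spikes$log2fc[i]
    se <- sqrt(expected / 400)
    expect_lt(abs(mean(lps[i, ]) - expected), 3 * se + 1e-9)
  }
})

test_that("paired count simulation has the donor-paired layout", {
  cm <- simulate_paired_counts(spike_specs(6), n_null = 50, n_donors = 7,
                               dispersion = 0.05, seed = 2)
  expect_identical(ncol(cm$counts), 14L)
  expect_identical(nrow(cm$counts), 65L)
  tab <- table(cm$samples$donor, cm$samples$treatment)
  expect_true(all(tab == 1L))
  expect_error(simulate_paired_counts(n_donors = 1), "donors")
  expect_error(simulate_paired_counts(
    tibble::tibble(feature_id = "x", baseline_mean = -1, log2fc = 0)),
    "baseline")
})

test_that("a fully null simulation yields calibrated paired p-values", {
  cm <- simulate_paired_counts(NULL, n_null = 2000, n_donors = 7,
                               dispersion = 0.05, seed = 17)
  pr <- paired_log2fc(cm)
  p <- paired_test(pr$ratios)
  frac <- mean(p < 0.05)
  sigma <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * sigma)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
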