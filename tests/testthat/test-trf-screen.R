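prof <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(locus_id = r[[1]], sequence = r[[2]],
                   offset = as.integer(r[[3]]), mean_cpm = as.numeric(r[[4]]))
  }))
}
seq21 <- function(ch = "A") strrep(ch, 21)

test_that("the screen applies CPM, dominance and length rules", {
  # dominant candidate: 600 vs 5 CPM -> dominance 120, accepted
  p <- prof(list("L1", seq21("A"), 31, 600), list("L1", "ACGTACGTACGTACG", 40, 5))
  got <- screen_trfs(p)
  expect_identical(got$sequence, seq21("A"))
  expect_equal(got$dominance, 120)
  # dominance 60 < 100 -> rejected
  p <- prof(list("L1", seq21("A"), 31, 600), list("L1", "ACGTACGTACGTACG", 40, 10))
  expect_identical(nrow(screen_trfs(p)), 0L)
  # lone sequence at a locus: dominance infinite, passes
  p <- prof(list("L1", seq21("A"), 31, 600))
  got <- screen_trfs(p)
  expect_identical(got$dominance, Inf)
  # two distinct sequences tied at the top: both fail
  p <- prof(list("L1", seq21("A"), 31, 600), list("L1", seq21("G"), 40, 600))
  expect_identical(nrow(screen_trfs(p)), 0L)
  # below the CPM floor
  p <- prof(list("L1", seq21("A"), 31, 400))
  expect_identical(nrow(screen_trfs(p)), 0L)
  # outside the length window
  p <- prof(list("L1", strrep("A", 17), 31, 900))
  expect_identical(nrow(screen_trfs(p)), 0L)
  expect_identical(nrow(screen_trfs(p[0, ])), 0L)
})

test_that("tightening thresholds never grows the accepted set", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      p <- tibble::tibble(
        locus_id = sample(sprintf("L%02d", 1:8), 40, replace = TRUE),
        sequence = stringi::stri_rand_strings(40, sample(15:32, 40, TRUE),
                                              pattern = "[ACGT]"),
        offset = sample.int(60, 40, TRUE),
        mean_cpm = rexp(40) * 800)
      base <- screen_trfs(p, min_cpm = 300, min_dominance = 20)
      for (cpm in c(500, 900)) {
        for (dom in c(50, 150)) {
          tight <- screen_trfs(p, min_cpm = cpm, min_dominance = dom)
          key <- function(x) paste(x$locus_id, x$sequence)
          expect_true(all(key(tight) %in% key(base)))
          expect_true(all(tight$dominance >= dom))
          expect_true(all(tight$mean_cpm >= cpm))
        }
      }
    }
  })
})

test_that("screen output is invariant to locus enumeration order", {
  withr::with_seed(77, {
    p <- tibble::tibble(
      locus_id = sample(sprintf("L%02d", 1:6), 30, replace = TRUE),
      sequence = stringi::stri_rand_strings(30, 21, pattern = "[ACGT]"),
      offset = sample.int(50, 30, TRUE),
      mean_cpm = rexp(30) * 1000)
  })
  a <- screen_trfs(p)
  b <- screen_trfs(p[withr::with_seed(3, sample(nrow(p))), ])
  expect_identical(a, b)
})

test_that("positional classification follows the precedence rules", {
  bs <- 31L; be <- 110L  # 80-nt body behind a 30-nt flank
  expect_identical(classify_position(31L, 21L, bs, be), "5p")
  expect_identical(classify_position(34L, 21L, bs, be), "5p")   # start tol
  expect_identical(classify_position(35L, 21L, bs, be), "M")
  expect_identical(classify_position(90L, 21L, bs, be), "3p")   # ends at be
  expect_identical(classify_position(87L, 21L, bs, be), "3p")   # end tol
  expect_identical(classify_position(86L, 21L, bs, be), "M")
  expect_identical(classify_position(111L, 19L, bs, be), "trailer3")
  # trailer precedence over 3p for anything starting past the body end
  expect_identical(classify_position(115L, 21L, bs, be), "trailer3")
  expect_error(classify_position(0L, 21L, bs, be), "bounds")
  expect_error(classify_position(31L, 21L, NA_integer_, be), "bounds")
})

test_that("identical sequences merge across loci; conflicts are flagged", {
  ref <- tibble::tibble(
    id = sprintf("L%02d", 1:9), category = "tRNA_locus",
    sequence = strrep("N", 150), body_start = 31L, body_end = 110L,
    flank = 30L)
  acc <- tibble::tibble(
    locus_id = ref$id, sequence = seq21("A"), offset = 31L,
    mean_cpm = 700, second_cpm = 2, dominance = 350)
  got <- merge_trfs(acc, ref)
  expect_identical(nrow(got), 1L)
  expect_identical(got$n_loci, 9L)
  expect_identical(got$position, "5p")
  expect_false(got$flagged)

  # two distinct sequences stay separate records
  acc2 <- dplyr::bind_rows(acc[1, ],
                           dplyr::mutate(acc[2, ], sequence = seq21("G")))
  expect_identical(nrow(merge_trfs(acc2, ref)), 2L)

  # one sequence accepted at a 5' position in one locus and trailer in
  # another is flagged, not silently merged
  acc3 <- dplyr::bind_rows(acc[1, ], dplyr::mutate(acc[2, ], offset = 111L))
  got3 <- merge_trfs(acc3, ref)
  expect_true(got3$flagged)
  expect_identical(got3$position, "5p/trailer3")

  # merging is invariant to candidate order and to partition-then-pool
  acc4 <- dplyr::bind_rows(acc2, acc3[0, ])
  m_all <- merge_trfs(acc4, ref)
  m_shuf <- merge_trfs(acc4[c(2, 1), ], ref)
  expect_identical(m_all, m_shuf)
})

test_that("summaries of the printed fragment table match its bookkeeping", {
  trfs <- fixture_trfs()
  s <- summarize_trfs(trfs)
  expect_identical(s$n_trfs, 18L)
  expect_identical(s$n_loci, 50L)
  expect_identical(s$n_amino_acids, 12L)
  expect_identical(s$n_types, 16L)
  expect_identical(s$positions,
                   c("5p" = 7L, "3p" = 8L, "M" = 1L, "trailer3" = 2L))
  expect_identical(sum(trfs$prior_id), 3L)

  empty <- summarize_trfs(fixture_trfs()[0, ])
  expect_identical(empty$n_trfs, 0L)
  expect_identical(empty$n_loci, 0L)
  expect_identical(sum(empty$positions), 0L)

  one <- summarize_trfs(fixture_trfs()[1, ])
  expect_identical(one$n_trfs, 1L)
  expect_identical(one$n_types, 1L)
})
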