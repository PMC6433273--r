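test_that("exact alignment equals a naive substring scan", {
  ref <- random_reference(n = 8, len = 70, seed = 41)
  withr::with_seed(42, {
    # half the queries are genuine subsequences, half random
    subs <- vapply(sample(seq_len(nrow(ref)), 50, replace = TRUE),
                   function(i) {
                     w <- sample(13:25, 1)
                     s <- sample(nchar(ref$sequence[i]) - w + 1, 1)
                     substr(ref$sequence[i], s, s + w - 1)
                   }, "")
    rand <- stringi::stri_rand_strings(50, 16, pattern = "[ACGT]")
  })
  queries <- unique(c(subs, rand))
  got <- align_exact(queries, ref)
  want <- naive_scan(queries, ref)
  expect_identical(nrow(got), nrow(want))
  expect_identical(got[order(got$query, got$ref_id, got$offset), ],
                   want[order(want$query, want$ref_id, want$offset), ])
})

test_that("a full-length reference query hits itself at offset one", {
  ref <- random_reference(n = 3, len = 40, seed = 7)
  hits <- align_exact(ref$sequence[2], ref)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$ref_id, "ref02")
  expect_identical(hits$offset, 1L)
})

test_that("the lysine fragment hits all nine of its loci and nothing else", {
  ref <- build_reference(trf_table4(), flank = 30, decoys = 20, seed = 2)
  hits <- align_exact("GCTAGCTCAGTCGGTAGAGCA", ref)
  lys <- trf_table4()
  expect_setequal(hits$ref_id,
                  lys$loci[[which(lys$trna_type == "LysCTT")]])
  expect_identical(nrow(hits), 9L)
  asn <- assign_reads(hits, "GCTAGCTCAGTCGGTAGAGCA")
  expect_identical(asn$status, "retained")
  expect_identical(asn$category, "tRNA_locus")
  expect_identical(asn$n_refs, 9L)
})

test_that("assignment retains single-category hits and discards the rest", {
  shared <- "ACGTACGTACGTACGTACGT"
  ref <- tibble::tibble(
    id = c("h1", "r1", "t1", "t2"),
    category = c("miRNA_hairpin", "rRNA", "tRNA_locus", "tRNA_locus"),
    sequence = c(paste0("GG", shared, "AA"), paste0("TT", shared, "CC"),
                 paste0("CACA", shared), paste0(shared, "GTGT")),
    body_start = NA_integer_, body_end = NA_integer_, flank = NA_integer_)
  queries <- c(shared, "TTTTTTTTTTTTTTT")
  asn <- assign_reads(align_exact(queries, ref), queries)
  expect_identical(asn$status[asn$sequence == shared], "multimapped")
  expect_identical(asn$status[asn$sequence == "TTTTTTTTTTTTTTT"], "unmapped")

  trna_only <- ref[ref$category == "tRNA_locus", ]
  asn2 <- assign_reads(align_exact(shared, trna_only), shared)
  expect_identical(asn2$status, "retained")
  expect_identical(asn2$feature_id, "t1;t2")
})

test_that("assignment is invariant to reference enumeration order", {
  ref <- build_reference(trf_table4(), flank = 30, decoys = 12, seed = 6)
  queries <- trf_table4()$sequence
  a1 <- assign_reads(align_exact(queries, ref), queries)
  shuffled <- ref[withr::with_seed(1, sample(nrow(ref))), ]
  a2 <- assign_reads(align_exact(queries, shuffled), queries)
  expect_identical(a1[order(a1$sequence), ], a2[order(a2$sequence), ])
})

test_that("count building conserves retained reads and reports fractions", {
  ref <- tibble::tibble(
    id = c("mirA", "mirB", "tX"),
    category = c("miRNA_hairpin", "miRNA_hairpin", "tRNA_locus"),
    sequence = c("ACGGTTACGGTTACGGTTAACC", "TTGGCCAATTGGCCAATTGGCA",
                 "GATTACAGATTACAGATTACAG"),
    body_start = NA_integer_, body_end = NA_integer_, flank = NA_integer_)
  queries <- c(ref$sequence, "AAAAAAAAAAAAAAA")
  asn <- assign_reads(align_exact(queries, ref), queries)
  collapsed <- list(
    s1 = tibble::tibble(sequence = queries[c(1, 3)], count = c(80L, 20L)),
    s2 = tibble::tibble(sequence = queries[c(1, 2, 4)],
                        count = c(30L, 50L, 999L)))
  samples <- tibble::tibble(sample = c("s1", "s2"), donor = c("d1", "d1"),
                            treatment = c("LPS", "medium"), timepoint = 6)
  x <- build_counts(collapsed, asn, samples)
  # unmapped sequences never enter the matrix
  expect_identical(sort(rownames(x$counts)), sort(ref$sequence))
  expect_identical(unname(x$mapped_totals), c(100, 80))
  fr <- x$fractions
  expect_identical(fr$fraction[fr$sample == "s1" &
                                 fr$category == "miRNA_hairpin"], 0.8)
  # a sample with only miRNA foreground is 100% miRNA
  expect_identical(fr$fraction[fr$sample == "s2" &
                                 fr$category == "miRNA_hairpin"], 1)
  expect_error(build_counts(collapsed[1], asn,
                            samples[samples$sample == "s2", ]),
               "absent from metadata")
})

test_that("CPM normalization scales columns to one million", {
  m <- matrix(c(100, 1999900, 10, 90), ncol = 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  cpm <- to_cpm(m, totals = c(a = 2e6, b = 100))
  expect_identical(cpm["f1", "a"], 50)
  expect_equal(colSums(to_cpm(m)), c(a = 1e6, b = 1e6))
  expect_error(to_cpm(m, totals = c(a = 2e6, b = 0)), "zero-total.*b")
  # invariant to a per-sample rescaling of raw counts
  scaled <- sweep(m, 2, c(3, 11), "*")
  expect_equal(to_cpm(scaled), to_cpm(m))
})

test_that("top-n share matches a brute-force sort-and-sum", {
  expect_identical(top_n_share(matrix(5, 1, 2), n = 1), 1)
  expect_equal(top_n_share(matrix(1, 200, 3), n = 100), 0.5)
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- matrix(rexp(300) * 100, nrow = 60)
      mu <- rowMeans(m)
      want <- sum(sort(mu, decreasing = TRUE)[1:10]) / sum(mu)
      expect_equal(top_n_share(m, 10), want)
    }
  })
  expect_warning(top_n_share(matrix(1, 5, 2), n = 10), "exceeds")
})
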