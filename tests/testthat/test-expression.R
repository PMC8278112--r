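test_that("read_matrix loads a TSV and enforces grouping and non-negativity", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2\ts3\ts4",
               "g1\t0.4\t0.8\t1\t2",
               "g2\t0\t0\t5\t0"), p)
  grp <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    tissue = c("A", "A", "B", "B"))
  m <- read_matrix(p, grp, units = "TPM")
  expect_equal(dim(m$values), c(2L, 4L))
  expect_equal(length(unique(m$grouping)), 2)

  expect_error(read_matrix(p, grp[grp$sample_id != "s4", ], units = "TPM"),
               "s4")

  writeLines(c("feature\ts1\ts2", "g1\t1\t-1.0"), p)
  expect_error(read_matrix(p, data.frame(sample_id = c("s1", "s2"),
                                         tissue = c("A", "B")), units = "TPM"),
               "g1.*s2")

  writeLines(c("feature\ts1\ts2", "g1\t1\t1", "g1\t2\t2"), p)
  expect_error(read_matrix(p, data.frame(sample_id = c("s1", "s2"),
                                         tissue = c("A", "B")), units = "TPM"),
               "duplicate feature ids")
})

test_that("average_replicates takes the arithmetic mean per tissue", {
  m <- em(matrix(c(0.4, 0.8, 1, 2,
                   0, 0, 0, 0), nrow = 2, byrow = TRUE),
          tissues = c("A", "A", "B", "B"))
  prof <- average_replicates(m)
  expect_equal(prof["g1", "A"], 0.6)
  expect_equal(prof["g1", "B"], 1.5)
  expect_equal(unname(prof["g2", ]), c(0, 0))

  single <- em(matrix(2.0, 1, 1), tissues = "A")
  expect_equal(unname(average_replicates(single)[1, "A"]), 2.0)

  counts <- em(matrix(1:4, 2), tissues = c("A", "B"), units = "counts")
  expect_error(average_replicates(counts), "normalize")
})

test_that("expression calls are strictly greater-than the threshold", {
  prof <- matrix(c(0.6, 0.5, 0.0, 0.51), nrow = 4,
                 dimnames = list(c("above", "boundary", "zero", "just"), "A"))
  calls <- call_expressed(prof, threshold = 0.5)
  expect_setequal(calls$expressed$A, c("above", "just"))
  expect_false("boundary" %in% calls$expressed$A)
  expect_false("zero" %in% calls$expressed$A)
})

test_that("call sets are monotone in the threshold", {
  set.seed(42)
  for (rep in 1:10) {
    prof <- matrix(rexp(60), nrow = 12,
                   dimnames = list(sprintf("g%02d", 1:12), LETTERS[1:5]))
    t1 <- runif(1, 0, 1); t2 <- t1 + runif(1, 0, 2)
    lo <- call_expressed(prof, t1)
    hi <- call_expressed(prof, t2)
    for (tis in LETTERS[1:5])
      expect_true(all(hi$expressed[[tis]] %in% lo$expressed[[tis]]))
  }
})

test_that("median-of-ratios size factors match hand-derived values", {
  ident <- matrix(c(3, 7, 2, 3, 7, 2), ncol = 2,
                  dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors_median_of_ratios(ident)), c(1, 1))

  single <- matrix(c(2, 8), nrow = 1, dimnames = list("a", c("s1", "s2")))
  expect_equal(unname(size_factors_median_of_ratios(single)), c(0.5, 2.0))

  # the zero-containing feature is excluded; the remaining ratios are 1
  zf <- matrix(c(0, 3, 5, 3), nrow = 2, dimnames = list(c("z", "k"), c("s1", "s2")))
  expect_equal(unname(size_factors_median_of_ratios(zf)), c(1, 1))

  allz <- matrix(c(0, 1, 1, 0), nrow = 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors_median_of_ratios(allz), "all-positive")
})

test_that("size factors agree with the DESeq2 implementation on random counts", {
  set.seed(101)
  # odd usable-feature count so the ratio median and DESeq2's log-ratio
  # median pick the same element; compare on the unit-geometric-mean scale
  counts <- matrix(rnbinom(606, mu = 50 * rep(runif(6, 0.5, 2), each = 101),
                           size = 5),
                   nrow = 101, dimnames = list(sprintf("g%03d", 1:101),
                                               sprintf("s%d", 1:6)))
  counts[counts == 0] <- 1  # keep every feature usable for both routes
  mine <- size_factors_median_of_ratios(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("normalization is idempotent: renormalized factors are all 1", {
  set.seed(7)
  counts <- em(matrix(rnbinom(80, mu = 40, size = 5) + 1, nrow = 20),
               tissues = rep(c("A", "B"), each = 2), units = "counts")
  norm <- normalize_counts(counts)
  again <- size_factors_median_of_ratios(norm$values)
  expect_equal(unname(again), rep(1, 4), tolerance = 1e-9)
})

test_that("sample similarity has exact metric structure", {
  ident <- em(matrix(c(1, 2, 1, 2), ncol = 2), tissues = c("A", "A"))
  s <- sample_similarity(ident)
  expect_equal(s$distance[1, 2], 0)
  expect_equal(s$correlation[1, 2], 1)

  tri <- em(matrix(c(0, 3, 4, 0), ncol = 2), tissues = c("A", "B"))
  expect_equal(sample_similarity(tri)$distance[1, 2], 5)

  set.seed(5)
  r <- em(matrix(rexp(40), ncol = 4), tissues = c("A", "A", "B", "B"))
  s <- sample_similarity(r)
  expect_equal(s$distance, t(s$distance))
  expect_equal(s$correlation, t(s$correlation))
  expect_equal(unname(diag(s$distance)), rep(0, 4))
  expect_equal(unname(diag(s$correlation)), rep(1, 4))

  const <- em(cbind(c(1, 1, 1), c(1, 2, 3)), tissues = c("A", "B"))
  expect_warning(s <- sample_similarity(const), "constant sample")
  expect_true(all(is.na(s$correlation["s1", ])))
})
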