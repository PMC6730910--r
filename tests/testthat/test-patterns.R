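test_that("random patterns are seeded, balanced and validated", {
  expect_error(random_pattern(0, seed = 1), "positive")
  expect_error(stim_pattern(c(0, 2)), "0 or 1")

  p1 <- random_pattern(1, seed = 7)
  expect_true(p1$bits %in% c(0L, 1L))

  # training-phase size: 384 s at 60 bit/s
  p <- random_pattern(384 * 60, seed = 3)
  expect_length(p$bits, 23040L)
  expect_identical(duration_s(p), 384)
  expect_identical(random_pattern(384 * 60, seed = 3)$bits, p$bits)

  # binomial bound on the fraction of ones: |phat - 0.5| < 3*sqrt(0.25/n)
  for (s in 1:5) {
    p <- random_pattern(10000, seed = s)
    expect_lt(abs(mean(p$bits) - 0.5), 3 * sqrt(0.25 / 10000))
  }
})

test_that("pattern sets have equal-length, uniquely labelled members", {
  ps <- random_pattern_set(32, 120, seed = 11)
  expect_length(ps, 32L)
  m <- pattern_matrix(ps)
  expect_equal(dim(m), c(32L, 120L))
  expect_gt(nrow(unique(m)), 31L) # all distinct
  ids <- vapply(ps$patterns, `[[`, character(1), "id")
  expect_identical(ids, sort(ids)) # lexicographic layout
  expect_false(anyDuplicated(ids) > 0)

  expect_error(random_pattern_set(1, 60, seed = 1), ">= 2")
  deg <- random_pattern_set(2, 1, seed = 1) # degenerate but valid
  expect_length(deg$patterns[[1]]$bits, 1L)
})

test_that("greedy decorrelation lowers the worst pairwise correlation on average", {
  worst <- function(seed, dec) {
    max_pairwise_correlation(
      random_pattern_set(2, 60, seed = seed, decorrelate = dec, pool_size = 200)
    )
  }
  seeds <- 1:20
  plain <- vapply(seeds, worst, numeric(1), dec = FALSE)
  decor <- vapply(seeds, worst, numeric(1), dec = TRUE)
  expect_lt(mean(decor), mean(plain))
})

test_that("pattern files round-trip and reject malformed input", {
  ps <- random_pattern_set(5, 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_patterns(ps, path)
  back <- read_patterns(path)
  expect_identical(pattern_matrix(back), pattern_matrix(ps))
  expect_identical(
    vapply(back$patterns, `[[`, character(1), "id"),
    vapply(ps$patterns, `[[`, character(1), "id")
  )

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("T01\t0101", "T02\t0121"), bad)
  expect_error(read_patterns(bad), "line 2, column 7")

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_warning(out <- read_patterns(empty), "empty")
  expect_length(out, 0L)
})
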