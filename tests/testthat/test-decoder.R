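test_that("pattern correlation behaves like Pearson r on code prefixes", {
  p <- random_pattern(120, seed = 1)
  expect_equal(pattern_correlation(as.numeric(p$bits), p), 1)
  expect_equal(pattern_correlation(as.numeric(1 - p$bits), p), -1)
  set.seed(2)
  expect_lt(abs(pattern_correlation(runif(120), p)), 0.3) # null r at n = 120
  expect_true(is.na(pattern_correlation(runif(10), stim_pattern(rep(1, 10)))))
  expect_error(pattern_correlation(1:5, p), "equal length")
  expect_error(pattern_correlation(c(1, 0), stim_pattern(c(1, 0))), "at least 3")
})

test_that("synchronous classification picks the most correlated target", {
  ps <- random_pattern_set(16, 60, seed = 3)
  k <- 5L
  dec <- classify_synchronous(as.numeric(ps$patterns[[k]]$bits), ps)
  expect_identical(dec$target_index, k)

  # tie between two identical candidates resolves to the lower index
  twin <- pattern_set(list(
    stim_pattern(ps$patterns[[1]]$bits, id = "A"),
    stim_pattern(ps$patterns[[1]]$bits, id = "B")
  ))
  tie <- classify_synchronous(as.numeric(ps$patterns[[1]]$bits), twin)
  expect_identical(tie$target_index, 1L)

  expect_error(classify_synchronous(runif(60), pattern_set(list())), "empty")
})

test_that("synchronous classification equals the brute-force argmax", {
  brute <- function(probs, ps) {
    rs <- vapply(ps$patterns, function(p) {
      suppressWarnings(cor(probs, p$bits[seq_along(probs)]))
    }, numeric(1))
    which.max(rs)
  }
  set.seed(4)
  for (i in 1:20) {
    ps <- random_pattern_set(sample(2:32, 1), 48, seed = 100 + i)
    probs <- runif(48)
    expect_identical(classify_synchronous(probs, ps)$target_index,
                     brute(probs, ps))
  }
})

test_that("correlation p-values follow the one-sided t-transform", {
  expect_equal(correlation_pvalue(0, 12), 0.5)
  expect_lt(correlation_pvalue(0.5, 120), correlation_pvalue(0.5, 12))
  # numerical t-tail oracle at (r = 0.5, n = 12): t = 0.5 * sqrt(10 / 0.75)
  t0 <- 0.5 * sqrt(10 / 0.75)
  oracle <- stats::integrate(function(x) stats::dt(x, df = 10), t0, Inf,
                             rel.tol = 1e-12)$value
  expect_equal(correlation_pvalue(0.5, 12), oracle, tolerance = 1e-12)
  expect_error(correlation_pvalue(0.5, 2), "at least 3")
  expect_error(correlation_pvalue(1, 12), "below 1")
})

test_that("asynchronous classification stops at the first p-value crossing", {
  ps <- random_pattern_set(8, 240, seed = 5)
  k <- 3L
  # exact prediction: r = 1 from the first evaluation at min_bits
  dec <- classify_asynchronous(as.numeric(ps$patterns[[k]]$bits), ps,
                               p_threshold = 1e-4, min_bits = 12L)
  expect_identical(dec$target_index, k)
  expect_equal(dec$trial_duration_s, 12 / 60)

  # noisy prediction: stopping time matches an independent per-bit scan
  set.seed(6)
  probs <- 0.6 * ps$patterns[[k]]$bits + 0.4 * runif(240)
  dec2 <- classify_asynchronous(probs, ps, p_threshold = 1e-6, min_bits = 12L)
  oracle_stop <- NA
  for (nb in 12:240) {
    pv <- vapply(ps$patterns, function(p) {
      r <- suppressWarnings(cor(probs[1:nb], p$bits[1:nb]))
      if (is.na(r)) return(NA_real_)
      stats::pt(r * sqrt((nb - 2) / (1 - r^2)), df = nb - 2, lower.tail = FALSE)
    }, numeric(1))
    if (any(pv < 1e-6, na.rm = TRUE)) { oracle_stop <- nb; break }
  }
  expect_equal(dec2$trial_duration_s, oracle_stop / 60)
  expect_identical(dec2$target_index, k)

  # threshold 1 selects at the very first evaluation (degenerate)
  deg <- classify_asynchronous(runif(240), ps, p_threshold = 1, min_bits = 12L)
  expect_equal(deg$trial_duration_s, 12 / 60)
})

test_that("independent streams stay in the non-control state", {
  ps <- random_pattern_set(32, 600, seed = 7)
  set.seed(8)
  outcomes <- vapply(1:20, function(i) {
    dec <- classify_asynchronous(runif(600), ps, p_threshold = 1e-6,
                                 max_trial_s = 10)
    is.na(dec$target_index)
  }, logical(1))
  expect_gte(mean(outcomes), 0.95)
})

test_that("large-set discrimination ranks the true code correctly", {
  p <- random_pattern(120, seed = 9)
  hit <- discriminate_large_set(as.numeric(p$bits), p, 1000, seed = 10)
  expect_true(hit$is_correct)
  expect_identical(hit$rank, 1L)
  expect_equal(hit$r_true, 1)

  # chance-level predictions: correct with probability ~ 1/n_candidates,
  # ranks roughly uniform
  set.seed(11)
  res <- t(vapply(1:200, function(i) {
    out <- discriminate_large_set(runif(120), p, 100, seed = 1000 + i)
    c(correct = out$is_correct, rank = out$rank)
  }, c(correct = 0, rank = 0)))
  expect_lte(mean(res[, "correct"]), 0.06)
  expect_gt(mean(res[, "rank"]), 30)
  expect_lt(mean(res[, "rank"]), 70)
})

test_that("discrimination accuracy decreases with the candidate-set size", {
  p_list <- lapply(1:200, function(i) random_pattern(120, seed = 2000 + i))
  set.seed(12)
  preds <- lapply(p_list, function(p) p$bits + rnorm(120, sd = 1.2))
  accs <- vapply(c(100L, 1000L, 10000L), function(nc) {
    mean(discriminate_set(preds, p_list, nc, seed = 13)$is_correct)
  }, numeric(1))
  expect_gt(accs[1], accs[2])
  expect_gt(accs[2], accs[3])
})

test_that("batched and single-trial discrimination agree on shared candidates", {
  p <- random_pattern(120, seed = 14)
  set.seed(15)
  pred <- p$bits + rnorm(120, sd = 1)
  single <- discriminate_large_set(pred, p, 500, seed = 16, block_size = 100L)
  batch <- discriminate_set(list(pred), list(p), 500, seed = 16, block_size = 100L)
  expect_identical(single$rank, batch$rank[1])
  expect_identical(single$is_correct, batch$is_correct[1])
})
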