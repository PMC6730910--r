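noise_windows <- function(n_samples, seed, labels_seed = NULL) {
  # pure-noise recording (full-rank design) with random labels
  set.seed(seed)
  rec <- matrix(rnorm(32 * n_samples), 32, n_samples)
  w <- extract_windows(rec)
  if (!is.null(labels_seed)) {
    set.seed(labels_seed)
    w$labels <- sample(0:1, length(w), replace = TRUE)
  }
  w
}

test_that("ridge with a vanishing penalty interpolates separable training data", {
  w <- noise_windows(500, seed = 1, labels_seed = 2) # 351 windows, 4800 features
  m <- train_ridge(w, lambda = 1e-6)
  pred <- predict(m, w)
  expect_identical(as.integer(pred >= 0.5), w$labels)
  expect_lt(max(abs(pred - w$labels)), 1e-2)
})

test_that("a huge ridge penalty shrinks weights and predictions to the label mean", {
  w <- noise_windows(400, seed = 3, labels_seed = 4)
  m <- train_ridge(w, lambda = 1e12)
  expect_lt(max(abs(m$weights)), 1e-6)
  expect_equal(mean(predict(m, w)), mean(w$labels), tolerance = 1e-3)
})

test_that("ridge training validates labels and shapes", {
  w <- noise_windows(300, seed = 5)
  expect_error(train_ridge(w), "labelled")
  w$labels <- rep(1L, length(w))
  expect_error(train_ridge(w), "single class")
  w$labels[1] <- 0L
  expect_error(train_ridge(w, lambda = -1), ">= 0")
})

test_that("noiseless simulated training recovers the code nearly perfectly", {
  pred <- pred5()
  expect_gte(bit_accuracy(pred, test5()$pattern), 0.98)
})

test_that("the spatially filtered ridge variant also decodes noiseless data", {
  m <- train_ridge(train10()$windows, spatial_filter = TRUE)
  expect_length(m$spatial_filter, 32L)
  pred <- suppressWarnings(aggregate_bits(predict(m, test5()$windows)))
  expect_gte(bit_accuracy(pred, test5()$pattern), 0.9)
})

test_that("trained models round-trip through the model container", {
  m <- ridge10()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$intercept, m$intercept)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$class, "cvep_ridge")
})

test_that("analytic CNN gradients match finite differences", {
  set.seed(42)
  B <- 12L
  X <- array(rnorm(150 * 32 * B), c(150, 32, B))
  y <- sample(0:1, B, replace = TRUE)
  params <- cvep:::cnn_init_params()
  mask <- matrix(sample(c(0, 2), 296 * B, replace = TRUE), 296, B)
  g <- cvep:::cnn_train_batch(X, y, params, mask)$grads
  h <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (cvep:::cnn_train_batch(X, y, up, mask)$loss -
             cvep:::cnn_train_batch(X, y, dn, mask)$loss) / (2 * h)
      an <- g[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 0.02)
    }
  }
})

test_that("CNN output is a two-class softmax probability", {
  fit <- train_cnn(train10()$windows, epochs = 1L, batch_size = 256L, seed = 1)
  w <- test5()$windows
  sub <- list(data = w$data[, , 1:50, drop = FALSE],
              start_indices = w$start_indices[1:50], labels = NULL)
  class(sub) <- "window_set"
  pm <- predict(fit$model, sub, type = "matrix")
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(rowSums(pm), rep(1, 50), tolerance = 1e-6)
  # stateless prediction: identical windows give identical outputs
  sub2 <- sub
  sub2$data <- sub$data[, , c(1, 1, 2), drop = FALSE]
  p2 <- predict(fit$model, sub2)
  expect_identical(p2[1], p2[2])
})

test_that("CNN training is reproducible and reports the best validation epoch", {
  w <- train10()$windows
  f1 <- train_cnn(w, epochs = 2L, seed = 7)
  f2 <- train_cnn(w, epochs = 2L, seed = 7)
  expect_identical(f1$report$history, f2$report$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$report$selected_epoch, which.max(f1$report$history$val_acc))
  # parameter count is fixed by the architecture, not the data size
  expect_identical(
    sum(vapply(f1$model$params, length, integer(1))),
    sum(vapply(train_cnn(noise_windows(1000, 9, 10), epochs = 1L,
                         batch_size = 128L, seed = 1)$model$params,
               length, integer(1)))
  )
})

test_that("CNN at chance on shuffled labels; errors on too little data", {
  p <- random_pattern(1020L, seed = 31) # 17 s -> > 10000 windows
  rec <- simulate_eeg(p, noise = noise_model(snr_db = 0), seed = 32)
  w <- extract_windows(rec, p)
  set.seed(33)
  w$labels <- sample(w$labels)
  fit <- train_cnn(w, epochs = 2L, seed = 34)
  val_acc <- max(fit$report$history$val_acc)
  expect_gt(val_acc, 0.45)
  expect_lt(val_acc, 0.55)

  small <- noise_windows(200, seed = 35, labels_seed = 36)
  expect_error(train_cnn(small, batch_size = 256L), "batch")
})
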