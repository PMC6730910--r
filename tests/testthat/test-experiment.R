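test_that("the training phase is reproducible and returns a usable model", {
  cfg <- smoke_cfg()
  tr1 <- run_training_phase(cfg, seed = 1)
  expect_identical(tr1$model$weights, smoke_model()$weights)
  expect_identical(tr1$n_bits, 600L)
  expect_s3_class(tr1$model, "cvep_ridge")
})

test_that("pattern prediction on noiseless data is near perfect and self-consistent", {
  cfg <- smoke_cfg()
  model <- smoke_model()
  tab <- run_pattern_prediction(cfg, model, seed = 2)
  expect_identical(tab$run, c("1", "2", "mean"))
  body <- tab[tab$run != "mean", ]
  expect_gte(min(body$acc), 0.99)
  expect_equal(body$itr_bpm, itr(body$acc, 2, 1 / 60)) # internal consistency
  expect_equal(tab$acc[tab$run == "mean"], aggregate_mean(body$acc))
  # byte-for-byte reproducibility of the emitted table
  expect_identical(tab, run_pattern_prediction(cfg, model, seed = 2))
})

test_that("an untrained random-weight model predicts at chance", {
  cfg <- smoke_cfg()
  set.seed(42)
  rand_model <- structure(
    list(weights = rnorm(4800, sd = 1e-4), intercept = 0.5, lambda = 1,
         spatial_filter = NULL),
    class = "cvep_ridge"
  )
  tab <- run_pattern_prediction(cfg, rand_model, seed = 3)
  acc <- tab$acc[tab$run == "mean"]
  expect_gt(acc, 0.42)
  expect_lt(acc, 0.58)
})

test_that("synchronous spelling on noiseless data selects every target", {
  cfg <- smoke_cfg()
  model <- smoke_model()
  tab <- run_synchronous_spelling(cfg, model, seed = 4)
  body <- tab[tab$run != "mean", ]
  expect_equal(body$acc, 1)
  expect_equal(body$itr_bpm, itr(1, 8, 1.5))
})

test_that("asynchronous spelling stops early and reports consistent rates", {
  cfg <- smoke_cfg()
  model <- smoke_model()
  tab <- run_asynchronous_spelling(cfg, model, seed = 5)
  body <- tab[tab$run != "mean", ]
  expect_equal(body$acc, 1)
  expect_lt(body$mean_trial_s, 1.5) # fast stopping on clean data
  expect_equal(body$clm_lpm, clm(body$acc, body$mean_trial_s))
  expect_equal(body$utr_bpm, utr(body$acc, 8, body$mean_trial_s))
  expect_equal(body$n_noncontrol, 0)
})

test_that("big-set discrimination on noiseless data finds the true code", {
  cfg <- smoke_cfg()
  model <- smoke_model()
  tab <- run_bigset_discrimination(cfg, model, seed = 6)
  body <- tab[tab$run != "mean", ]
  expect_equal(body$acc, 1)
  expect_equal(body$mean_rank, 1)
  expect_equal(body$itr_bpm, itr(1, 1000, 2.5))
})

test_that("accuracy is monotone in simulator SNR", {
  accs <- vapply(c(6, -6, -20), function(snr) {
    cfg <- smoke_cfg(snr_db = snr)
    cfg$pattern$runs <- 1L
    model <- run_training_phase(cfg, seed = 7)$model
    tab <- run_pattern_prediction(cfg, model, seed = 8)
    tab$acc[tab$run == "mean"]
  }, numeric(1))
  expect_gte(accs[1], accs[2])
  expect_gte(accs[2], accs[3])
})

test_that("result tables are written with a JSON sidecar", {
  cfg <- smoke_cfg()
  tab <- data.frame(run = c("1", "mean"), acc = c(1, 1), itr_bpm = c(45, 45))
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_table(tab, path, cfg = cfg, seed = 99)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- utils::read.csv(path, colClasses = c(run = "character"))
  expect_equal(back$acc, tab$acc)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 99)
  expect_equal(side$config$model, "ridge")
})
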