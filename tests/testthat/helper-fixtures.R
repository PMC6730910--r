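# Shared simulated fixtures, built once per test run. The noiseless
# 10 s training set and its ridge fit are reused across several files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

train10 <- function() {
  fixture("train10", function() {
    p <- random_pattern(600L, seed = 101)
    rec <- simulate_eeg(p, seed = 102)
    list(pattern = p, rec = rec, windows = extract_windows(rec, p))
  })
}

ridge10 <- function() {
  fixture("ridge10", function() train_ridge(train10()$windows))
}

test5 <- function() {
  fixture("test5", function() {
    p <- random_pattern(300L, seed = 103)
    rec <- simulate_eeg(p, seed = 104)
    list(pattern = p, rec = rec, windows = extract_windows(rec))
  })
}

# bit prediction of the noiseless test run under the noiseless ridge fit
pred5 <- function() {
  fixture("pred5", function() {
    suppressWarnings(aggregate_bits(predict(ridge10(), test5()$windows)))
  })
}

# small experiment configuration shared by the protocol tests
smoke_cfg <- function(...) {
  experiment_config(
    model = "ridge", training_seconds = 10,
    pattern = list(runs = 2L, trials_per_run = 4L),
    sync = list(runs = 1L, n_targets = 8L),
    async = list(runs = 1L, trials_per_run = 8L, n_targets = 8L,
                 max_trial_s = 4),
    bigset = list(trials = 8L, n_candidates = 1000L, block_size = 500L),
    ...
  )
}

smoke_model <- function() {
  fixture("smoke_model", function() run_training_phase(smoke_cfg(), seed = 1)$model)
}
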