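test_that("default kernel is unit energy, 150 taps, tapered at both ends", {
  k <- vep_kernel()
  expect_length(k$taps, 150L)
  expect_equal(sum(k$taps^2), 1, tolerance = 1e-12)
  peak <- max(abs(k$taps))
  expect_lt(abs(k$taps[1]), 0.05 * peak)
  expect_lt(abs(k$taps[150]), 0.05 * peak)
  expect_identical(k$taps, vep_kernel()$taps) # deterministic
})

test_that("noiseless simulation is the kernel superposition, spatially mixed", {
  # single 1-bit followed by zeros, unit mixing on channel 1: channel 1 is
  # the convolution of the 10-sample frame with the kernel; all others zero
  k <- vep_kernel()
  pat <- stim_pattern(c(1, rep(0, 29)))
  mix <- c(1, rep(0, 31))
  rec <- simulate_eeg(pat, mixing = mix, seed = 1, padding_ms = 0)
  stim <- rep(c(1, rep(0, 29)), each = 10)
  expected <- vapply(seq_along(stim), function(t) {
    taps_idx <- seq_len(min(t, 150))
    sum(k$taps[taps_idx] * stim[t - taps_idx + 1])
  }, numeric(1))
  expect_equal(rec$data[1, ], expected, tolerance = 1e-10)
  expect_equal(max(abs(rec$data[-1, ])), 0)

  # all-zero pattern, noiseless -> all-zero recording
  rec0 <- simulate_eeg(stim_pattern(rep(0, 30)), seed = 1, padding_ms = 0)
  expect_equal(max(abs(rec0$data)), 0)
})

test_that("recording geometry and reproducibility hold", {
  p <- random_pattern(60, seed = 5)
  rec <- simulate_eeg(p, noise = noise_model(snr_db = 3), seed = 9)
  expect_equal(dim(rec$data), c(32L, 60 * 10 + 150))
  expect_equal(rec$fs, 600L)
  expect_equal(rec$padding_samples, 150L)
  rec2 <- simulate_eeg(p, noise = noise_model(snr_db = 3), seed = 9)
  expect_identical(rec$data, rec2$data)
  expect_error(simulate_eeg(p, mixing = rep(1, 5)), "32")
})

test_that("realised SNR matches the configured level", {
  p <- random_pattern(300, seed = 2)
  for (target in c(0, -6)) {
    rec <- simulate_eeg(p, noise = noise_model(snr_db = target), seed = 3)
    expect_lt(abs(estimate_snr(rec, rec$clean) - target), 0.5)
  }
  rec <- simulate_eeg(p, seed = 3) # noiseless sentinel
  expect_identical(estimate_snr(rec, rec$clean), Inf)
  expect_equal(estimate_snr(rec$data + rec$data, rec$data), 0) # noise = clean
  expect_error(estimate_snr(rec$data, rec$data[, 1:10]), "shape")
})

test_that("the simulator is linear in the kernel when the nonlinearity is off", {
  mk <- function(taps) structure(list(taps = taps, description = "test"),
                                 class = "vep_kernel")
  t <- (0:149) / 600
  a <- mk(exp(-(t - 0.08)^2 / (2 * 0.01^2)))
  b <- mk(-0.5 * exp(-(t - 0.18)^2 / (2 * 0.02^2)))
  ab <- mk(a$taps + b$taps)
  p <- random_pattern(120, seed = 4)
  ra <- simulate_eeg(p, kernel = a, seed = 6)
  rb <- simulate_eeg(p, kernel = b, seed = 6)
  rab <- simulate_eeg(p, kernel = ab, seed = 6)
  expect_equal(rab$data, ra$data + rb$data, tolerance = 1e-10)

  # saturation breaks additivity
  nl <- noise_model(nonlinearity = "saturating", gain = 5)
  sa <- simulate_eeg(p, kernel = a, noise = nl, seed = 6)
  sb <- simulate_eeg(p, kernel = b, noise = nl, seed = 6)
  sab <- simulate_eeg(p, kernel = ab, noise = nl, seed = 6)
  expect_gt(max(abs(sab$clean - (sa$clean + sb$clean))), 1e-3)
})

test_that("recordings round-trip through text and binary containers", {
  p <- random_pattern(24, seed = 8, id = "T01")
  rec <- simulate_eeg(p, noise = noise_model(snr_db = 0), seed = 10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_recording(rec, tsv)
  back <- read_eeg_recording(tsv)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$n_bits, rec$n_bits)
  expect_identical(back$pattern_id, "T01")

  rds <- withr::local_tempfile(fileext = ".rds")
  write_eeg_recording(rec, rds, format = "rds")
  expect_identical(read_eeg_recording(rds, format = "rds")$data, rec$data)
})
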