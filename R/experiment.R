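#' Configuration for simulated online experiments
#'
#' Bundles every setting of the end-to-end protocols: the training phase
#' (default 384 s of random stimulation, i.e. 23040 bits), pattern
#' prediction runs (7 runs of 32 two-second trials of fully random codes),
#' synchronous spelling (7 runs over a 32-target layout in lexicographic
#' order, 1 s trials + 0.5 s inter-trial), asynchronous self-paced spelling
#' (6 runs of 32 trials, p-value threshold stopping), and massive
#' candidate-set discrimination (2 s trials against `n_candidates` codes).
#' Simulator settings (SNR, noise colour, nonlinearity, kernel, spatial
#' mixing) and the model choice are shared by all protocols.
#'
#' @param model `"ridge"` or `"cnn"`.
#' @param training_seconds Length of the training stimulation in seconds.
#' @param snr_db,pink_fraction,nonlinearity,gain Simulator noise settings,
#'   see [noise_model()].
#' @param kernel,mixing Simulator response settings, see [vep_kernel()] and
#'   [occipital_mixing()].
#' @param lambda Ridge penalty (ridge model).
#' @param cnn List of [train_cnn()] hyperparameters (cnn model).
#' @param pattern,sync,async,bigset Per-protocol settings; any element given
#'   here overrides the default listed above.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("ridge", "cnn"),
                              training_seconds = 384,
                              snr_db = Inf, pink_fraction = 0.8,
                              nonlinearity = "none", gain = 3,
                              kernel = vep_kernel(),
                              mixing = occipital_mixing(),
                              lambda = 1,
                              cnn = list(),
                              pattern = list(), sync = list(),
                              async = list(), bigset = list()) {
  model <- match.arg(model)
  merge_defaults <- function(given, defaults) {
    stopifnot(all(names(given) %in% names(defaults)))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    model = model,
    training_seconds = training_seconds,
    noise = noise_model(snr_db = snr_db, pink_fraction = pink_fraction,
                        nonlinearity = nonlinearity, gain = gain),
    kernel = kernel, mixing = mixing, lambda = lambda,
    cnn = merge_defaults(cnn, list(
      val_fraction = 1 / 6, epochs = 25L, batch_size = 256L,
      learning_rate = 0.001, dropout = 0.5
    )),
    pattern = merge_defaults(pattern, list(
      runs = 7L, trials_per_run = 32L, trial_s = 2,
      bit_T_s = 1 / 60
    )),
    sync = merge_defaults(sync, list(
      runs = 7L, n_targets = 32L, trial_s = 1, inter_trial_s = 0.5,
      decorrelate = FALSE
    )),
    async = merge_defaults(async, list(
      runs = 6L, trials_per_run = 32L, n_targets = 32L,
      p_threshold = 1e-4, inter_trial_s = 0.5, max_trial_s = 10,
      min_bits = 12L, noncontrol = "abstain", decorrelate = FALSE
    )),
    bigset = merge_defaults(bigset, list(
      trials = 32L, trial_s = 2, inter_trial_s = 0.5,
      n_candidates = 500000L, block_size = 100000L
    ))
  )
  structure(cfg, class = "experiment_config")
}

# Deterministic stream of sub-seeds so that each stochastic stage of an
# experiment gets its own reproducible seed from the single top-level one.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

sim_recording <- function(cfg, pat, seed) {
  simulate_eeg(pat, kernel = cfg$kernel, mixing = cfg$mixing,
               noise = cfg$noise, seed = seed)
}

#' Run the training phase
#'
#' Generates the training stimulation code (`training_seconds * 60` random
#' bits), simulates the concurrent EEG, extracts the labelled sliding
#' windows and trains the configured backward model.
#'
#' @param cfg An [experiment_config()].
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @return List with `model`, `report` (`NULL` for ridge) and `n_bits`.
#' @export
run_training_phase <- function(cfg, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- derive_seeds(seed, 3L)
  n_bits <- as.integer(round(cfg$training_seconds * FRAME_RATE))
  pat <- random_pattern(n_bits, seed = seeds[1], id = "train")
  rec <- sim_recording(cfg, pat, seeds[2])
  w <- extract_windows(rec, pat)
  if (cfg$model == "ridge") {
    list(model = train_ridge(w, lambda = cfg$lambda), report = NULL, n_bits = n_bits)
  } else {
    fit <- train_cnn(w,
      val_fraction = cfg$cnn$val_fraction, epochs = cfg$cnn$epochs,
      batch_size = cfg$cnn$batch_size, learning_rate = cfg$cnn$learning_rate,
      dropout = cfg$cnn$dropout, seed = seeds[3]
    )
    list(model = fit$model, report = fit$report, n_bits = n_bits)
  }
}

predict_bits <- function(cfg, model, pat, seed) {
  rec <- sim_recording(cfg, pat, seed)
  w <- extract_windows(rec)
  suppressWarnings(aggregate_bits(predict(model, w)))
}

#' Pattern prediction protocol (passive BCI)
#'
#' Each trial presents a fully random code and every bit of it is predicted
#' from the following 250 ms of EEG; one "trial" of the passive scenario is
#' one bit. Reports per-run bit accuracy and the per-bit ITR with `N = 2`
#' and the configured `T` (1/60 s by default).
#'
#' @param cfg An [experiment_config()].
#' @param model A trained backward model.
#' @param seed Integer seed.
#' @return A result table (`data.frame`) with one row per run and a final
#'   mean row; columns `run`, `acc`, `itr_bpm`.
#' @export
run_pattern_prediction <- function(cfg, model, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  p <- cfg$pattern
  n_bits <- as.integer(round(p$trial_s * FRAME_RATE))
  seeds <- derive_seeds(seed, 2L * p$runs * p$trials_per_run)
  i <- 0L
  rows <- lapply(seq_len(p$runs), function(run) {
    correct <- 0L; total <- 0L
    for (tr in seq_len(p$trials_per_run)) {
      i <<- i + 2L
      pat <- random_pattern(n_bits, seed = seeds[i - 1L])
      pred <- predict_bits(cfg, model, pat, seeds[i])
      correct <- correct + sum(pred$bits == pat$bits)
      total <- total + n_bits
    }
    acc <- correct / total
    data.frame(run = as.character(run), acc = acc,
               itr_bpm = itr(acc, 2, p$bit_T_s))
  })
  finish_table(do.call(rbind, rows))
}

#' Synchronous spelling protocol
#'
#' Fixed-length trials over a multi-target layout: each run visits every
#' target in lexicographic order, the attended target's code drives the
#' simulated EEG, and the correlation classifier selects a target at trial
#' end. ITR uses `N` targets and `T = trial_s + inter_trial_s`.
#'
#' @inheritParams run_pattern_prediction
#' @return Result table with columns `run`, `acc`, `itr_bpm` and a mean row.
#' @export
run_synchronous_spelling <- function(cfg, model, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  s <- cfg$sync
  n_bits <- as.integer(round(s$trial_s * FRAME_RATE))
  seeds <- derive_seeds(seed, 1L + s$runs * s$n_targets)
  targets <- random_pattern_set(s$n_targets, n_bits, seed = seeds[1],
                                decorrelate = s$decorrelate)
  T_sel <- s$trial_s + s$inter_trial_s
  i <- 1L
  rows <- lapply(seq_len(s$runs), function(run) {
    correct <- 0L
    for (k in seq_len(s$n_targets)) { # lexicographic target order
      i <<- i + 1L
      pred <- predict_bits(cfg, model, targets$patterns[[k]], seeds[i])
      dec <- classify_synchronous(pred, targets)
      if (dec$target_index == k) correct <- correct + 1L
    }
    acc <- correct / s$n_targets
    data.frame(run = as.character(run), acc = acc,
               itr_bpm = itr(acc, s$n_targets, T_sel))
  })
  finish_table(do.call(rbind, rows))
}

#' Asynchronous self-paced spelling protocol
#'
#' Variable-length trials: stimulation continues until a candidate's
#' correlation p-value crosses the configured threshold (or the cap is
#' reached, a non-control outcome). Per run the table reports accuracy,
#' mean trial duration (including the inter-trial time), ITR, CLM and UTR,
#' all computed from that run's accuracy and mean duration. Non-control
#' outcomes are counted as abstentions by default — logged, reported in
#' `n_noncontrol`, excluded from the accuracy denominator — or as errors
#' when `async$noncontrol = "error"`.
#'
#' @inheritParams run_pattern_prediction
#' @return Result table with columns `run`, `acc`, `itr_bpm`, `clm_lpm`,
#'   `utr_bpm`, `mean_trial_s`, `n_noncontrol` and a mean row.
#' @export
run_asynchronous_spelling <- function(cfg, model, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  a <- cfg$async
  max_bits <- as.integer(round(a$max_trial_s * FRAME_RATE))
  seeds <- derive_seeds(seed, 1L + a$runs * a$trials_per_run)
  targets <- random_pattern_set(a$n_targets, max_bits, seed = seeds[1],
                                decorrelate = a$decorrelate)
  i <- 1L
  rows <- lapply(seq_len(a$runs), function(run) {
    correct <- 0L; decided <- 0L; noncontrol <- 0L
    durations <- numeric(0)
    for (tr in seq_len(a$trials_per_run)) {
      k <- (tr - 1L) %% a$n_targets + 1L # lexicographic
      i <<- i + 1L
      pred <- predict_bits(cfg, model, targets$patterns[[k]], seeds[i])
      dec <- classify_asynchronous(pred$probs, targets,
                                   p_threshold = a$p_threshold,
                                   max_trial_s = a$max_trial_s,
                                   min_bits = a$min_bits)
      durations <- c(durations, dec$trial_duration_s + a$inter_trial_s)
      if (is.na(dec$target_index)) {
        noncontrol <- noncontrol + 1L
        if (a$noncontrol == "error") decided <- decided + 1L
      } else {
        decided <- decided + 1L
        if (dec$target_index == k) correct <- correct + 1L
      }
    }
    acc <- if (decided > 0) correct / decided else NA_real_
    mean_T <- mean(durations)
    data.frame(run = as.character(run), acc = acc,
               itr_bpm = if (is.na(acc)) NA_real_ else itr(acc, a$n_targets, mean_T),
               clm_lpm = if (is.na(acc)) NA_real_ else clm(acc, mean_T),
               utr_bpm = if (is.na(acc)) NA_real_ else {
                 suppressWarnings(utr(acc, a$n_targets, mean_T))
               },
               mean_trial_s = mean_T, n_noncontrol = noncontrol)
  })
  finish_table(do.call(rbind, rows))
}

#' Massive candidate-set discrimination protocol
#'
#' Each trial presents one random code; the prediction is then asked to
#' pick that code out of `n_candidates` candidates. The distractor codes
#' are drawn once per protocol run and shared by all trials — they play
#' the role of the other `n_candidates - 1` targets of a (virtual) layout —
#' and are streamed in blocks ([discriminate_set()]) so memory stays
#' bounded. ITR uses `N = n_candidates` and `T = trial_s + inter_trial_s`.
#'
#' @inheritParams run_pattern_prediction
#' @return Result table with columns `run`, `acc`, `itr_bpm`,
#'   `mean_rank` and a mean row.
#' @export
run_bigset_discrimination <- function(cfg, model, seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  b <- cfg$bigset
  n_bits <- as.integer(round(b$trial_s * FRAME_RATE))
  seeds <- derive_seeds(seed, 2L * b$trials + 1L)
  pats <- vector("list", b$trials)
  preds <- vector("list", b$trials)
  for (tr in seq_len(b$trials)) {
    pats[[tr]] <- random_pattern(n_bits, seed = seeds[2L * tr - 1L])
    preds[[tr]] <- predict_bits(cfg, model, pats[[tr]], seeds[2L * tr])
  }
  res <- discriminate_set(preds, pats, b$n_candidates,
                          seed = seeds[2L * b$trials + 1L],
                          block_size = b$block_size)
  acc <- mean(res$is_correct)
  finish_table(data.frame(
    run = "1", acc = acc,
    itr_bpm = itr(acc, b$n_candidates, b$trial_s + b$inter_trial_s),
    mean_rank = mean(res$rank)
  ))
}

# Append the mean row; every emitted table satisfies
# mean row == aggregate_mean of each numeric column.
finish_table <- function(df) {
  mean_row <- df[1, , drop = FALSE]
  mean_row[[1]] <- "mean"
  for (j in seq_along(df)[-1]) {
    mean_row[[j]] <- if (is.numeric(df[[j]])) aggregate_mean(df[[j]]) else NA
  }
  out <- rbind(df, mean_row)
  rownames(out) <- NULL
  out
}

#' Write a result table with a JSON sidecar
#'
#' Writes the table as CSV and, next to it, `<path>.json` recording the
#' configuration and seed that produced it, for auditability.
#'
#' @param tab A result table from one of the `run_*` functions.
#' @param path CSV output path.
#' @param cfg The [experiment_config()] used (optional).
#' @param seed The seed used (optional).
#' @export
write_result_table <- function(tab, path, cfg = NULL, seed = NULL) {
  utils::write.csv(tab, path, row.names = FALSE)
  sidecar <- list(
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config = serialize_config(cfg)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

serialize_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  out <- unclass(cfg)
  out$kernel <- cfg$kernel$description
  out$mixing <- as.list(cfg$mixing)
  out$noise <- unclass(cfg$noise)
  out
}
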