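#' Slide 250 ms windows sample-wise over a recording
#'
#' The backward models predict the stimulus bit shown at a given frame from
#' the *following* 250 ms of EEG, so a recording of `n_samples` samples
#' yields `n_samples - 149` overlapping windows of 150 samples x 32
#' channels, one starting at every sample. The window starting at sample
#' `10 * i` (0-based) is labelled with bit `i` of the driving pattern; the
#' nine windows starting inside frame `i` carry the same label at the
#' following sample offsets. Windows that begin after the last pattern bit
#' (inside the padding) get an `NA` label.
#'
#' @param recording An `eeg_recording` (or a channels x samples matrix).
#' @param pattern Optional [stim_pattern()] providing labels.
#' @return An object of class `window_set`: list with `data` (array
#'   `150 x 32 x n_windows`), `start_indices` (0-based sample starts),
#'   `labels` (integer 0/1 or `NA`, or `NULL` when no pattern is given).
#'   For debugging, a window set can be written to the binary container
#'   with `saveRDS()`.
#' @examples
#' p <- random_pattern(12, seed = 1)
#' rec <- simulate_eeg(p, seed = 1)
#' w <- extract_windows(rec, p)
#' dim(w$data)
#' @export
extract_windows <- function(recording, pattern = NULL) {
  data <- if (inherits(recording, "eeg_recording")) recording$data else recording
  if (nrow(data) != N_CHANNELS) {
    stop(sprintf("recording must have %d channels", N_CHANNELS), call. = FALSE)
  }
  n_samples <- ncol(data)
  if (n_samples < WINDOW_SAMPLES) {
    stop(sprintf("recording has %d samples; at least %d are required for one window",
                 n_samples, WINDOW_SAMPLES), call. = FALSE)
  }
  n_win <- n_samples - WINDOW_SAMPLES + 1L
  arr <- extract_windows_cpp(t(data), WINDOW_SAMPLES) # 150 x 32 x n_win
  starts <- seq_len(n_win) - 1L
  labels <- NULL
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "stim_pattern"))
    bit_idx <- starts %/% SAMPLES_PER_FRAME + 1L
    labels <- ifelse(bit_idx <= length(pattern$bits), pattern$bits[bit_idx], NA_integer_)
  }
  structure(
    list(data = arr, start_indices = starts, labels = labels),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d windows of %d samples x %d channels%s>\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2],
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' @export
length.window_set <- function(x) dim(x$data)[3]

# Feature-major view of a window set: 4800 x n_windows matrix (time-major
# within each channel). A free `dim` change — each window is a contiguous
# slice of the underlying cube — so no data are copied.
feature_matrix <- function(windows) {
  d <- dim(windows$data)
  matrix(windows$data, d[1] * d[2], d[3])
}

#' Aggregate sample-wise predictions to per-bit predictions
#'
#' The models emit one probability per sample (600 per second); each frame
#' of the 60 Hz code spans exactly 10 samples, so consecutive blocks of 10
#' values are averaged into one probability per bit and binarised at the
#' threshold. A probability exactly at the threshold maps to bit 1. A
#' trailing remainder that does not fill a 10-sample block is dropped with a
#' warning.
#'
#' @param probs Numeric vector of sample-wise probabilities in \[0, 1\].
#' @param samples_per_bit Samples per frame (fixed at 10 for 600 Hz / 60 Hz).
#' @param threshold Binarisation threshold (default 0.5).
#' @return An object of class `bit_prediction`: list with `probs` (one per
#'   bit), `bits` (0/1) and `threshold`.
#' @examples
#' aggregate_bits(rep(0.8, 10))
#' @export
aggregate_bits <- function(probs, samples_per_bit = SAMPLES_PER_FRAME,
                           threshold = 0.5) {
  if (length(probs) == 0L) stop("no sample-wise predictions to aggregate", call. = FALSE)
  n_bits <- length(probs) %/% samples_per_bit
  if (n_bits == 0L) {
    stop(sprintf("need at least %d sample-wise predictions for one bit",
                 samples_per_bit), call. = FALSE)
  }
  rem <- length(probs) - n_bits * samples_per_bit
  if (rem > 0L) {
    warning(sprintf("dropping %d trailing sample-wise predictions not filling a %d-sample block",
                    rem, samples_per_bit), call. = FALSE)
    probs <- probs[seq_len(n_bits * samples_per_bit)]
  }
  bit_probs <- colMeans(matrix(probs, samples_per_bit, n_bits))
  structure(
    list(probs = bit_probs, bits = as.integer(bit_probs >= threshold),
         threshold = threshold),
    class = "bit_prediction"
  )
}

#' @export
print.bit_prediction <- function(x, ...) {
  cat(sprintf("<bit_prediction: %d bits, %.1f%% ones (threshold %.2f)>\n",
              length(x$bits), 100 * mean(x$bits), x$threshold))
  invisible(x)
}

#' @export
length.bit_prediction <- function(x) length(x$bits)

#' Fraction of correctly predicted bits
#'
#' @param pred A `bit_prediction` (or plain 0/1 vector).
#' @param truth A [stim_pattern()] (or plain 0/1 vector) of the same length.
#' @return Accuracy in \[0, 1\].
#' @export
bit_accuracy <- function(pred, truth) {
  p <- if (inherits(pred, "bit_prediction")) pred$bits else as.integer(pred)
  t <- if (inherits(truth, "stim_pattern")) truth$bits else as.integer(truth)
  if (length(p) != length(t)) {
    stop(sprintf("prediction has %d bits but truth has %d", length(p), length(t)),
         call. = FALSE)
  }
  mean(p == t)
}
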