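#' Reported benchmark results for the EEG2Code method
#'
#' Per-subject results reported for the EEG2Code method on real EEG,
#' shipped as plain-text tables. They are *inputs*, not outputs, of this
#' package: the metric functions ([itr()], [clm()], [utr()]) can be applied
#' to the printed accuracies and timings to reproduce the printed rates,
#' which is how the metric implementation is validated. Accuracies are in
#' percent, rates in bit/min (CLM in letters/min), times in seconds.
#'
#' @param which One of:
#'   * `"offline"` — per-subject pattern-prediction and synchronous-control
#'     accuracy/ITR for the ridge and CNN variants (ITR conventions:
#'     `N = 2`, `T = 1/60` s per bit; `N = 32`, `T = 1.5` s per selection);
#'   * `"async"` — per-subject asynchronous speller CLM, accuracy, ITR,
#'     mean trial duration (incl. 0.5 s inter-trial) and UTR (`N = 32`,
#'     per-subject `T`);
#'   * `"bigset"` — per-subject accuracy/ITR for discriminating 500,000
#'     candidate codes from 2 s of EEG (`N = 500000`, `T = 2.5` s);
#'   * `"online"` — summary quantities of the online passive-BCI runs
#'     (285 bit predictions per 5 s run, so `T = 5/285` s per bit).
#' @return A `data.frame`.
#' @examples
#' tab <- published_results("offline")
#' itr(tab$pattern_acc_cnn / 100, 2, 1 / 60)
#' @export
published_results <- function(which = c("offline", "async", "bigset", "online")) {
  which <- match.arg(which)
  file <- system.file(
    "extdata",
    sprintf("eeg2code_%s_results.csv", which),
    package = "cvep", mustWork = TRUE
  )
  utils::read.csv(file, stringsAsFactors = FALSE)
}
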