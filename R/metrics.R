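#' BCI performance measures
#'
#' The three standard measures of BCI communication performance, all
#' expressed per minute. `itr()` is the Shannon information transfer rate
#'
#' \deqn{ITR = \left(\log_2 N + P \log_2 P + (1-P)\log_2\frac{1-P}{N-1}\right)\cdot\frac{60}{T}}
#'
#' in bit/min, with the convention `x * log2(x) = 0` at `x = 0` (so `P = 1`
#' gives `60 * log2(N) / T` exactly and `P = 1/N` gives 0). `utr()` is the
#' utility bitrate
#'
#' \deqn{UTR = (2P - 1)\,\log_2(N-1)\cdot\frac{60}{T}}
#'
#' which accounts for correcting errors with a backspace; below chance it
#' is negative and returned as-is with a warning (the floored measure is
#' CLM). At `N = 2` the factor `log2(N - 1)` degenerates and 0 is returned.
#' `clm()` is the net error-free spelling speed in correct letters per
#' minute,
#'
#' \deqn{CLM = 60\,(2P - 1)/T \text{ if } P \ge 0.5, \text{ else } 0.}
#'
#' @param P Accuracy in \[0, 1\].
#' @param N Number of classes (>= 2 for `itr`).
#' @param T_s Time in seconds required for one prediction (> 0), including
#'   any inter-trial time. For per-bit rates both `T_s = 1/60` (one frame)
#'   and `T_s = 5/285` (285 bit predictions per 5 s run, which avoids the
#'   slight bias of 1/60 caused by the 250 ms window) are in use; the
#'   caller selects the convention.
#' @return Rate in bit/min (`itr`, `utr`) or letters/min (`clm`). All three
#'   are vectorised over their arguments.
#' @examples
#' itr(1.0, 32, 1.5) # 200 bit/min
#' clm(0.979, T_s = 1.19)
#' utr(0.979, 32, 1.19)
#' @export
itr <- function(P, N, T_s) {
  check_perf(P, N, T_s, n_min = 2)
  xlog2 <- function(x) ifelse(x == 0, 0, x * log2(x))
  bits <- log2(N) + xlog2(P) + ifelse(P == 1, 0, (1 - P) * log2((1 - P) / (N - 1)))
  bits * 60 / T_s
}

#' @rdname itr
#' @export
clm <- function(P, T_s) {
  check_perf(P, 2, T_s, n_min = 2)
  ifelse(P >= 0.5, 60 * (2 * P - 1) / T_s, 0)
}

#' @rdname itr
#' @export
utr <- function(P, N, T_s) {
  check_perf(P, N, T_s, n_min = 2)
  out <- ifelse(N == 2, 0, (2 * P - 1) * log2(N - 1) * 60 / T_s)
  if (any(out < 0)) {
    warning("accuracy below chance: utility bitrate is negative", call. = FALSE)
  }
  out
}

check_perf <- function(P, N, T_s, n_min) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1)) {
    stop("`P` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(N)) || any(N < n_min)) {
    stop(sprintf("`N` must be at least %d", n_min), call. = FALSE)
  }
  if (any(!is.finite(T_s)) || any(T_s <= 0)) {
    stop("`T_s` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean of per-unit metric values
#'
#' Result tables report the arithmetic mean of the per-subject (or per-run)
#' metric values — the metric of the mean accuracy is a different (and by
#' Jensen's inequality smaller, for the ITR) quantity.
#'
#' @param values Non-empty numeric vector.
#' @return Arithmetic mean.
#' @export
aggregate_mean <- function(values) {
  if (length(values) == 0L) stop("cannot aggregate an empty vector", call. = FALSE)
  mean(as.numeric(values))
}
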