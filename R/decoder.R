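#' Correlation between a predicted and a candidate stimulation pattern
#'
#' Pearson correlation of the real-valued per-bit predictions against a
#' candidate code of the same length. Real-valued probabilities (not the
#' binarised bits) are used throughout the decoders: they preserve the
#' model's confidence.
#'
#' @param probs Numeric per-bit predictions.
#' @param candidate A [stim_pattern()] (or 0/1 vector) of equal length.
#' @return Pearson r in \[-1, 1\], or `NA` ("undefined") when the candidate
#'   is constant; undefined candidates are excluded from every argmax.
#' @export
pattern_correlation <- function(probs, candidate) {
  bits <- if (inherits(candidate, "stim_pattern")) candidate$bits else as.numeric(candidate)
  if (length(probs) != length(bits)) {
    stop("prediction and candidate must have equal length", call. = FALSE)
  }
  if (length(probs) < 3L) stop("need at least 3 bits to correlate", call. = FALSE)
  if (var(bits) == 0 || var(probs) == 0) return(NA_real_)
  cor(as.numeric(probs), bits)
}

# Correlations of one prediction against every row of a 0/1 candidate
# matrix, vectorised. Constant rows give NA.
correlate_candidates <- function(probs, bits_matrix) {
  p <- as.numeric(probs)
  k <- length(p)
  pc <- p - mean(p)
  sp <- sqrt(sum(pc^2))
  s1 <- rowSums(bits_matrix)
  num <- drop(bits_matrix %*% pc)
  sb <- sqrt(s1 - s1^2 / k)
  r <- num / (sb * sp)
  r[sb == 0 | sp == 0] <- NA_real_
  r
}

#' Synchronous target classification
#'
#' Fixed-length trials: at trial end the predicted pattern is correlated
#' with the code of every target and the target with the highest
#' correlation is selected (ties broken towards the lowest index).
#'
#' @param pred A `bit_prediction` (or numeric per-bit predictions).
#' @param candidates A [pattern_set()]; each candidate's prefix of the trial
#'   length is used.
#' @return An object of class `sync_decision`: list with `target_index`,
#'   `target_id` and `correlations` (one per candidate, `NA` where
#'   undefined).
#' @export
classify_synchronous <- function(pred, candidates) {
  stopifnot(inherits(candidates, "pattern_set"))
  if (length(candidates) == 0L) stop("candidate set is empty", call. = FALSE)
  probs <- if (inherits(pred, "bit_prediction")) pred$probs else as.numeric(pred)
  m <- pattern_matrix(candidates)
  if (ncol(m) < length(probs)) {
    stop("candidate patterns are shorter than the trial", call. = FALSE)
  }
  m <- m[, seq_along(probs), drop = FALSE]
  r <- correlate_candidates(probs, m)
  if (all(is.na(r))) stop("all candidate correlations are undefined", call. = FALSE)
  best <- which.max(r) # ignores NA, first maximum = lowest index
  structure(
    list(target_index = best,
         target_id = candidates$patterns[[best]]$id,
         correlations = r),
    class = "sync_decision"
  )
}

#' @export
print.sync_decision <- function(x, ...) {
  cat(sprintf("<sync_decision: target %d (%s), r = %.3f>\n",
              x$target_index, x$target_id, x$correlations[x$target_index]))
  invisible(x)
}

#' One-sided p-value for a positive pattern correlation
#'
#' Significance of the hypothesis that the correlation between prediction
#' and candidate code is greater than zero, via the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a Student-t distribution
#' with `n - 2` degrees of freedom. Unlike the raw correlation this takes
#' the trial length into account, which is what makes it usable as a
#' stopping rule for asynchronous control.
#'
#' @param r Pearson correlation(s), |r| < 1.
#' @param n Number of bits the correlation was computed over (>= 3).
#' @return One-sided p-value(s) in (0, 1); a zero correlation gives
#'   exactly 0.5.
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("`n` must be at least 3", call. = FALSE)
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be below 1", call. = FALSE)
  t <- r * sqrt((n - 2) / (1 - r^2))
  pt(t, df = n - 2, lower.tail = FALSE)
}

#' Asynchronous (self-paced) target classification
#'
#' Variable-length trials: after every new bit the prediction so far is
#' compared with all candidate codes and the correlation p-values are
#' computed; the first time any p-value falls below the threshold, that
#' target is selected (ties: smallest p, then lowest index) and the elapsed
#' stimulation time is reported. Evaluation starts at `min_bits` (the
#' t-test is unstable on fewer points). If `max_trial_s` of stimulation
#' passes without a crossing, the non-control state is returned.
#'
#' @param probs Numeric per-bit predictions, in presentation order (the
#'   growing prediction stream; at most `max_trial_s * 60` bits are used).
#' @param candidates A [pattern_set()] spanning at least the bits used.
#' @param p_threshold Selection threshold in (0, 1\].
#' @param max_trial_s Stimulation time cap in seconds.
#' @param min_bits First evaluation point (default 12 bits = 200 ms).
#' @return An object of class `async_decision`: list with `target_index`
#'   (`NA` for non-control), `target_id` (`"NON_CONTROL"` if no selection),
#'   `trial_duration_s` (stimulation time until selection, a multiple of
#'   1/60 s, or the cap), and `p_values` at decision time.
#' @export
classify_asynchronous <- function(probs, candidates, p_threshold,
                                  max_trial_s = 10, min_bits = 12L) {
  stopifnot(inherits(candidates, "pattern_set"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("`p_threshold` must lie in (0, 1]", call. = FALSE)
  }
  probs <- if (inherits(probs, "bit_prediction")) probs$probs else as.numeric(probs)
  max_bits <- min(length(probs), floor(max_trial_s * FRAME_RATE))
  m <- pattern_matrix(candidates)
  if (ncol(m) < max_bits) {
    stop("candidate patterns are shorter than the maximum trial length", call. = FALSE)
  }
  first_eval <- max(3L, as.integer(min_bits))
  if (max_bits >= first_eval) {
    for (nb in seq.int(first_eval, max_bits)) {
      r <- correlate_candidates(probs[seq_len(nb)], m[, seq_len(nb), drop = FALSE])
      r[is.na(r)] <- NA_real_
      pv <- rep(NA_real_, length(r))
      ok <- !is.na(r) & abs(r) < 1
      pv[ok] <- correlation_pvalue(r[ok], nb)
      pv[!is.na(r) & r >= 1] <- 0 # perfect match saturates the test
      if (any(!is.na(pv) & pv < p_threshold) || p_threshold >= 1) {
        if (p_threshold >= 1) pv[is.na(pv)] <- 1
        best <- which.min(pv)
        return(structure(
          list(target_index = best,
               target_id = candidates$patterns[[best]]$id,
               trial_duration_s = nb / FRAME_RATE,
               p_values = pv),
          class = "async_decision"
        ))
      }
    }
  }
  structure(
    list(target_index = NA_integer_, target_id = "NON_CONTROL",
         trial_duration_s = max_bits / FRAME_RATE,
         p_values = NULL),
    class = "async_decision"
  )
}

#' @export
print.async_decision <- function(x, ...) {
  if (is.na(x$target_index)) {
    cat(sprintf("<async_decision: NON_CONTROL after %.2f s>\n", x$trial_duration_s))
  } else {
    cat(sprintf("<async_decision: target %d (%s) after %.2f s, p = %.2e>\n",
                x$target_index, x$target_id, x$trial_duration_s,
                x$p_values[x$target_index]))
  }
  invisible(x)
}

#' Discriminate the true code among a massive candidate set
#'
#' Because every target carries a random code, an arbitrary number of
#' candidate targets can be scored without recording EEG for them: the
#' predicted pattern is correlated with the true code and with
#' `n_candidates - 1` freshly drawn random distractor codes, and the true
#' code's rank among all candidates is reported. Distractors are generated
#' and correlated in streamed blocks so that memory stays bounded even at
#' half a million candidates.
#'
#' @param pred A `bit_prediction` (or numeric per-bit predictions).
#' @param true_pattern The [stim_pattern()] actually presented.
#' @param n_candidates Total candidate count (>= 2), e.g. 500000.
#' @param seed Integer seed for the distractor codes.
#' @param block_size Distractors per streamed block.
#' @return List with `is_correct` (true code has rank 1), `rank` (1 =
#'   best), `r_true`, and `n_candidates`.
#' @export
discriminate_large_set <- function(pred, true_pattern, n_candidates, seed,
                                   block_size = 100000L) {
  stopifnot(inherits(true_pattern, "stim_pattern"))
  if (!is.numeric(n_candidates) || n_candidates < 2) {
    stop("`n_candidates` must be at least 2", call. = FALSE)
  }
  probs <- if (inherits(pred, "bit_prediction")) pred$probs else as.numeric(pred)
  k <- length(true_pattern$bits)
  if (length(probs) != k) {
    stop("prediction and true pattern must have equal length", call. = FALSE)
  }
  r_true <- pattern_correlation(probs, true_pattern)
  if (is.na(r_true)) r_true <- -Inf
  n_distract <- as.integer(n_candidates) - 1L
  n_better <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < n_distract) {
      m <- min(block_size, n_distract - done)
      block <- matrix(as.numeric(runif(m * k) < 0.5), m, k)
      r <- correlate_candidates(probs, block)
      n_better <- n_better + sum(r > r_true, na.rm = TRUE)
      done <- done + m
    }
  })
  list(is_correct = n_better == 0L, rank = n_better + 1L,
       r_true = r_true, n_candidates = as.integer(n_candidates))
}

#' Discriminate many trials against one shared candidate set
#'
#' Batched counterpart of [discriminate_large_set()]: one set of
#' `n_candidates - 1` random distractor codes is drawn (streamed in
#' blocks) and every trial's prediction is ranked against it. This mirrors
#' a fixed layout of `n_candidates` simultaneously presented targets and
#' reads each distractor block once for all trials instead of once per
#' trial.
#'
#' @param preds List of per-trial predictions (`bit_prediction` or numeric
#'   vectors), all of one length.
#' @param true_patterns List of the [stim_pattern()]s actually presented,
#'   parallel to `preds`.
#' @param n_candidates Total candidate count (>= 2).
#' @param seed Integer seed for the shared distractor codes.
#' @param block_size Distractors per streamed block.
#' @return A `data.frame` with one row per trial: `is_correct`, `rank`,
#'   `r_true`.
#' @export
discriminate_set <- function(preds, true_patterns, n_candidates, seed,
                             block_size = 100000L) {
  stopifnot(length(preds) == length(true_patterns), length(preds) >= 1L)
  if (!is.numeric(n_candidates) || n_candidates < 2) {
    stop("`n_candidates` must be at least 2", call. = FALSE)
  }
  m <- length(preds)
  probs <- lapply(preds, function(p) {
    if (inherits(p, "bit_prediction")) p$probs else as.numeric(p)
  })
  k <- length(true_patterns[[1]]$bits)
  if (any(vapply(probs, length, integer(1)) != k)) {
    stop("all predictions must match the pattern length", call. = FALSE)
  }
  PC <- vapply(probs, function(v) v - mean(v), numeric(k)) # k x m
  sp <- sqrt(colSums(PC^2))
  r_true <- vapply(seq_len(m), function(i) {
    r <- pattern_correlation(probs[[i]], true_patterns[[i]])
    if (is.na(r)) -Inf else r
  }, numeric(1))
  counts <- integer(m)
  n_distract <- as.integer(n_candidates) - 1L
  with_seed(seed, {
    done <- 0L
    while (done < n_distract) {
      nb <- min(block_size, n_distract - done)
      B <- matrix(as.numeric(runif(nb * k) < 0.5), nb, k)
      s1 <- rowSums(B)
      sb <- sqrt(s1 - s1^2 / k)
      R <- (B %*% PC) / outer(sb, sp) # nb x m correlations
      cmp <- R > matrix(r_true, nb, m, byrow = TRUE)
      counts <- counts + as.integer(colSums(cmp, na.rm = TRUE))
      done <- done + nb
    }
  })
  data.frame(is_correct = counts == 0L, rank = counts + 1L, r_true = r_true)
}
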