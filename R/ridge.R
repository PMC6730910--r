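#' Train the linear ridge regression backward model
#'
#' The baseline EEG2Code model: each 250 ms window (150 samples x 32
#' channels) is flattened to a 4800-vector and a closed-form ridge
#' regression maps it to the bit shown at the window start. The intercept
#' is unpenalised (features and labels are centred before solving). The fit
#' is deterministic given its inputs.
#'
#' @param windows A labelled [extract_windows()] result; windows with `NA`
#'   labels (padding) are dropped. Both bit classes must be present.
#' @param lambda Ridge penalty (>= 0). The default of 1 is a mild,
#'   configurable regulariser.
#' @param spatial_filter If `TRUE`, learn a single discriminative 32-channel
#'   spatial filter from the training data first and fit the ridge on the
#'   150 filtered samples per window instead of the full 4800 features.
#'   Off by default: the reference configuration feeds unfiltered windows.
#' @return An object of class `cvep_ridge` with elements `weights`,
#'   `intercept`, `lambda` and optionally `spatial_filter` (32-vector).
#' @seealso [predict.cvep_ridge()]
#' @export
train_ridge <- function(windows, lambda = 1, spatial_filter = FALSE) {
  stopifnot(inherits(windows, "window_set"))
  if (is.null(windows$labels)) stop("windows must be labelled for training", call. = FALSE)
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  keep <- !is.na(windows$labels)
  y <- as.numeric(windows$labels[keep])
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class; both bit values are required",
         call. = FALSE)
  }
  filt <- NULL
  if (spatial_filter) {
    filt <- learn_spatial_filter(windows$data[, , keep, drop = FALSE], y)
    Xp <- t(project_windows(windows$data[, , keep, drop = FALSE], filt))
  } else {
    Xp <- feature_matrix(windows) # features x windows, no copy
    if (!all(keep)) Xp <- Xp[, keep, drop = FALSE]
  }
  n <- ncol(Xp)
  xbar <- rowMeans(Xp)
  ybar <- mean(y)
  G <- tcrossprod(Xp) - n * tcrossprod(xbar)
  b <- drop(Xp %*% y) - n * xbar * ybar
  diag(G) <- diag(G) + lambda
  w <- tryCatch({
    U <- chol(G)
    drop(backsolve(U, backsolve(U, b, transpose = TRUE)))
  }, error = function(e) drop(qr.solve(G, b, tol = 1e-12)))
  structure(
    list(weights = w, intercept = ybar - sum(xbar * w), lambda = lambda,
         spatial_filter = filt),
    class = "cvep_ridge"
  )
}

# Discriminative spatial filter: regularised regression of the bit label on
# the window-averaged channel activity (a CCA-style single component).
learn_spatial_filter <- function(arr, y) {
  A <- t(apply(arr, 3L, colMeans)) # n x 32 channel means
  A <- scale(A, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(A) + 1e-6 * diag(ncol(A))
  w <- drop(solve(G, crossprod(A, yc)))
  w / sqrt(sum(w^2))
}

project_windows <- function(arr, filt) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(1L, 3L, 2L)), d[1] * d[3], d[2])
  matrix(m %*% filt, d[3], d[1], byrow = TRUE)
}

#' @export
print.cvep_ridge <- function(x, ...) {
  cat(sprintf("<cvep_ridge: %d features, lambda = %g%s>\n",
              length(x$weights), x$lambda,
              if (is.null(x$spatial_filter)) "" else ", spatially filtered"))
  invisible(x)
}

#' Sample-wise predictions from a ridge backward model
#'
#' @param object A [train_ridge()] fit.
#' @param windows A `window_set`.
#' @param ... Unused.
#' @return Numeric vector, one probability-like value in \[0, 1\] per window
#'   (raw affine outputs are clipped to the unit interval).
#' @export
predict.cvep_ridge <- function(object, windows, ...) {
  stopifnot(inherits(windows, "window_set"))
  if (is.null(object$spatial_filter)) {
    Xp <- feature_matrix(windows)
    if (nrow(Xp) != length(object$weights)) {
      stop("window shape does not match the trained model", call. = FALSE)
    }
    raw <- drop(crossprod(Xp, object$weights)) + object$intercept
  } else {
    X <- project_windows(windows$data, object$spatial_filter)
    if (ncol(X) != length(object$weights)) {
      stop("window shape does not match the trained model", call. = FALSE)
    }
    raw <- drop(X %*% object$weights) + object$intercept
  }
  pmin(pmax(raw, 0), 1)
}
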