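#' Train the convolutional EEG2Code model
#'
#' The non-linear backward model: a five-layer convolutional network that
#' takes a raw (not spatially filtered) 150 x 32 window and outputs the two
#' class probabilities `p0`, `p1 = 1 - p0` that the bit at the window start
#' is black or white. Layer 1 holds 16 convolutional kernels of size 1 x 32
#' acting as learned spatial filters; layer 2 holds 8 kernels of size
#' 64 x 1 acting as temporal filters (zero-padded to preserve length); both
#' are batch-normalised and rectified. Two temporal max-pools (size 2,
#' stride 2) then a dense head (dropout, 128 rectified units, 2-way
#' softmax) complete the model. Training minimises the 2-class
#' cross-entropy with adaptive-moment gradient descent (learning rate
#' 0.001, batch size 256 by default, 25 epochs); after every epoch the
#' model is scored on a held-out validation split and the epoch with the
#' highest validation accuracy is kept as the final model.
#'
#' The validation split is the *contiguous tail* of the window sequence,
#' not a random subset: neighbouring windows overlap by up to 149 samples,
#' so a random split would leak test information into training.
#'
#' @param windows A labelled [extract_windows()] result (`NA`-labelled
#'   padding windows are dropped).
#' @param val_fraction Fraction of windows held out for validation, in
#'   (0, 0.5].
#' @param epochs,batch_size,learning_rate,dropout Training hyperparameters.
#' @param seed Integer seed driving weight initialisation, batch shuffling
#'   and dropout; fixed seed and data give an identical model and report.
#' @param verbose Print one line per epoch.
#' @return A list with elements `model` (class `cvep_cnn`) and `report`
#'   (class `cnn_training_report`: per-epoch training loss/accuracy and
#'   validation accuracy, plus the selected epoch and seed).
#' @seealso [predict.cvep_cnn()]
#' @export
train_cnn <- function(windows, val_fraction = 1 / 6, epochs = 25L,
                      batch_size = 256L, learning_rate = 0.001,
                      dropout = 0.5, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(windows, "window_set"))
  if (is.null(windows$labels)) stop("windows must be labelled for training", call. = FALSE)
  if (!is.numeric(val_fraction) || val_fraction <= 0 || val_fraction > 0.5) {
    stop("`val_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  keep <- which(!is.na(windows$labels))
  y <- as.integer(windows$labels[keep])
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class; both bit values are required",
         call. = FALSE)
  }
  n <- length(keep)
  n_val <- max(1L, floor(n * val_fraction))
  n_train <- n - n_val
  if (n_train < batch_size) {
    stop(sprintf(
      "only %d training windows for a batch size of %d; lower `batch_size` or provide more data",
      n_train, batch_size
    ), call. = FALSE)
  }
  idx_train <- keep[seq_len(n_train)]
  idx_val <- keep[seq.int(n_train + 1L, n)]
  y_train <- as.integer(windows$labels[idx_train])
  y_val <- as.integer(windows$labels[idx_val])
  Xval <- windows$data[, , idx_val, drop = FALSE]

  with_seed(seed, {
    params <- cnn_init_params()
    adam <- list(m = lapply(params, function(p) p * 0),
                 v = lapply(params, function(p) p * 0), t = 0L)
    bn <- list(rm1 = rep(0, 16), rv1 = rep(1, 16),
               rm2 = rep(0, 8), rv2 = rep(1, 8))
    momentum <- 0.1

    best <- list(val_acc = -Inf, params = params, bn = bn, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), val_acc = numeric())

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_train)
      starts <- seq.int(1L, n_train, by = batch_size)
      losses <- accs <- numeric(0)
      for (s in starts) {
        bidx <- ord[s:min(s + batch_size - 1L, n_train)]
        if (length(bidx) < 8L) next # too small for stable batch statistics
        Xb <- windows$data[, , idx_train[bidx], drop = FALSE]
        yb <- y_train[bidx]
        mask <- matrix(
          (runif(296L * length(bidx)) >= dropout) / (1 - dropout),
          296L, length(bidx)
        )
        step <- cnn_train_batch(Xb, yb, params, mask)
        g <- step$grads
        adam$t <- adam$t + 1L
        for (nm in names(params)) {
          adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * g[[nm]]
          adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * g[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - 0.9^adam$t)
          vhat <- adam$v[[nm]] / (1 - 0.999^adam$t)
          params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
        bn$rm1 <- (1 - momentum) * bn$rm1 + momentum * drop(step$bn1_mean)
        bn$rv1 <- (1 - momentum) * bn$rv1 + momentum * drop(step$bn1_var)
        bn$rm2 <- (1 - momentum) * bn$rm2 + momentum * drop(step$bn2_mean)
        bn$rv2 <- (1 - momentum) * bn$rv2 + momentum * drop(step$bn2_var)
        losses <- c(losses, step$loss)
        accs <- c(accs, step$acc)
      }
      val_prob <- cnn_predict_chunked(Xval, params, bn)
      val_acc <- mean(as.integer(val_prob >= 0.5) == y_val)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = mean(losses), train_acc = mean(accs),
        val_acc = val_acc
      ))
      if (verbose) {
        message(sprintf("epoch %2d: loss %.4f train acc %.3f val acc %.3f",
                        ep, mean(losses), mean(accs), val_acc))
      }
      if (val_acc > best$val_acc) {
        best <- list(val_acc = val_acc, params = params, bn = bn, epoch = ep)
      }
    }

    model <- structure(
      list(params = best$params, bn = best$bn,
           hyper = list(epochs = epochs, batch_size = batch_size,
                        learning_rate = learning_rate, dropout = dropout,
                        val_fraction = val_fraction)),
      class = "cvep_cnn"
    )
    report <- structure(
      list(history = hist, selected_epoch = best$epoch, seed = seed),
      class = "cnn_training_report"
    )
    list(model = model, report = report)
  })
}

# He initialisation for the rectified layers; batch-norm scale starts at 1.
cnn_init_params <- function() {
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(
    W1 = he(32, 16, 32), b1 = rep(0, 16), g1 = rep(1, 16), be1 = rep(0, 16),
    W2 = he(64 * 16, 8, 64 * 16), b2 = rep(0, 8), g2 = rep(1, 8), be2 = rep(0, 8),
    W3 = he(296, 128, 296), b3 = rep(0, 128),
    W4 = he(128, 2, 128), b4 = rep(0, 2)
  )
}

cnn_predict_chunked <- function(X, params, bn, chunk = 2048L) {
  n <- dim(X)[3]
  out <- numeric(n)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- drop(cnn_predict_batch(
      X[, , s:e, drop = FALSE], params, bn$rm1, bn$rv1, bn$rm2, bn$rv2
    ))
  }
  out
}

#' @export
print.cvep_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<cvep_cnn: 5-layer convolutional EEG2Code model, %d parameters>\n", n_par))
  invisible(x)
}

#' @export
print.cnn_training_report <- function(x, ...) {
  cat(sprintf("<cnn_training_report: %d epochs, selected epoch %d (val acc %.3f)>\n",
              nrow(x$history), x$selected_epoch,
              x$history$val_acc[x$selected_epoch]))
  invisible(x)
}

#' Sample-wise predictions from the convolutional model
#'
#' @param object A trained `cvep_cnn`.
#' @param windows A `window_set`.
#' @param type `"response"` for the probability of bit 1 per window,
#'   `"matrix"` for both class probabilities (columns `p0`, `p1`).
#' @param ... Unused.
#' @return Numeric vector in \[0, 1\], or a two-column matrix with rows
#'   summing to 1.
#' @export
predict.cvep_cnn <- function(object, windows, type = c("response", "matrix"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(windows, "window_set"))
  d <- dim(windows$data)
  if (d[1] != WINDOW_SAMPLES || d[2] != N_CHANNELS) {
    stop("window shape does not match the model input (150 x 32)", call. = FALSE)
  }
  p1 <- cnn_predict_chunked(windows$data, object$params, object$bn)
  if (type == "response") return(p1)
  cbind(p0 = 1 - p1, p1 = p1)
}

#' Save and load trained backward models
#'
#' Models are stored as an R binary container (RDS) holding the full object
#' (architecture parameters, batch-norm statistics, hyperparameters) plus a
#' JSON sidecar `<path>.json` with human-readable metadata.
#'
#' @param model A `cvep_ridge` or `cvep_cnn`.
#' @param path Output file.
#' @return `load_model()` returns the model object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cvep_ridge") || inherits(model, "cvep_cnn"))
  saveRDS(model, path)
  meta <- list(
    class = class(model)[1],
    saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_parameters = if (inherits(model, "cvep_cnn")) {
      sum(vapply(model$params, length, integer(1)))
    } else length(model$weights) + 1L
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
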