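#' Stimulation pattern objects
#'
#' A stimulation pattern is the binary code a visual target flickers with:
#' one bit per monitor frame at 60 Hz, where 0 encodes a black and 1 a white
#' stimulus. `stim_pattern()` constructs a pattern from an explicit bit
#' vector; [random_pattern()] draws a fully random one.
#'
#' @param bits Integer (or logical) vector of 0/1 values, one per frame.
#' @param id Optional target label.
#' @return An object of class `stim_pattern`: a list with elements `bits`
#'   (integer 0/1 vector), `frame_rate` (fixed at 60 Hz) and `id`.
#' @examples
#' p <- stim_pattern(c(1, 0, 0, 1, 1))
#' duration_s(p)
#' @export
stim_pattern <- function(bits, id = NULL) {
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("a stimulation pattern needs at least one bit", call. = FALSE)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("pattern bits must all be 0 or 1", call. = FALSE)
  }
  structure(
    list(bits = bits, frame_rate = FRAME_RATE, id = id),
    class = "stim_pattern"
  )
}

#' @rdname stim_pattern
#' @param x A `stim_pattern`.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "stim_pattern"))
  length(x$bits) / FRAME_RATE
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat(sprintf(
    "<stim_pattern%s: %d bits (%.3f s at %d Hz), %.1f%% ones>\n",
    if (is.null(x$id)) "" else paste0(" ", x$id),
    length(x$bits), duration_s(x), x$frame_rate, 100 * mean(x$bits)
  ))
  invisible(x)
}

#' @export
length.stim_pattern <- function(x) length(x$bits)

#' Draw a fully random stimulation pattern
#'
#' Each bit is drawn independently with probability 0.5, the modulation used
#' for the fully random c-VEP stimulation condition. Identical seeds give
#' identical patterns.
#'
#' @param n_bits Number of frames (>= 1).
#' @param seed Integer seed for the pattern bits.
#' @param id Optional target label.
#' @return A [stim_pattern()].
#' @examples
#' random_pattern(120, seed = 1)
#' @export
random_pattern <- function(n_bits, seed, id = NULL) {
  if (!is.numeric(n_bits) || length(n_bits) != 1L || n_bits < 1) {
    stop("`n_bits` must be a positive integer", call. = FALSE)
  }
  bits <- with_seed(seed, rbinom(as.integer(n_bits), 1L, 0.5))
  stim_pattern(bits, id = id)
}

#' Sets of target stimulation patterns
#'
#' A pattern set holds one stimulation code per selectable target, all of
#' equal length, with unique labels kept in lexicographic order (the order
#' targets are arranged in the matrix-keyboard layout).
#'
#' @param patterns List of [stim_pattern()] objects of equal length with
#'   unique non-`NULL` ids.
#' @return An object of class `pattern_set`.
#' @seealso [random_pattern_set()] to generate one.
#' @export
pattern_set <- function(patterns) {
  if (length(patterns) < 1L) {
    return(structure(list(patterns = list()), class = "pattern_set"))
  }
  stopifnot(all(vapply(patterns, inherits, logical(1), "stim_pattern")))
  lens <- vapply(patterns, function(p) length(p$bits), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all patterns in a set must have the same length", call. = FALSE)
  }
  ids <- vapply(patterns, function(p) as.character(p$id %||% NA_character_), character(1))
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("all patterns in a set must carry unique ids", call. = FALSE)
  }
  patterns <- patterns[order(ids)]
  structure(list(patterns = patterns), class = "pattern_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' @export
print.pattern_set <- function(x, ...) {
  n <- length(x$patterns)
  nb <- if (n) length(x$patterns[[1]]$bits) else 0L
  cat(sprintf("<pattern_set: %d targets x %d bits>\n", n, nb))
  invisible(x)
}

#' Bits of a pattern set as a matrix
#'
#' @param x A `pattern_set`.
#' @return Integer matrix, one row per target (in id order), one column per
#'   frame.
#' @export
pattern_matrix <- function(x) {
  stopifnot(inherits(x, "pattern_set"))
  do.call(rbind, lapply(x$patterns, `[[`, "bits"))
}

#' Generate a set of random target patterns
#'
#' Draws one random stimulation code per target. With `decorrelate = TRUE` a
#' greedy search over a pool of random candidates picks, for each successive
#' target, the candidate minimising the maximum absolute pairwise Pearson
#' correlation with the codes already chosen. This is a documented proxy for
#' optimised (decorrelated) stimulation patterns; it makes no claim of
#' equivalence to any published optimisation scheme.
#'
#' @param n_targets Number of targets (>= 2).
#' @param n_bits Frames per pattern.
#' @param seed Integer seed.
#' @param decorrelate Use the greedy low-correlation search instead of
#'   independent draws.
#' @param pool_size Candidate pool size per target for the greedy search.
#' @return A [pattern_set()] with ids `"T01"`, `"T02"`, ... in lexicographic
#'   order.
#' @examples
#' ps <- random_pattern_set(32, 120, seed = 7)
#' length(ps)
#' @export
random_pattern_set <- function(n_targets, n_bits, seed, decorrelate = FALSE,
                               pool_size = 1000L) {
  if (!is.numeric(n_targets) || length(n_targets) != 1L || n_targets < 2) {
    stop("`n_targets` must be an integer >= 2", call. = FALSE)
  }
  n_targets <- as.integer(n_targets)
  n_bits <- as.integer(n_bits)
  ids <- sprintf("T%02d", seq_len(n_targets))
  bits_list <- with_seed(seed, {
    if (!decorrelate) {
      lapply(seq_len(n_targets), function(i) rbinom(n_bits, 1L, 0.5))
    } else {
      greedy_decorrelated_bits(n_targets, n_bits, pool_size)
    }
  })
  pattern_set(Map(function(b, id) stim_pattern(b, id = id), bits_list, ids))
}

# Greedy proxy for optimised stimulation codes: for each new target, draw
# `pool_size` random candidates and keep the one whose worst-case |r| against
# the already selected codes is smallest. Constant candidates (possible only
# at tiny n_bits) count as |r| = 0.
greedy_decorrelated_bits <- function(n_targets, n_bits, pool_size) {
  chosen <- list(rbinom(n_bits, 1L, 0.5))
  for (i in seq_len(n_targets - 1L)) {
    sel <- do.call(cbind, chosen)
    pool <- matrix(rbinom(n_bits * pool_size, 1L, 0.5), nrow = n_bits)
    worst <- vapply(seq_len(pool_size), function(j) {
      r <- suppressWarnings(cor(pool[, j], sel))
      r[is.na(r)] <- 0
      max(abs(r))
    }, numeric(1))
    chosen[[length(chosen) + 1L]] <- pool[, which.min(worst)]
  }
  chosen
}

#' Maximum absolute pairwise correlation within a pattern set
#'
#' @param x A `pattern_set` with at least two patterns.
#' @return The largest |Pearson r| over all target pairs; undefined
#'   (constant-pattern) pairs contribute 0.
#' @export
max_pairwise_correlation <- function(x) {
  m <- t(pattern_matrix(x))
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 0
  max(abs(r))
}

#' Read and write stimulation pattern files
#'
#' Plain-text format, one pattern per line: the bits as a run of `'0'`/`'1'`
#' characters, optionally preceded by `"<id><TAB>"`. Blank lines are
#' ignored. `write_patterns()` followed by `read_patterns()` is the identity
#' on a pattern set.
#'
#' @param path File path.
#' @return `read_patterns()` returns a [pattern_set()]; an empty file gives
#'   an empty set with a warning.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    warning("pattern file is empty: ", path, call. = FALSE)
    return(pattern_set(list()))
  }
  pats <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      id <- sprintf("T%02d", i)
      code <- parts[[1]]
      col0 <- 0L
    } else {
      id <- parts[[1]]
      code <- parts[[2]]
      col0 <- nchar(id) + 1L
    }
    chars <- strsplit(code, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("0", "1"))
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid character '%s' in pattern file %s at line %d, column %d",
        chars[bad[1]], path, lineno[i], col0 + bad[1]
      ), call. = FALSE)
    }
    pats[[i]] <- stim_pattern(as.integer(chars), id = id)
  }
  pattern_set(pats)
}

#' @rdname read_patterns
#' @param x A `pattern_set`.
#' @export
write_patterns <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  lines <- vapply(x$patterns, function(p) {
    paste0(p$id, "\t", paste(p$bits, collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
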