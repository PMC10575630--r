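# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so generator calls are
#' bit-reproducible without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Fisher-Pearson skewness (delegates to e1071, type 2)
#' @noRd
skewness_adj <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(0)
  e1071::skewness(x, type = 2)
}

#' Robust SD via the median absolute deviation
#'
#' `stats::mad` with the 1.4826 consistency constant; NA-safe.
#' @noRd
robust_sd <- function(x) stats::mad(x, na.rm = TRUE)

# Assert a scalar probability / positive scalar; terse arg checking used by
# the public constructors.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  x
}
check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("`%s` must be %s", name,
                        if (strict) "> 0" else ">= 0"), call. = FALSE)
  x
}

#' Maximal runs of TRUE in a logical vector
#'
#' Returns a data.frame with start/end indices of each run; NAs break runs.
#' @noRd
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Flatten an H x W x T movie into a T x P matrix (P = H*W, column-major)
#' @noRd
movie_as_matrix <- function(movie) {
  d <- dim(movie)
  stopifnot(length(d) == 3L)
  t(matrix(movie, nrow = d[1L] * d[2L], ncol = d[3L]))
}

#' Reshape a length-P vector back to H x W
#' @noRd
as_image <- function(v, dim_hw) matrix(v, nrow = dim_hw[1L], ncol = dim_hw[2L])

`%||%` <- function(a, b) if (is.null(a)) b else a
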