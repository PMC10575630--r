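# Plain-format I/O: multipage TIFF movies, CSV traces / trajectories /
# entry sequences, JSON ground truth.

#' Write / read a movie as multipage grayscale TIFF
#'
#' Intensities are scaled to `[0, 1]` by `scale` (default the movie
#' maximum) and stored as 32-bit float pages; the scale is returned so
#' callers can restore absolute units on read.
#'
#' @param movie H x W x T array.
#' @param path Output file.
#' @param scale Intensity that maps to 1.0 (default `max(movie)`).
#' @return `write_movie_tiff`: the scale used (invisibly).
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  d <- dim(movie)
  stopifnot(length(d) == 3L)
  scale <- scale %||% max(movie)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[3L]), function(t)
    pmin(pmax(movie[, , t] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_movie_tiff
#' @param frame_rate Hz, attached to the returned array.
#' @export
read_movie_tiff <- function(path, scale = 1, frame_rate = 30) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
  out <- out * scale
  attr(out, "frame_rate") <- frame_rate
  class(out) <- "calcium_movie"
  out
}

#' Write / read dF/F0 traces as CSV (time_s, then one column per neuron)
#'
#' @param traces T x N matrix with attribute `frame_rate`.
#' @param path CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  fps <- attr(traces, "frame_rate") %||% 30
  df <- data.frame(time_s = (seq_len(nrow(traces)) - 1L) / fps,
                   as.data.frame(unclass(traces)))
  names(df) <- c("time_s", paste0("n", seq_len(ncol(traces))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  traces <- as.matrix(df[, -1L, drop = FALSE])
  fps <- if (nrow(df) >= 2L) 1 / stats::median(diff(df$time_s)) else 30
  attr(traces, "frame_rate") <- fps
  traces
}

#' Write / read a trajectory as CSV (time_s, x, y)
#' @param traj A `trajectory` data.frame.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_s", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "x", "y") %in% names(df)))
  attr(df, "frame_rate") <- 1 / stats::median(diff(df$time_s))
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Write / read an arm-entry sequence as CSV (time_s, arm)
#' @param seq An `arm_entries` object.
#' @param path CSV path.
#' @export
write_entries_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq)[, c("time_s", "arm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_entries_csv
#' @export
read_entries_csv <- function(path) {
  df <- utils::read.csv(path)
  arm_entries(df$arm, df$time_s)
}
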