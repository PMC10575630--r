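# Derivative-based detection of calcium-event rising phases.

#' Moving-window least-squares derivative of a trace
#'
#' Slope of a centered linear regression over a `window_s` window
#' (6 frames at 30 Hz for the default 200 ms), in trace units per second.
#' More noise-robust than a two-point difference. Edge samples without a
#' full window are NA.
#'
#' @param x Numeric trace.
#' @param frame_rate Hz.
#' @param window_s Window length, s (default 0.2).
#' @return Numeric vector of the same length as `x`.
#' @export
rolling_slope <- function(x, frame_rate, window_s = 0.2) {
  w <- max(2L, round(window_s * frame_rate))
  n <- length(x)
  if (n < w) stop("trace shorter than the derivative window", call. = FALSE)
  off <- seq_len(w) - (w + 1) / 2          # centered sample offsets
  coef <- off / sum(off^2) * frame_rate    # slope per second
  left <- floor((w - 1) / 2)
  out <- rep(NA_real_, n)
  core <- (1L + left):(n - (w - 1L - left))
  acc <- numeric(length(core))
  for (k in seq_len(w)) acc <- acc + coef[k] * x[core - left + (k - 1L)]
  out[core] <- acc
  out
}

#' Robust baseline fluctuation of a trace and its derivative
#'
#' Scale estimates via MAD x 1.4826, so sparse large transients do not
#' inflate their own detection threshold. A constant trace gives (0, 0).
#'
#' @param x Numeric dF/F0 trace.
#' @param frame_rate Hz.
#' @param window_s Derivative window, s.
#' @return Named numeric vector `c(sd_dff, sd_deriv)` (the derivative SD
#'   is in units/s).
#' @export
baseline_sd <- function(x, frame_rate, window_s = 0.2) {
  c(sd_dff = robust_sd(x),
    sd_deriv = robust_sd(rolling_slope(x, frame_rate, window_s)))
}

#' Detect calcium-event rising phases
#'
#' An event candidate is a maximal run of samples where the moving-window
#' first derivative of dF/F0 is above zero; the run must contain at least
#' one sample whose derivative exceeds `deriv_thresh_sd` baseline SDs of
#' the derivative, and the dF/F0 peak within the run must exceed the trace
#' median by `peak_thresh_sd` baseline SDs. The event spans from the first
#' frame of the run (derivative rises above 0) to the last frame before
#' the derivative falls below 0; its magnitude is the dF/F0 difference
#' between end and start of the rising phase.
#'
#' Both thresholds are relative to robust baseline scales, so the detector
#' is invariant to adding a constant and equivariant under positive
#' rescaling of the trace.
#'
#' @param x Numeric dF/F0 trace (or `calcium_trace`).
#' @param frame_rate Hz.
#' @param window_s Derivative window, s (default 0.2).
#' @param peak_thresh_sd Peak threshold in baseline SDs of dF/F0
#'   (default 3).
#' @param deriv_thresh_sd Slope threshold in baseline SDs of the
#'   derivative (default 5).
#' @return A data.frame of class `calcium_events` with columns
#'   `start_idx`, `end_idx`, `magnitude`, `peak_dff`, ordered by
#'   `start_idx` (non-overlapping by construction); attribute
#'   `baseline_sd` records the scales used.
#' @export
detect_events <- function(x, frame_rate, window_s = 0.2,
                          peak_thresh_sd = 3, deriv_thresh_sd = 5) {
  if (inherits(x, "calcium_trace")) x <- x$dff
  stopifnot(peak_thresh_sd > 0, deriv_thresh_sd > 0)
  dv <- rolling_slope(x, frame_rate, window_s)
  sds <- c(sd_dff = robust_sd(x), sd_deriv = robust_sd(dv))
  # a constant trace has zero baseline scale and no positive-derivative
  # runs, so it naturally yields no events; noise-free transients keep
  # working because the thresholds degrade gracefully to zero
  med <- stats::median(x)
  runs <- true_runs(dv > 0)
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    max(dv[s:e]) > deriv_thresh_sd * sds["sd_deriv"] &&
      max(x[s:e]) > med + peak_thresh_sd * sds["sd_dff"]
  }, logical(1))
  runs <- runs[keep, , drop = FALSE]
  ev <- data.frame(start_idx = runs$start, end_idx = runs$end,
                   magnitude = x[runs$end] - x[runs$start],
                   peak_dff = vapply(seq_len(nrow(runs)), function(i)
                     max(x[runs$start[i]:runs$end[i]]), numeric(1)))
  ev <- ev[order(ev$start_idx), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("calcium_events", "data.frame"),
            baseline_sd = sds)
}

#' Event rate and mean magnitude
#'
#' @param events A `calcium_events` data.frame.
#' @param duration_s Trace duration, s (> 0).
#' @return List with `rate_per_min` (= count / duration * 60), `n_events`,
#'   `mean_magnitude` (NA when there are no events).
#' @export
event_summary <- function(events, duration_s) {
  check_pos(duration_s, "duration_s")
  n <- nrow(events)
  list(rate_per_min = n / duration_s * 60, n_events = n,
       mean_magnitude = if (n > 0) mean(events$magnitude) else NA_real_)
}
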