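# Y-maze scoring: arm-entry detection, spontaneous alternation, trial
# segmentation into 20 position bins, and locomotion summaries.

#' Ordered arm-entry sequence
#'
#' @param arm Character vector of arm labels; consecutive duplicates are
#'   not allowed (an "entry" requires leaving the previous arm first).
#' @param entry_times Optional numeric vector of entry times (s), strictly
#'   increasing.
#' @return A data.frame of class `arm_entries` with columns `arm` and
#'   `time_s`.
#' @export
arm_entries <- function(arm, entry_times = NULL) {
  arm <- as.character(arm)
  n <- length(arm)
  if (n >= 2L && any(arm[-1L] == arm[-n]))
    stop("arm entry sequence contains an immediate re-entry", call. = FALSE)
  if (is.null(entry_times)) entry_times <- seq_len(n) - 1
  if (length(entry_times) != n || (n >= 2L && any(diff(entry_times) <= 0)))
    stop("entry_times must be strictly increasing and match entries")
  structure(data.frame(arm = arm, time_s = as.numeric(entry_times)),
            class = c("arm_entries", "data.frame"))
}

#' Detect arm entries from a body-center trajectory
#'
#' The "all four paws in the arm" criterion of manual scoring is proxied by
#' the body center passing a depth threshold: an entry into arm `k` is
#' recorded when the axial projection onto `k` exceeds
#' `entry_frac * arm_length`, and no further entry can register until the
#' animal has retreated below `exit_frac * arm_length` (hysteresis, so a
#' single visit is never double-counted). Consecutive detections of the
#' same arm are collapsed.
#'
#' @param traj A `trajectory` data.frame (columns `time_s`, `x`, `y`).
#' @param geometry A [maze_geometry()].
#' @param entry_frac Entry threshold as a fraction of arm length
#'   (default 0.33).
#' @param exit_frac Hysteresis release threshold (default 0.15).
#' @return An `arm_entries` object; empty (with a warning) if the
#'   trajectory never passes the entry threshold.
#' @export
detect_arm_entries <- function(traj, geometry = attr(traj, "geometry"),
                               entry_frac = 0.33, exit_frac = 0.15) {
  if (is.null(geometry)) geometry <- maze_geometry()
  stopifnot(entry_frac > exit_frac, entry_frac < 1)
  pr <- arm_projection(as.matrix(traj[, c("x", "y")]), geometry)
  d_in <- entry_frac * geometry$arm_length
  d_out <- exit_frac * geometry$arm_length
  entries <- character(0)
  times <- numeric(0)
  armed <- TRUE
  for (i in seq_along(pr$depth)) {
    if (armed && pr$depth[i] >= d_in) {
      if (length(entries) == 0L || entries[length(entries)] != pr$arm[i]) {
        entries <- c(entries, pr$arm[i])
        times <- c(times, traj$time_s[i])
      }
      armed <- FALSE
    } else if (!armed && pr$depth[i] <= d_out) {
      armed <- TRUE
    }
  }
  if (length(entries) == 0L)
    warning("trajectory never leaves the center region; empty sequence")
  arm_entries(entries, times)
}

#' Spontaneous alternation percentage
#'
#' Slides a window of three consecutive entries along the sequence and
#' counts windows whose three labels are all distinct (e.g. ABC but not
#' ABA). The score is
#' `alternating triplets / (total entries - 2) * 100`.
#'
#' @param seq An `arm_entries` object or character vector of arm labels.
#' @return A list of class `alternation_result` with `alternating_entries`,
#'   `total_entries` and `alternation_pct`.
#' @examples
#' alternation_percentage(c("A", "B", "C", "A", "C", "B"))
#' @export
alternation_percentage <- function(seq) {
  arm <- if (inherits(seq, "arm_entries")) seq$arm else as.character(seq)
  n <- length(arm)
  if (n < 3L) stop("alternation undefined: need at least 3 entries",
                   call. = FALSE)
  trip <- vapply(seq_len(n - 2L), function(i) {
    length(unique(arm[i:(i + 2L)])) == 3L
  }, logical(1))
  structure(list(alternating_entries = sum(trip),
                 total_entries = n,
                 alternation_pct = 100 * sum(trip) / (n - 2L)),
            class = "alternation_result")
}

#' @export
print.alternation_result <- function(x, ...) {
  cat(sprintf("alternation: %d/%d triplets = %.1f%%\n",
              x$alternating_entries, x$total_entries - 2L,
              x$alternation_pct))
  invisible(x)
}

#' Chance-level alternation of a random-exploration agent
#'
#' Simulates agents that pick uniformly between the two available arms
#' (`p_alt`, default 0.5) and scores each session, giving the Monte-Carlo
#' chance level (50% for a fair chooser) with a normal-approximation CI of
#' the mean.
#'
#' @param n_entries Entries per session (default 30).
#' @param n_sessions Number of simulated sessions.
#' @param seed Integer seed.
#' @param p_alt Choice bias of the simulated agent; 0.5 = chance
#'   (exposed for calibration checks).
#' @param conf Confidence level for the CI of the mean.
#' @return A list with `mean_pct`, `ci` (length 2), `sd_pct`, `n_sessions`.
#' @export
chance_level <- function(n_entries = 30, n_sessions = 1e4, seed = 1,
                         p_alt = 0.5, conf = 0.95) {
  pct <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n_sessions)
    vapply(seeds, function(s) {
      sq <- simulate_choice_sequence(
        agent_spec(p_alt = p_alt, n_entries = n_entries, seed = s))
      alternation_percentage(sq)$alternation_pct
    }, numeric(1))
  })
  m <- mean(pct)
  se <- stats::sd(pct) / sqrt(n_sessions)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(mean_pct = m, ci = c(m - z * se, m + z * se),
       sd_pct = stats::sd(pct), n_sessions = n_sessions)
}

#' Segment a trajectory into terminal-to-terminal trials with position bins
#'
#' A trial spans the movement away from the terminal of one arm to the
#' arrival at the terminal of the next entered arm. Along-path distance
#' (start terminal -> center -> end terminal) is divided into `n_bins`
#' equal bins; for symmetric arms the maze center falls on the bin 10|11
#' boundary. A trial is flagged `alternating` iff its end arm completes a
#' non-repeating triplet with the two preceding entries; the first two
#' entries have no such history and get `NA` (excluded from selectivity
#' contrasts but retained for position maps).
#'
#' @param traj A `trajectory`.
#' @param seq The matching `arm_entries` (e.g. from [detect_arm_entries()]).
#' @param geometry A [maze_geometry()].
#' @param n_bins Number of position bins (default 20).
#' @return An object of class `maze_trials`: list with `trials` (data.frame
#'   `trial`, `start_idx`, `end_idx`, `start_arm`, `end_arm`,
#'   `alternating`), and per-sample vectors `bin_index`, `trial_index`
#'   (NA outside trials), plus `frame_rate`.
#' @export
segment_trials <- function(traj, seq, geometry = attr(traj, "geometry"),
                           n_bins = 20L) {
  if (is.null(geometry)) geometry <- maze_geometry()
  stopifnot(inherits(seq, "arm_entries"), n_bins >= 2L)
  n_entry <- nrow(seq)
  if (n_entry < 2L) stop("need at least 2 entries to form a trial")
  xy <- as.matrix(traj[, c("x", "y")])
  t_s <- traj$time_s
  ns <- length(t_s)
  proj <- xy %*% t(geometry$directions)  # depth along each arm
  colnames(proj) <- geometry$arms
  entry_idx <- vapply(seq$time_s, function(tt) which.min(abs(t_s - tt)),
                      integer(1))
  bin_index <- rep(NA_integer_, ns)
  trial_index <- rep(NA_integer_, ns)
  res <- vector("list", n_entry - 1L)
  for (i in 2:n_entry) {
    a <- seq$arm[i - 1L]; b <- seq$arm[i]
    lo <- entry_idx[i - 1L]
    hi <- if (i < n_entry) entry_idx[i + 1L] - 1L else ns
    seg <- lo:hi
    # trial start: last sample at maximal depth in the start arm before
    # the entry into the end arm; trial end: first sample at maximal
    # depth in the end arm ("stopped at the terminal")
    pre <- seg[seg <= entry_idx[i]]
    da <- proj[pre, a]
    s_idx <- pre[max(which(da >= max(da) - 1e-9))]
    post <- seg[seg >= entry_idx[i]]
    db <- proj[post, b]
    e_idx <- post[min(which(db >= max(db) - 1e-9))]
    span <- s_idx:e_idx
    depth_a <- proj[span, a]; depth_b <- proj[span, b]
    d0 <- depth_a[1L]; d1 <- depth_b[length(span)]
    # along-path coordinate: out of arm a, then into arm b
    s_path <- ifelse(depth_a >= depth_b, d0 - depth_a, d0 + depth_b)
    s_path <- pmin(pmax(s_path, 0), d0 + d1)
    b_idx <- pmin(pmax(ceiling(s_path / (d0 + d1) * n_bins), 1L), n_bins)
    b_idx <- cummax(b_idx)   # bins are nondecreasing along the path
    bin_index[span] <- b_idx
    trial_index[span] <- i - 1L
    alt <- if (i >= 3L)
      length(unique(seq$arm[(i - 2L):i])) == 3L else NA
    res[[i - 1L]] <- data.frame(trial = i - 1L, start_idx = s_idx,
                                end_idx = e_idx, start_arm = a,
                                end_arm = b, alternating = alt)
  }
  structure(list(trials = do.call(rbind, res),
                 bin_index = bin_index, trial_index = trial_index,
                 n_bins = as.integer(n_bins),
                 frame_rate = attr(traj, "frame_rate") %||%
                   (1 / stats::median(diff(t_s)))),
            class = "maze_trials")
}

#' @export
print.maze_trials <- function(x, ...) {
  cat(sprintf("%d trials, %d bins, %d of %d alternating (%d unassessed)\n",
              nrow(x$trials), x$n_bins,
              sum(x$trials$alternating, na.rm = TRUE),
              sum(!is.na(x$trials$alternating)),
              sum(is.na(x$trials$alternating))))
  invisible(x)
}

#' Distance travelled per time bin
#'
#' Sums Euclidean step lengths of the body-center track within consecutive
#' time bins (default 5 min), the standard locomotion time course for
#' open-field / amphetamine assays.
#'
#' @param traj A `trajectory`.
#' @param bin_minutes Bin width in minutes.
#' @return Numeric vector, cm per bin (last bin may be partial).
#' @export
locomotion_timecourse <- function(traj, bin_minutes = 5) {
  check_pos(bin_minutes, "bin_minutes")
  n <- nrow(traj)
  if (n < 2L) return(numeric(0))
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  bin <- floor(traj$time_s[-1L] / (bin_minutes * 60)) + 1L
  as.numeric(tapply(step, factor(bin, levels = seq_len(max(bin))), sum,
                    default = 0))
}
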