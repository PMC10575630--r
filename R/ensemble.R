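# Position-binned ensemble analysis: trial-averaged activity maps,
# peak-proportion curves with bootstrap CIs, pre-center peaking and
# selectivity contrasts, stimulation time courses.

# Per-(trial, bin) mean activity for every neuron.
# Returns means (K x N), plus the trial and bin of each of the K keys.
trial_bin_means <- function(traces, trials) {
  traces <- as.matrix(traces)
  stopifnot(inherits(trials, "maze_trials"),
            nrow(traces) == length(trials$bin_index))
  ok <- !is.na(trials$trial_index)
  if (!any(ok)) stop("no trials")
  key <- interaction(trials$trial_index[ok], trials$bin_index[ok],
                     drop = TRUE)
  sums <- rowsum(traces[ok, , drop = FALSE], key)
  cnt <- as.vector(table(key))
  parts <- strsplit(rownames(sums), ".", fixed = TRUE)
  list(means = sums / cnt,
       trial = as.integer(vapply(parts, `[[`, character(1), 1L)),
       bin = as.integer(vapply(parts, `[[`, character(1), 2L)))
}

#' Trial-averaged position activity map
#'
#' For every neuron, dF/F0 is averaged within each of the position bins of
#' each trial, then averaged across trials (bins a trial never visited are
#' skipped for that trial). The per-neuron peak bin is the argmax across
#' bins, ties broken toward the lowest bin and flagged.
#'
#' @param traces T x N matrix of dF/F0 traces aligned to the trajectory
#'   samples (e.g. from [simulate_ensemble()] or [extract_trace()]).
#' @param trials A `maze_trials` object from [segment_trials()].
#' @return An object of class `position_activity_map`: `activity`
#'   (N x n_bins), `peak_bin`, `peak_tied` (logical), `n_trials_per_bin`.
#' @export
position_activity_map <- function(traces, trials) {
  tb <- trial_bin_means(traces, trials)
  n_bins <- trials$n_bins
  binf <- factor(tb$bin, levels = seq_len(n_bins))
  act <- t(rowsum(tb$means, binf) / as.vector(table(binf)))   # N x bins
  colnames(act) <- seq_len(n_bins)
  peak <- max.col(act, ties.method = "first")
  tied <- apply(act, 1L, function(r) sum(r == max(r)) > 1L)
  structure(list(activity = act, peak_bin = peak, peak_tied = tied,
                 n_trials_per_bin = as.vector(table(binf))),
            class = "position_activity_map")
}

#' @export
print.position_activity_map <- function(x, ...) {
  cat(sprintf("position activity map: %d neurons x %d bins\n",
              nrow(x$activity), ncol(x$activity)))
  invisible(x)
}

#' Proportion of neurons peaking at each maze position, with bootstrap CI
#'
#' `proportion[b]` is the fraction of neurons whose trial-averaged
#' activity peaks in bin `b` (sums to 1). The 95% CI is a seeded
#' percentile bootstrap over neurons.
#'
#' @param map A `position_activity_map` (or an integer vector of peak
#'   bins with attribute-free input via `n_bins`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @param n_bins Number of bins when `map` is a plain peak-bin vector.
#' @return A list of class `peak_proportion_curve`: `proportion`,
#'   `ci_low`, `ci_high`, `n_neurons`.
#' @export
peak_proportion_curve <- function(map, n_boot = 2000L, conf = 0.95,
                                  seed = 1, n_bins = 20L) {
  peak <- if (inherits(map, "position_activity_map")) map$peak_bin
          else as.integer(map)
  if (inherits(map, "position_activity_map")) n_bins <- ncol(map$activity)
  n <- length(peak)
  if (n == 0L) stop("no neurons", call. = FALSE)
  prop <- tabulate(peak, n_bins) / n
  bs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      tabulate(peak[sample.int(n, n, replace = TRUE)], n_bins) / n
    }, numeric(n_bins))
  })
  a <- (1 - conf) / 2
  structure(list(proportion = prop,
                 ci_low = apply(bs, 1L, stats::quantile, probs = a),
                 ci_high = apply(bs, 1L, stats::quantile, probs = 1 - a),
                 n_neurons = n),
            class = "peak_proportion_curve")
}

#' Compare the proportion of pre-center-peaking neurons between groups
#'
#' Builds the 2 x 2 table (peak inside vs outside the window) x group and
#' applies the Pearson chi-square test without continuity correction. The
#' default window, bins 8-10, is the stretch of track right before the
#' maze center on the 1..20 start-to-end axis.
#'
#' @param map_a,map_b `position_activity_map`s (or peak-bin vectors) for
#'   the two groups.
#' @param window Integer bin window (default `8:10`).
#' @return A `test_result` (see [chi_square()]) with the contingency
#'   table attached as attribute `table`.
#' @export
compare_precenter_peaking <- function(map_a, map_b, window = 8:10) {
  pk <- function(m) if (inherits(m, "position_activity_map")) m$peak_bin else m
  a <- pk(map_a); b <- pk(map_b)
  tab <- rbind(A = c(inside = sum(a %in% window), outside = sum(!a %in% window)),
               B = c(inside = sum(b %in% window), outside = sum(!b %in% window)))
  res <- chi_square(tab)
  attr(res, "table") <- tab
  res
}

#' Alternation-selectivity map
#'
#' For each neuron, the activity difference between alternating and
#' non-alternating trials is computed at each track position
#' (`diff[n, b]` = mean over alternating trials - mean over
#' non-alternating trials of bin-b activity). A neuron is
#' alternation-selective at position `b` when that difference exceeds the
#' mean of the differences at all other positions by more than `sd_mult`
#' (default 2) standard deviations of those other-position differences.
#' The criterion is one-sided ("higher than"). Neurons with fewer than
#' `min_trials` trials of either type are marked not assessable.
#'
#' @param traces T x N dF/F0 matrix aligned to the trajectory.
#' @param trials A `maze_trials`; trials with undefined alternation status
#'   (the first two entries) are excluded from the contrast.
#' @param sd_mult SD multiplier of the criterion (default 2).
#' @param min_trials Minimum trials per type (default 3).
#' @return An object of class `selectivity_map`: `diff` (N x bins),
#'   `selective` (N x bins logical, NA rows for non-assessable neurons),
#'   `assessable` (logical N).
#' @export
alternation_selectivity <- function(traces, trials, sd_mult = 2,
                                    min_trials = 3L) {
  tb <- trial_bin_means(traces, trials)
  n_bins <- trials$n_bins
  alt_of_trial <- trials$trials$alternating[tb$trial]
  use <- !is.na(alt_of_trial)
  n_alt <- length(unique(tb$trial[use & alt_of_trial]))
  n_non <- length(unique(tb$trial[use & !alt_of_trial]))
  N <- ncol(tb$means)
  assessable <- rep(n_alt >= min_trials && n_non >= min_trials, N)
  if (!assessable[1L]) {
    return(structure(list(diff = matrix(NA_real_, N, n_bins),
                          selective = matrix(NA, N, n_bins),
                          assessable = assessable,
                          n_alt_trials = n_alt, n_nonalt_trials = n_non),
                     class = "selectivity_map"))
  }
  mean_by_bin <- function(rows) {
    binf <- factor(tb$bin[rows], levels = seq_len(n_bins))
    t(rowsum(tb$means[rows, , drop = FALSE], binf) /
        as.vector(table(binf)))
  }
  dif <- mean_by_bin(which(use & alt_of_trial)) -
    mean_by_bin(which(use & !alt_of_trial))          # N x bins
  sel <- matrix(NA, N, n_bins)
  if (assessable[1L]) {
    for (b in seq_len(n_bins)) {
      oth <- dif[, -b, drop = FALSE]
      mu <- rowMeans(oth)
      sdo <- apply(oth, 1L, stats::sd)
      sel[, b] <- dif[, b] - mu > sd_mult * sdo
    }
  }
  structure(list(diff = dif, selective = sel, assessable = assessable,
                 n_alt_trials = n_alt, n_nonalt_trials = n_non),
            class = "selectivity_map")
}

#' Compare proportions of alternation-selective neurons between groups
#'
#' Counts neurons selective at any position inside `window` (among
#' assessable neurons) per group and applies the Pearson chi-square test.
#'
#' @param sel_a,sel_b `selectivity_map`s for the two groups.
#' @param window Integer bin window (default `8:10`); must be non-empty.
#' @return A `test_result` with the 2 x 2 table as attribute `table`.
#' @export
compare_selective_proportions <- function(sel_a, sel_b, window = 8:10) {
  if (length(window) == 0L) stop("empty bin window", call. = FALSE)
  cnt <- function(s) {
    m <- s$selective[s$assessable, window, drop = FALSE]
    hit <- apply(m, 1L, any)
    c(selective = sum(hit, na.rm = TRUE), other = sum(!hit, na.rm = TRUE))
  }
  tab <- rbind(A = cnt(sel_a), B = cnt(sel_b))
  res <- chi_square(tab)
  attr(res, "table") <- tab
  res
}

#' Stimulation-response dF/F time course
#'
#' For frame-mean fluorescence series from stimulation imaging: F0 is the
#' average of the first `baseline_s` seconds, dF/F = (Ft - F0)/F0, and
#' the response summary is the peak dF/F inside `response_window_s`
#' (stimulus onset at `stim_onset_s`).
#'
#' @param frame_means Numeric series of frame-mean fluorescence.
#' @param frame_rate Hz (the assay uses 1/0.351 s frames).
#' @param baseline_s Baseline window, s (default 15).
#' @param stim_onset_s Stimulus time, s (default 20).
#' @param response_window_s Window for the peak response (default
#'   `c(20, 40)`).
#' @return A list of class `stim_timecourse`: `time_s`, `dff`, `f0`,
#'   `peak_dff`, `stim_onset_s`.
#' @export
stim_timecourse <- function(frame_means, frame_rate,
                            baseline_s = 15, stim_onset_s = 20,
                            response_window_s = c(20, 40)) {
  n <- length(frame_means)
  nb <- floor(baseline_s * frame_rate)
  if (n < nb) stop("series shorter than the baseline window", call. = FALSE)
  f0 <- mean(frame_means[seq_len(nb)])
  if (f0 == 0) stop("zero baseline fluorescence")
  tt <- (seq_len(n) - 1L) / frame_rate
  dff <- (frame_means - f0) / f0
  win <- tt >= response_window_s[1L] & tt <= response_window_s[2L]
  structure(list(time_s = tt, dff = dff, f0 = f0,
                 peak_dff = if (any(win)) max(dff[win]) else NA_real_,
                 stim_onset_s = stim_onset_s),
            class = "stim_timecourse")
}

#' Fractional change in spontaneous-activity SD
#'
#' The overall-activity metric for actuator validation: each epoch is
#' summarized by the SD of its spontaneous dF/F trace and the change is
#' `(SD2 - SD1) / SD1` (reported as a percentage when multiplied by 100).
#'
#' @param trace_pre,trace_post Spontaneous activity traces before/after
#'   treatment.
#' @return Dimensionless fraction.
#' @export
activity_change <- function(trace_pre, trace_post) {
  sd1 <- stats::sd(trace_pre)
  if (is.na(sd1) || sd1 == 0) stop("SD of the pre epoch is zero",
                                   call. = FALSE)
  (stats::sd(trace_post) - sd1) / sd1
}
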