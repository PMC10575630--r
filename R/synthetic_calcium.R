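# Synthetic calcium data: position-tuned GCaMP6s-like traces with ground
# truth, Gaussian footprints, and rendered movies for the extraction stage.

#' Specification of a simulated position-tuned ensemble
#'
#' @param n_neurons Number of neurons.
#' @param peak_bin Integer vector (length `n_neurons`, values 1..20) of
#'   preferred position bins, or `NULL` to draw uniformly at random.
#' @param amp Transient peak amplitude in dF/F0 units (> 0).
#' @param selective Logical vector flagging neurons whose transient
#'   amplitude depends on trial type, or a single count of selective
#'   neurons (assigned to the first neurons); default none.
#' @param selective_gain Multiplicative amplitude factor applied on
#'   alternating trials for selective neurons (default 2). A gain of 1
#'   encodes no selectivity.
#' @param tau_rise,tau_decay Rise/decay time constants of the
#'   difference-of-exponentials transient kernel, s. Defaults 0.18 s and
#'   1.8 s give the fast-rising, slowly decaying GCaMP6s shape the event
#'   detector assumes; `tau_decay > tau_rise > 0` is required.
#' @param noise_sd Additive white Gaussian noise SD, dF/F0 units (>= 0).
#' @param event_rate_bg Position-independent background transient rate,
#'   events/min (default 2).
#' @param seed Integer seed.
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(n_neurons, peak_bin = NULL, amp = 1,
                        selective = FALSE, selective_gain = 2,
                        tau_rise = 0.18, tau_decay = 1.8,
                        noise_sd = 0.1, event_rate_bg = 2, seed = 1) {
  check_pos(amp, "amp")
  check_pos(tau_rise, "tau_rise")
  if (tau_decay <= tau_rise) stop("tau_decay must exceed tau_rise")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(event_rate_bg, "event_rate_bg", strict = FALSE)
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1L)
  if (is.numeric(selective) && length(selective) == 1L)
    selective <- seq_len(n_neurons) <= selective
  selective <- rep_len(as.logical(selective), n_neurons)
  if (!is.null(peak_bin)) {
    peak_bin <- rep_len(as.integer(peak_bin), n_neurons)
    stopifnot(all(peak_bin >= 1L))
  }
  structure(list(n_neurons = n_neurons, peak_bin = peak_bin, amp = amp,
                 selective = selective, selective_gain = selective_gain,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, event_rate_bg = event_rate_bg,
                 seed = seed),
            class = "tuning_spec")
}

#' Difference-of-exponentials calcium transient kernel
#'
#' `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)`, sampled at `frame_rate`
#' and normalized to unit peak, truncated at `5 * tau_decay`.
#'
#' @param tau_rise,tau_decay Time constants, s.
#' @param frame_rate Hz.
#' @return Numeric vector (kernel samples, first sample at t = 0).
#' @export
calcium_kernel <- function(tau_rise = 0.18, tau_decay = 1.8,
                           frame_rate = 30) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0, frame_rate > 0)
  t <- seq(0, 5 * tau_decay, by = 1 / frame_rate)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

#' Simulate position-tuned dF/F0 traces for a set of trials
#'
#' Each neuron fires one transient per trial, triggered at the first
#' sample where the animal occupies the neuron's `peak_bin`; selective
#' neurons scale the amplitude by `selective_gain` on alternating trials.
#' Background transients occur at `event_rate_bg` uniformly in time. All
#' impulses are convolved with the [calcium_kernel()] and white Gaussian
#' noise is added. Ground truth records every event and each neuron's
#' true peak bin and selectivity flag.
#'
#' @param trials A `maze_trials` object (per-sample bin occupancy).
#' @param tuning A [tuning_spec()].
#' @return A list of class `ensemble_sim`: `traces` (T x n_neurons matrix,
#'   attribute `frame_rate`), `ground_truth` (list with `events`
#'   data.frame, `peak_bin`, `selective`), and `kernel`.
#' @export
simulate_ensemble <- function(trials, tuning) {
  stopifnot(inherits(trials, "maze_trials"), inherits(tuning, "tuning_spec"))
  n_t <- length(trials$bin_index)
  if (n_t == 0L || nrow(trials$trials) == 0L) stop("empty trials")
  fps <- trials$frame_rate
  n_bins <- trials$n_bins
  kern <- calcium_kernel(tuning$tau_rise, tuning$tau_decay, fps)
  nk <- length(kern)
  # transient onset leads the tuned bin by the kernel time-to-peak, so
  # the fluorescence maximum falls at the neuron's preferred position
  tau_peak <- log(tuning$tau_decay / tuning$tau_rise) /
    (1 / tuning$tau_rise - 1 / tuning$tau_decay)
  lead <- round(tau_peak * fps)
  with_seed(tuning$seed, {
    peak_bin <- tuning$peak_bin %||% sample.int(n_bins, tuning$n_neurons,
                                                replace = TRUE)
    # first sample of each (trial, bin) occupancy
    n_trials <- nrow(trials$trials)
    onset_of <- matrix(NA_integer_, n_trials, n_bins)
    ok <- !is.na(trials$trial_index)
    idx <- which(ok)
    # column-major linear index into onset_of[trial, bin]
    key <- (trials$bin_index[ok] - 1L) * n_trials + trials$trial_index[ok]
    first <- !duplicated(key)
    onset_of[key[first]] <- idx[first]
    alt <- trials$trials$alternating
    traces <- matrix(0, n_t, tuning$n_neurons)
    ev <- vector("list", tuning$n_neurons)
    dur_min <- n_t / fps / 60
    for (n in seq_len(tuning$n_neurons)) {
      on_idx <- onset_of[, peak_bin[n]]
      tr_id <- which(!is.na(on_idx))
      on_idx <- pmax(1L, on_idx[tr_id] - lead)
      amp_n <- tuning$amp *
        ifelse(tuning$selective[n] & !is.na(alt[tr_id]) & alt[tr_id],
               tuning$selective_gain, 1)
      kind <- rep("tuned", length(on_idx))
      n_bg <- stats::rpois(1, tuning$event_rate_bg * dur_min)
      if (n_bg > 0) {
        bg_idx <- sample.int(n_t, n_bg)
        on_idx <- c(on_idx, bg_idx)
        amp_n <- c(amp_n, rep(tuning$amp, n_bg))
        kind <- c(kind, rep("background", n_bg))
        tr_id <- c(tr_id, rep(NA_integer_, n_bg))
      }
      x <- numeric(n_t)
      for (e in seq_along(on_idx)) {
        i0 <- on_idx[e]
        i1 <- min(n_t, i0 + nk - 1L)
        x[i0:i1] <- x[i0:i1] + amp_n[e] * kern[seq_len(i1 - i0 + 1L)]
      }
      traces[, n] <- x
      ev[[n]] <- if (length(on_idx)) {
        data.frame(neuron = n, onset_idx = on_idx, amplitude = amp_n,
                   kind = kind, trial = tr_id)
      }
    }
    if (tuning$noise_sd > 0)
      traces <- traces + matrix(stats::rnorm(length(traces),
                                             sd = tuning$noise_sd),
                                nrow = n_t)
    attr(traces, "frame_rate") <- fps
    structure(list(traces = traces,
                   ground_truth = list(events = do.call(rbind, ev),
                                       peak_bin = peak_bin,
                                       selective = tuning$selective),
                   kernel = kern),
              class = "ensemble_sim")
  })
}

#' Compact Gaussian spatial footprints
#'
#' Places `n` truncated Gaussian footprints (unit peak) on a jittered grid
#' so they are disjoint or weakly overlapping.
#'
#' @param n Number of footprints.
#' @param dim_hw Image dimensions `c(H, W)`.
#' @param sigma_px Footprint SD, pixels.
#' @param margin Border kept free of centers, pixels.
#' @param seed Integer seed.
#' @return List: `footprints` (H x W x n array), `centers` (n x 2 matrix,
#'   row/col).
#' @export
gaussian_footprints <- function(n, dim_hw = c(64, 64), sigma_px = 3,
                                margin = 10, seed = 1) {
  stopifnot(n >= 1, all(dim_hw > 2 * margin))
  with_seed(seed, {
    g <- ceiling(sqrt(n))
    rs <- seq(margin, dim_hw[1] - margin, length.out = g)
    cs <- seq(margin, dim_hw[2] - margin, length.out = g)
    grid <- expand.grid(r = rs, c = cs)[seq_len(n), , drop = FALSE]
    grid <- grid + matrix(stats::runif(2 * n, -1, 1), ncol = 2)
    fp <- array(0, c(dim_hw, n))
    rr <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
    cc <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
    for (i in seq_len(n)) {
      d2 <- (rr - grid$r[i])^2 + (cc - grid$c[i])^2
      f <- exp(-d2 / (2 * sigma_px^2))
      f[d2 > (3 * sigma_px)^2] <- 0
      fp[, , i] <- f
    }
    list(footprints = fp, centers = as.matrix(grid))
  })
}

#' Render a movie from footprints and traces
#'
#' Each frame is `baseline + sum_i footprint_i * trace_i(t)`, optionally
#' attenuated by a static dark vessel shadow and corrupted by white
#' Gaussian noise. Noise-free, the time-mean of each pixel equals the
#' footprint-weighted mean of the traces plus the (possibly shadowed)
#' baseline, i.e. the renderer conserves flux.
#'
#' @param footprints H x W x N array of nonnegative spatial footprints.
#' @param traces T x N matrix of dF/F0-scale temporal signals.
#' @param baseline Constant background fluorescence (default 100, so
#'   F0 > 0 everywhere).
#' @param noise_sd Per-pixel Gaussian noise SD (in baseline units).
#' @param vessel_mask Optional H x W logical mask of vessel pixels.
#' @param vessel_atten Fractional darkening of masked pixels (default 0.6).
#' @param frame_rate Hz, stored as an attribute.
#' @param seed Seed for the noise.
#' @return H x W x T array of class `calcium_movie` with attributes
#'   `frame_rate` and `baseline`.
#' @export
render_movie <- function(footprints, traces, baseline = 100, noise_sd = 0,
                         vessel_mask = NULL, vessel_atten = 0.6,
                         frame_rate = 30, seed = 1) {
  d <- dim(footprints)
  if (length(d) == 2L) { footprints <- array(footprints, c(d, 1L)); d <- dim(footprints) }
  traces <- as.matrix(traces)
  if (d[3L] != ncol(traces))
    stop("footprint/trace count mismatch", call. = FALSE)
  P <- d[1L] * d[2L]
  fp_mat <- matrix(footprints, nrow = P)
  frames <- baseline + fp_mat %*% t(traces)      # P x T
  if (!is.null(vessel_mask)) {
    stopifnot(identical(dim(vessel_mask), d[1:2]))
    frames <- frames * (1 - vessel_atten * as.numeric(vessel_mask))
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(seed,
      matrix(stats::rnorm(length(frames), sd = noise_sd), nrow = P))
  }
  movie <- array(frames, c(d[1:2], nrow(traces)))
  attr(movie, "frame_rate") <- frame_rate
  attr(movie, "baseline") <- baseline
  class(movie) <- "calcium_movie"
  movie
}
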