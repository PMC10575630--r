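# Synthetic Y-maze behavior: biased arm-choice agent and continuous
# trajectories, with ground truth for every downstream behavioral stage.

#' Specification of a simulated Y-maze agent
#'
#' @param p_alt Probability in `[0, 1]` of choosing the non-recent ("new")
#'   arm at each decision point. 0.5 reproduces random exploration, for
#'   which the expected spontaneous alternation is 50%.
#' @param n_entries Number of arm entries to simulate (>= 3; the triplet
#'   alternation score is undefined below 3 entries).
#' @param speed Running speed along the maze axis, cm/s.
#' @param pause_s Dwell time at each arm terminal, s.
#' @param seed Integer seed; every generator in the package is
#'   bit-reproducible given its seed.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(p_alt = 0.5, n_entries = 30, speed = 10,
                       pause_s = 1, seed = 1) {
  check_prob(p_alt, "p_alt")
  if (!is.numeric(n_entries) || n_entries < 3)
    stop("sequence too short for alternation: n_entries must be >= 3",
         call. = FALSE)
  check_pos(speed, "speed")
  check_pos(pause_s, "pause_s", strict = FALSE)
  structure(list(p_alt = p_alt, n_entries = as.integer(n_entries),
                 speed = speed, pause_s = pause_s, seed = seed),
            class = "agent_spec")
}

#' Simulate a sequence of Y-maze arm choices
#'
#' The agent never re-enters the arm it just exited, so at every decision
#' point exactly two arms are available: the arm visited before the current
#' one ("old") and the remaining arm ("new"). The new arm is chosen with
#' probability `p_alt`; the very first choice (no history) is uniform over
#' the two available arms. With `p_alt = 0.5` each triplet of consecutive
#' entries is non-repeating with probability exactly 1/2, so the expected
#' alternation percentage is 50%.
#'
#' @param spec An [agent_spec()].
#' @param start_arm Label of the arm the animal is placed in (default the
#'   first arm of the geometry).
#' @param geometry A [maze_geometry()].
#' @return An `arm_entries` object (see [arm_entries()]); entry times are
#'   derived from `speed`/`pause_s` as the times the agent reaches each
#'   terminal.
#' @examples
#' simulate_choice_sequence(agent_spec(p_alt = 1, n_entries = 6, seed = 1))
#' @export
simulate_choice_sequence <- function(spec, start_arm = NULL,
                                     geometry = maze_geometry()) {
  stopifnot(inherits(spec, "agent_spec"))
  arms <- geometry$arms
  start_arm <- start_arm %||% arms[1L]
  if (!start_arm %in% arms) stop("unknown start arm")
  n <- spec$n_entries
  with_seed(spec$seed, {
    entries <- character(n)
    entries[1L] <- start_arm
    for (i in 2:n) {
      avail <- setdiff(arms, entries[i - 1L])
      if (i == 2L) {
        entries[i] <- sample(avail, 1L)
      } else {
        old <- entries[i - 2L]
        new <- setdiff(avail, old)
        entries[i] <- if (stats::runif(1) < spec$p_alt) new else old
      }
    }
    # terminal-to-terminal transit time: depth out + depth in, plus dwell
    transit <- 2 * geometry$arm_length / spec$speed + spec$pause_s
    arm_entries(entries, entry_times = transit * (seq_len(n) - 1L))
  })
}

#' Simulate a continuous body-center trajectory from an entry sequence
#'
#' The body center runs at constant speed along the arm axes
#' (terminal -> center -> next terminal), dwelling `pause_s` at each
#' terminal, sampled at `1/dt` Hz. The path is exact (no jitter), so
#' [detect_arm_entries()] recovers the generating sequence and the
#' built-in odometer equals the summed step lengths.
#'
#' @param seq An `arm_entries` object giving the order of terminals visited.
#' @param geometry A [maze_geometry()].
#' @param speed cm/s, must be > 0.
#' @param dt Sampling interval, s (default 1/30 to match 30 Hz video).
#' @param pause_s Dwell at each terminal, s.
#' @return A data.frame of class `trajectory` with columns `time_s`, `x`,
#'   `y` and attributes `frame_rate` and `geometry`.
#' @export
simulate_trajectory <- function(seq, geometry = maze_geometry(),
                                speed = 10, dt = 1 / 30, pause_s = 1) {
  stopifnot(inherits(seq, "arm_entries"))
  if (dt <= 0) stop("dt must be > 0")
  if (speed <= 0) stop("agent never reaches terminal: speed must be > 0")
  arms <- seq$arm
  L <- geometry$arm_length
  term <- geometry$directions * L   # terminal coordinates per arm
  pts <- list(term[arms[1L], , drop = FALSE])
  dwell <- max(1L, round(pause_s / dt))
  # dwell at the start terminal, then leg-by-leg constant-speed motion
  path <- do.call(rbind, rep(pts, dwell))
  n_leg <- max(2L, ceiling(L / (speed * dt)))
  for (i in seq_along(arms)[-1L]) {
    a <- term[arms[i - 1L], ]
    b <- term[arms[i], ]
    f <- seq_len(n_leg) / n_leg
    out_leg <- cbind(a[1] * (1 - f), a[2] * (1 - f))       # to center
    in_leg <- cbind(b[1] * f, b[2] * f)                    # into next arm
    path <- rbind(path, out_leg, in_leg,
                  matrix(b, nrow = dwell, ncol = 2, byrow = TRUE))
  }
  traj <- data.frame(time_s = (seq_len(nrow(path)) - 1L) * dt,
                     x = path[, 1L], y = path[, 2L])
  attr(traj, "frame_rate") <- 1 / dt
  attr(traj, "geometry") <- geometry
  class(traj) <- c("trajectory", "data.frame")
  traj
}
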