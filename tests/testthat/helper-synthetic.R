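# Shared fixtures, all generated in code.

# Trace with transients of known amplitude at given onsets.
kernel_trace <- function(n, onsets, amp = 1, frame_rate = 30,
                         noise_sd = 0, seed = 1) {
  k <- calcium_kernel(frame_rate = frame_rate)
  x <- numeric(n)
  for (o in onsets) {
    i1 <- min(n, o + length(k) - 1L)
    x[o:i1] <- x[o:i1] + amp * k[seq_len(i1 - o + 1L)]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(n, sd = noise_sd)
  }
  x
}

# A small session: sequence -> trajectory -> entries -> trials.
small_session <- function(n_entries = 20, p_alt = 0.7, seed = 5) {
  sq <- simulate_choice_sequence(
    agent_spec(p_alt = p_alt, n_entries = n_entries, seed = seed))
  traj <- simulate_trajectory(sq)
  ent <- detect_arm_entries(traj)
  list(seq = sq, traj = traj, entries = ent,
       trials = segment_trials(traj, ent))
}

# Movie with sparse planted sources for extraction tests.
planted_movie <- function(n_src = 3, dim_hw = c(48, 48), n_frames = 900,
                          n_events = 5, noise_sd = 0, seed = 3) {
  fp <- gaussian_footprints(n_src, dim_hw, sigma_px = 3, seed = seed)
  set.seed(seed + 1)
  pool <- max(1L, n_frames - 300L)
  traces <- sapply(seq_len(n_src), function(i)
    kernel_trace(n_frames, sort(sample(pool, min(n_events, pool)))))
  movie <- render_movie(fp$footprints, traces, baseline = 100,
                        noise_sd = noise_sd, seed = seed + 2)
  list(movie = movie, footprints = fp, traces = traces)
}
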