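test_that("agent spec validates its invariants", {
  expect_error(agent_spec(p_alt = 1.2), "probability")
  expect_error(agent_spec(n_entries = 2), "too short")
  expect_error(simulate_trajectory(arm_entries(c("A", "B", "C")), speed = 0),
               "never reaches")
  expect_error(simulate_trajectory(arm_entries(c("A", "B")), dt = 0), "dt")
})

test_that("choice sequences honor the alternation bias", {
  full <- simulate_choice_sequence(agent_spec(p_alt = 1, n_entries = 6, seed = 1))
  expect_equal(alternation_percentage(full)$alternation_pct, 100)
  none <- simulate_choice_sequence(agent_spec(p_alt = 0, n_entries = 6, seed = 1))
  expect_equal(alternation_percentage(none)$alternation_pct, 0)
  # returns alternate strictly between two arms (ABAB style)
  expect_equal(length(unique(none$arm)), 2)
})

test_that("choice sequences never re-enter the exited arm and are reproducible", {
  for (i in 1:15) {
    sq <- simulate_choice_sequence(agent_spec(p_alt = 0.5, n_entries = 25, seed = i))
    expect_false(any(sq$arm[-1] == sq$arm[-nrow(sq)]))
  }
  a <- simulate_choice_sequence(agent_spec(seed = 99))
  b <- simulate_choice_sequence(agent_spec(seed = 99))
  expect_identical(a, b)
})

test_that("mean alternation converges to p_alt", {
  for (p in c(0.3, 0.7)) {
    pct <- sapply(1:200, function(i) {
      alternation_percentage(simulate_choice_sequence(
        agent_spec(p_alt = p, n_entries = 30, seed = 1000 + i)))$alternation_pct
    })
    # binomial CI on 200 * 28 triplet draws
    se <- sqrt(p * (1 - p) / (200 * 28)) * 100
    expect_lt(abs(mean(pct) - 100 * p), 4 * se)
  }
})

test_that("calcium kernel is fast-rising, slow-decaying, unit peak", {
  k <- calcium_kernel(0.18, 1.8, 30)
  expect_equal(max(k), 1)
  expect_lt(which.max(k), length(k) / 4)
  expect_error(calcium_kernel(1.8, 0.18), "tau_decay")
})

test_that("noise-free ensemble transients carry the planted amplitude", {
  s <- small_session(seed = 5)
  tn <- tuning_spec(1, peak_bin = 9, amp = 1.3, noise_sd = 0,
                    event_rate_bg = 0, seed = 2)
  sim <- simulate_ensemble(s$trials, tn)
  ev <- detect_events(sim$traces[, 1], 30)
  expect_gt(nrow(ev), 0)
  expect_lt(max(abs(ev$magnitude - 1.3)) / 1.3, 0.06)
  expect_error(simulate_ensemble(
    structure(list(bin_index = integer(0), trial_index = integer(0),
                   trials = data.frame(), n_bins = 20L, frame_rate = 30),
              class = "maze_trials"), tn), "empty")
})

test_that("selective gain scales amplitude on alternating trials only", {
  s <- small_session(seed = 5)
  tn <- tuning_spec(1, peak_bin = 9, amp = 1, selective = TRUE,
                    selective_gain = 2, noise_sd = 0, event_rate_bg = 0,
                    seed = 2)
  sim <- simulate_ensemble(s$trials, tn)
  ev <- sim$ground_truth$events
  alt <- s$trials$trials$alternating[ev$trial]
  expect_true(all(ev$amplitude[which(alt)] == 2))
  expect_true(all(ev$amplitude[which(!alt)] == 1))
})

test_that("random peak bins are uniform across the track", {
  s <- small_session(seed = 5)
  tn <- tuning_spec(400, noise_sd = 0.1, seed = 3)
  sim <- simulate_ensemble(s$trials, tn)
  gof <- chisq.test(tabulate(sim$ground_truth$peak_bin, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("rendered movies conserve flux and validate inputs", {
  pm <- planted_movie(n_src = 2, n_frames = 200)
  mu_pix <- apply(pm$movie, c(1, 2), mean)
  fp_mat <- matrix(pm$footprints$footprints, ncol = 2)
  expected <- 100 + matrix(fp_mat %*% colMeans(pm$traces), 48, 48)
  expect_equal(mu_pix, expected, tolerance = 1e-10)
  expect_error(render_movie(pm$footprints$footprints, pm$traces[, 1, drop = FALSE]),
               "mismatch")
})

test_that("histology phantoms validate inputs and blank cases", {
  expect_error(phantom_spec(bouton_density_per_100um = -1), "density")
  ph <- simulate_histology(phantom_spec(n_axons = 0, image_size = 128, seed = 1))
  expect_equal(ph$ground_truth$bouton_count, 0)
  expect_equal(ph$ground_truth$total_length_um, 0)
  ph2 <- simulate_histology(phantom_spec(n_axons = 2, image_size = 256, seed = 4))
  expect_gt(ph2$ground_truth$total_length_um, 0)
  expect_identical(ph2$red,
                   simulate_histology(phantom_spec(n_axons = 2, image_size = 256,
                                                   seed = 4))$red)
})
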