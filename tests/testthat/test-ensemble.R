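test_that("position maps peak at the planted tuning bin", {
  s <- small_session(n_entries = 25, seed = 5)
  tn <- tuning_spec(30, peak_bin = rep(c(5, 9, 14), 10), noise_sd = 0,
                    event_rate_bg = 0, seed = 2)
  sim <- simulate_ensemble(s$trials, tn)
  pm <- position_activity_map(sim$traces, s$trials)
  expect_true(all(abs(pm$peak_bin - sim$ground_truth$peak_bin) <= 1))
  expect_equal(ncol(pm$activity), 20)
})

test_that("constant neurons give flat rows with flagged ties", {
  s <- small_session(n_entries = 8, seed = 3)
  traces <- matrix(1, length(s$trials$bin_index), 2)
  pm <- position_activity_map(traces, s$trials)
  expect_true(all(pm$peak_bin == 1))
  expect_true(all(pm$peak_tied))
  expect_true(all(abs(pm$activity - 1) < 1e-12))
})

test_that("peak proportion curves sum to one with deterministic CIs", {
  pc <- peak_proportion_curve(rep(10L, 100), n_boot = 100, seed = 4)
  expect_equal(pc$proportion[10], 1)
  expect_equal(sum(pc$proportion), 1)
  set.seed(8)
  peaks <- sample.int(20, 400, replace = TRUE)
  c1 <- peak_proportion_curve(peaks, n_boot = 300, seed = 9)
  c2 <- peak_proportion_curve(peaks, n_boot = 300, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$ci_low <= c1$proportion + 1e-12))
  expect_true(all(c1$proportion <= c1$ci_high + 1e-12))
  # uniform planted peaks: the true 0.05 lies inside the 95% CI for all
  # but at most the expected handful of bins
  expect_gte(sum(c1$ci_low <= 0.05 & 0.05 <= c1$ci_high), 18)
  expect_error(peak_proportion_curve(integer(0)), "no neurons")
})

test_that("pre-center peaking contrast matches hand-computed chi-square", {
  same <- c(rep(9L, 30), rep(2L, 70))
  r0 <- compare_precenter_peaking(same, same)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  # groups building the table [[30,70],[10,90]]
  a <- c(rep(9L, 30), rep(2L, 70))
  b <- c(rep(9L, 10), rep(2L, 90))
  r <- compare_precenter_peaking(a, b)
  expect_equal(r$statistic, 12.5, tolerance = 1e-9)
  expect_equal(r$df, 1)
  r_swap <- compare_precenter_peaking(b, a)
  expect_equal(r_swap$statistic, r$statistic)
})

test_that("planted selective neurons are flagged; inverse gain is not", {
  s <- small_session(n_entries = 40, seed = 5)
  tn <- tuning_spec(40, peak_bin = rep(9, 40), selective = 20,
                    selective_gain = 2, noise_sd = 0.1, seed = 7)
  sim <- simulate_ensemble(s$trials, tn)
  sel <- alternation_selectivity(sim$traces, s$trials)
  expect_gte(mean(sel$selective[1:20, 9]), 0.9)
  # gain < 1 (suppression on alternating trials) must not trigger the
  # one-sided criterion at the tuned bin
  tn_inv <- tuning_spec(20, peak_bin = rep(9, 20), selective = 20,
                        selective_gain = 0.5, noise_sd = 0.1, seed = 8)
  sim_inv <- simulate_ensemble(s$trials, tn_inv)
  sel_inv <- alternation_selectivity(sim_inv$traces, s$trials)
  expect_lte(mean(sel_inv$selective[, 9]), 0.1)
})

test_that("neurons without enough trials of each type are not assessable", {
  s <- small_session(n_entries = 5, p_alt = 1, seed = 2)  # no non-alt trials
  tn <- tuning_spec(3, peak_bin = c(4, 9, 15), seed = 1)
  sim <- simulate_ensemble(s$trials, tn)
  sel <- alternation_selectivity(sim$traces, s$trials)
  expect_false(any(sel$assessable))
})

test_that("selective-proportion contrast validates the window", {
  s <- small_session(n_entries = 30, seed = 6)
  tn <- tuning_spec(20, peak_bin = rep(9, 20), selective = 10,
                    noise_sd = 0.1, seed = 3)
  sim <- simulate_ensemble(s$trials, tn)
  sel <- alternation_selectivity(sim$traces, s$trials)
  r <- compare_selective_proportions(sel, sel)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_error(compare_selective_proportions(sel, sel, window = integer(0)),
               "window")
})

test_that("stimulation time courses are baseline-anchored", {
  fps <- 1 / 0.351
  const <- stim_timecourse(rep(5, 115), fps)
  expect_true(all(const$dff == 0))
  f <- rep(10, 115)
  f[round(20 * fps):115] <- 15
  st <- stim_timecourse(f, fps)
  expect_equal(st$peak_dff, 0.5, tolerance = 1e-9)
  expect_equal(mean(st$dff[seq_len(floor(15 * fps))]), 0, tolerance = 1e-12)
  expect_error(stim_timecourse(rep(1, 10), fps), "baseline")
  # synthetic response kernel: peak recovered within 5%
  resp <- rep(10, 115)
  tt <- (seq_len(115) - 1) / fps
  resp <- resp + 3 * pmax(0, 1 - abs(tt - 25) / 4) * (tt > 20)
  st2 <- stim_timecourse(resp, fps)
  expect_lt(abs(st2$peak_dff - 0.3) / 0.3, 0.05)
})

test_that("activity change is the fractional SD change", {
  x <- sin(1:500 / 5)
  expect_equal(activity_change(x, x), 0)
  expect_equal(activity_change(x, 2 * x), 1, tolerance = 1e-12)
  expect_error(activity_change(rep(1, 10), x), "zero")
})
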