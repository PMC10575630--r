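test_that("t statistics are reconstructed from printed summaries", {
  r <- t_from_summary(group_summary(68.5, 2.5, 7), group_summary(59.5, 2.4, 7))
  expect_equal(r$statistic, 2.597, tolerance = 1e-3)
  expect_equal(r$df, 12)
  r2 <- t_from_summary(group_summary(82, 17, 6), group_summary(20, 14, 6))
  expect_equal(r2$statistic, 2.815, tolerance = 1e-3)
  expect_equal(r2$df, 10)
  same <- t_from_summary(group_summary(5, 1, 8), group_summary(5, 2, 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(group_summary(1, 1, 1), "n must be")
})

test_that("summary and raw-sample t tests agree on the same data", {
  set.seed(6)
  x <- rnorm(9, 1); y <- rnorm(9)
  raw <- t_from_samples(x, y)
  summ <- t_from_summary(group_summary(mean(x), sd(x) / 3, 9),
                         group_summary(mean(y), sd(y) / 3, 9))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_equal(t_from_samples(x, x)$statistic, 0)
  expect_error(t_from_samples(1, y), "n >= 2")
  # welch flavor has fractional df
  w <- t_from_samples(x, c(y, rnorm(20, 0, 3)), flavor = "welch")
  expect_equal(w$method, "welch_t")
})

test_that("planted shifts are detected with reasonable power", {
  sig <- sapply(1:40, function(i) {
    set.seed(i)
    t_from_samples(rnorm(20, 1), rnorm(20))$p < 0.05
  })
  expect_gte(mean(sig), 0.5)
})

test_that("type-I error of the t test is calibrated at 5%", {
  set.seed(42)
  p <- replicate(4000, t_from_samples(rnorm(8), rnorm(8))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("chi-square matches hand computation and symmetry", {
  r0 <- chi_square(rbind(c(50, 50), c(50, 50)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r <- chi_square(rbind(c(30, 70), c(10, 90)))
  expect_equal(r$statistic, 12.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_equal(chi_square(rbind(c(10, 90), c(30, 70)))$statistic, r$statistic)
  expect_error(chi_square(rbind(c(-1, 2), c(3, 4))), "negative")
  expect_warning(small <- chi_square(rbind(c(2, 8), c(7, 3))), "expected")
  expect_true(is.numeric(small$exact_p))
})

test_that("mixed ANOVA reports the group main effect with df (1, n-2)", {
  mk <- function(offset, seed) {
    set.seed(seed)
    expand.grid(subject = 1:12, time = 1:5) |>
      transform(group = ifelse(subject <= 6, "a", "b")) |>
      transform(value = rnorm(60, sd = 0.5) + offset * (group == "b") +
                  0.2 * time + rep(rnorm(12, sd = 0.5), 5))
  }
  r <- anova_stim_response(mk(2.5, 1))
  expect_equal(r$df, c(1, 10))
  expect_lt(r$p, 0.05)
  null <- anova_stim_response(mk(0, 2))
  expect_gt(null$p, 0.05)
  # F grows with the planted offset
  fs <- sapply(c(0.5, 2, 5), function(d) anova_stim_response(mk(d, 3))$statistic)
  expect_true(all(diff(fs) > 0))
  bad <- mk(1, 4)[-1, ]
  expect_error(anova_stim_response(bad), "unbalanced")
})

test_that("normality checks calibrate on Gaussian and reject exponential", {
  set.seed(9)
  p_norm <- replicate(40, normality_check(rnorm(50))$p)
  expect_gte(mean(p_norm > 0.05), 0.85)
  p_exp <- replicate(20, normality_check(rexp(50))$p)
  expect_gte(mean(p_exp < 0.05), 0.9)
  expect_error(normality_check(c(1, 2)), "n must be")
  expect_error(normality_check(rep(3, 10)), "degenerate")
})

test_that("reports round-trip through JSON", {
  empty <- build_report()
  f <- tempfile(fileext = ".json")
  write_report(empty, f)
  expect_equal(read_report(f)$results, setNames(list(), character(0)),
               ignore_attr = TRUE)
  rep <- build_report(
    results = list(alternation = list(mean_pct = 61.5, n = 9),
                   chi = unclass(chi_square(rbind(c(30, 70), c(10, 90))))),
    config = list(entry_frac = 0.33, skew_min = 1, bins = 20),
    seed = 7)
  write_report(rep, f)
  back <- read_report(f)
  expect_equal(back$results$alternation$mean_pct, 61.5)
  expect_equal(back$results$chi$statistic, 12.5)
  expect_equal(back$config$entry_frac, 0.33)
  expect_equal(back$seed, 7)
})
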