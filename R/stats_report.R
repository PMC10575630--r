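# Statistical battery: two-sample t tests (raw and summary-statistic
# forms), Pearson chi-square, mixed two-way ANOVA for stimulation time
# courses, Shapiro-Wilk normality, and report assembly.

#' Group summary (mean, SEM, n)
#'
#' The summary form in which group results are printed
#' (mean +/- SEM, n animals).
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Group size (>= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  check_pos(sem, "sem", strict = FALSE)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  invisible(x)
}

#' Two-sample t test from printed summary statistics
#'
#' Reconstructs the two-tailed t test from group means, SEMs and sizes.
#' The Student (pooled-variance) flavor recovers each group SD as
#' `sem * sqrt(n)` and uses `df = n_a + n_b - 2`; for equal group sizes
#' this reduces to `t = (m_a - m_b) / sqrt(sem_a^2 + sem_b^2)`. The Welch
#' flavor uses the same statistic with Welch-Satterthwaite df.
#'
#' @param a,b [group_summary()] objects.
#' @param flavor `"student"` (default, matches the printed dfs of the
#'   source analyses) or `"welch"`.
#' @return A `test_result`.
#' @examples
#' t_from_summary(group_summary(68.5, 2.5, 7), group_summary(59.5, 2.4, 7))
#' @export
t_from_summary <- function(a, b, flavor = c("student", "welch")) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  flavor <- match.arg(flavor)
  va <- a$sem^2 * a$n    # group variance
  vb <- b$sem^2 * b$n
  if (flavor == "student") {
    df <- a$n + b$n - 2L
    sp2 <- ((a$n - 1L) * va + (b$n - 1L) * vb) / df
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "student_t"
  } else {
    se2 <- a$sem^2 + b$sem^2
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / (a$sem^4 / (a$n - 1L) + b$sem^4 / (b$n - 1L))
    method <- "welch_t"
  }
  test_result(t, df, 2 * stats::pt(-abs(t), df), method)
}

#' Two-sample two-tailed t test from raw samples
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param flavor `"student"` (pooled) or `"welch"`.
#' @return A `test_result`; agrees with [t_from_summary()] applied to the
#'   samples' own summaries.
#' @export
t_from_samples <- function(x, y, flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = flavor == "student")
  test_result(ht$statistic, ht$parameter, ht$p.value,
              if (flavor == "student") "student_t" else "welch_t")
}

#' Pearson chi-square test on a count table
#'
#' No continuity correction (the source analyses pool hundreds of cells
#' per group). With any expected cell below 5 a warning is issued and,
#' for 2 x 2 tables, the Fisher exact p is attached as `exact_p`.
#'
#' @param table Matrix of nonnegative counts (2 x 2 or 2 x k).
#' @return A `test_result` with `df = (rows-1)(cols-1)`.
#' @examples
#' chi_square(rbind(c(30, 70), c(10, 90)))  # statistic 12.5, df 1
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  res <- test_result(ht$statistic, ht$parameter, ht$p.value, "chi_square")
  if (any(ht$expected < 5)) {
    warning("expected cell count below 5; attaching exact test as fallback")
    if (all(dim(table) == 2L))
      res$exact_p <- stats::fisher.test(table)$p.value
  }
  res
}

#' Group main effect of a mixed two-way ANOVA on stimulation time courses
#'
#' Mixed design with a between-subjects factor `group` (2 levels) and a
#' within-subjects factor `time`: each subject contributes one value per
#' timepoint. The group main effect is tested against the between-subject
#' error stratum, giving `df = (1, n_a + n_b - 2)` (F(1, 10) for 6
#' subjects per group).
#'
#' @param data Data.frame with columns `group`, `subject`, `time`,
#'   `value`; every subject must have a complete, identical time series
#'   (balanced within-subject design).
#' @return A `test_result` with `method = "anova_group_main"` and
#'   `df = c(1, n_subjects - 2)`.
#' @export
anova_stim_response <- function(data) {
  stopifnot(all(c("group", "subject", "time", "value") %in% names(data)))
  data$group <- factor(data$group)
  data$subject <- factor(data$subject)
  data$time <- factor(data$time)
  if (nlevels(data$group) != 2L) stop("exactly 2 groups required")
  tab <- table(data$subject, data$time)
  if (any(tab != 1L))
    stop("unbalanced within-subject series", call. = FALSE)
  fit <- stats::aov(value ~ group * time + Error(subject), data = data)
  s <- summary(fit)[["Error: subject"]][[1L]]
  rn <- trimws(rownames(s))
  g <- s[rn == "group", ]
  test_result(g[["F value"]], c(g[["Df"]], s[rn == "Residuals", "Df"]),
              g[["Pr(>F)"]], "anova_group_main")
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample, n >= 3; constant samples are degenerate and
#'   raise an error.
#' @return A `test_result` with the W statistic (`df = NA`).
#' @export
normality_check <- function(x) {
  if (length(x) < 3L) stop("n must be >= 3", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) sample; normality undefined", call. = FALSE)
  ht <- stats::shapiro.test(x)
  test_result(ht$statistic, NA_real_, ht$p.value, "shapiro_wilk")
}

#' Assemble a structured analysis report
#'
#' Bundles any set of results with the configuration, seeds and package
#' version used, as a JSON-serializable structure that round-trips
#' through [write_report()] / [read_report()].
#'
#' @param results Named list of results from any modules (may be empty).
#' @param config Named list of parameter values used (defaults and
#'   overrides); stored verbatim.
#' @param seed Seed(s) used for any stochastic step.
#' @return A list of class `mesoframe_report`.
#' @export
build_report <- function(results = list(), config = list(), seed = NULL) {
  structure(list(
    package = "mesoframe",
    version = as.character(utils::packageVersion("mesoframe")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    results = results
  ), class = "mesoframe_report")
}

#' @rdname build_report
#' @param report A `mesoframe_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(path)
}

#' @rdname build_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "mesoframe_report")
}
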