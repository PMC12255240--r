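#' Generate a two-way random-effects rating table
#'
#' Simulates `y_ijk = mu + s_i + r_j + e_ijk` with subject, rater and error
#' variance components, the design used for inter-/intra-rater reliability
#' studies (subjects x raters x repeats). The theoretical ICC(2,K) implied by
#' the planted components (K = raters x repeats treated as the averaged
#' ratings) is attached for recovery tests.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_raters Number of raters.
#' @param n_repeats Repeats per rater.
#' @param var_subject,var_rater,var_error Variance components (>= 0).
#' @param mean Grand mean of the measurements.
#' @param seed Integer seed.
#' @return A tibble (class `reliability_table`) with columns `subject`,
#'   `rater`, `repeat`, `value`; attribute `theoretical_icc`.
#' @export
generate_rating_table <- function(n_subjects, n_raters = 2, n_repeats = 3,
                                  var_subject = 9, var_rater = 0.25,
                                  var_error = 1, mean = 5, seed = 1L) {
  if (n_subjects < 2) abort("need at least 2 subjects")
  if (any(c(var_subject, var_rater, var_error) < 0)) abort("variances must be non-negative")
  set.seed(seed)
  s <- rnorm(n_subjects, 0, sqrt(var_subject))
  r <- rnorm(n_raters, 0, sqrt(var_rater))
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             rater = seq_len(n_raters),
                             `repeat` = seq_len(n_repeats))
  grid$value <- mean + s[grid$subject] + r[grid$rater] +
    rnorm(nrow(grid), 0, sqrt(var_error))

  K <- n_raters * n_repeats
  theo <- if (K == 1) {
    var_subject / (var_subject + var_rater + var_error)
  } else {
    # rater effects repeat across the K columns; plug expected mean squares
    # into the ICC(2,K) formula
    rater_term <- n_repeats * (n_raters - 1) / (K - 1) * var_rater
    K * var_subject / (K * var_subject + var_error + rater_term)
  }
  attr(grid, "theoretical_icc") <- theo
  class(grid) <- c("reliability_table", class(grid))
  grid
}

#' ICC(2,k) with confidence interval and SEM
#'
#' Two-way random-effects, absolute-agreement intraclass correlation for the
#' average of k ratings (Shrout-Fleiss ICC(2,k)), computed from the ANOVA
#' mean squares of the complete subjects x ratings grid:
#' `ICC(2,k) = (MS_subjects - MS_error) / (MS_subjects + (MS_ratings - MS_error)/n)`.
#' The single-measure ICC(2,1) is also reported. The 95% CI uses the
#' F-distribution bounds for the single-measure coefficient stepped up with
#' the Spearman-Brown relation. Measurement precision is
#' `SEM = SD x sqrt(1 - ICC)` with SD the standard deviation of all
#' measurements.
#'
#' @param table A `reliability_table` (long, columns `subject`, `value`, and
#'   `rater`/`repeat` or `rating`), or a numeric matrix subjects x ratings.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result` with elements `icc` (ICC(2,k)),
#'   `icc_single`, `ci95`, `sem`, `sd`, `n`, `k`, and the mean squares.
#' @export
icc_2k <- function(table, conf_level = 0.95) {
  m <- reliability_matrix(table)
  if (anyNA(m)) abort("incomplete rating grid: every subject needs every rating")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 ratings")

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong F-bounds for ICC(A,1), stepped up via Spearman-Brown
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (mse > 0 || msc > 0) {
    a <- (k * icc_1) / (n * (1 - icc_1))
    bq <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
    v <- (a * msc + bq * mse)^2 /
      ((a * msc)^2 / (k - 1) + (bq * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    sb <- function(x) k * x / (1 + (k - 1) * x)
    ci <- c(sb(lo1), sb(up1))
  } else {
    ci <- c(1, 1)  # perfect agreement grid
  }

  s_all <- sd(as.vector(m))
  sem <- if (icc_k <= 1) s_all * sqrt(max(0, 1 - icc_k)) else NA_real_
  structure(list(icc = icc_k, icc_single = icc_1, ci95 = ci, sem = sem,
                 sd = s_all, n = n, k = k,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 conf_level = conf_level),
            class = "icc_result")
}

reliability_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  tb <- as_tibble(table)
  if (!all(c("subject", "value") %in% names(tb))) {
    abort("table needs `subject` and `value` columns (or pass a matrix)")
  }
  if ("rating" %in% names(tb)) {
    key <- tb$rating
  } else if (all(c("rater", "repeat") %in% names(tb))) {
    key <- paste(tb$rater, tb[["repeat"]], sep = ".")
  } else if ("rater" %in% names(tb)) {
    key <- tb$rater
  } else {
    abort("table needs a `rating` column or `rater`(/`repeat`) columns")
  }
  wide <- tapply(tb$value, list(tb$subject, key), function(x) {
    if (length(x) != 1) NA_real_ else x
  })
  matrix(wide, nrow = nrow(wide), dimnames = dimnames(wide))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f  [%.3f, %.3f]  SEM = %.3f (n = %d)\n",
              x$k, x$icc, x$ci95[1], x$ci95[2], x$sem, x$n))
  invisible(x)
}

#' Standard error of measurement from SD and ICC
#' @param sd Standard deviation of the measurements.
#' @param icc Reliability coefficient (<= 1).
#' @return `sd * sqrt(1 - icc)`.
#' @export
#' @examples
#' sem_from_icc(3.0, 0.91)  # 0.9
sem_from_icc <- function(sd, icc) {
  if (any(icc > 1)) abort("ICC must be <= 1")
  sd * sqrt(1 - icc)
}

#' Cohen's d from group summaries
#'
#' Mean difference divided by the pooled standard deviation.
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return Cohen's d (signed, a minus b).
#' @export
#' @examples
#' cohens_d_summary(1.31, 0.19, 26, 1.28, 0.18, 26)
cohens_d_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) return(if (mean_a == mean_b) 0 else Inf * sign(mean_a - mean_b))
  (mean_a - mean_b) / sp
}

#' Normality/variance-gated two-group comparison
#'
#' Shapiro-Wilk normality tests on each group and a Levene (Brown-Forsythe,
#' median-centred) variance test across groups, both at alpha 0.05, gate the
#' test choice: a Mann-Whitney U test when either gate rejects, otherwise an
#' unpaired Student's t-test (equal variances) with the requested tails.
#' Cohen's d (mean difference over pooled SD) is always computed.
#'
#' @param a,b Numeric samples (n >= 3 each).
#' @param tails `"two"` or `"one"`.
#' @param alpha Significance level applied to the comparison itself.
#' @param direction For one-tailed tests, the alternative: `"greater"` tests
#'   `a > b`.
#' @return An object of class `group_comparison`.
#' @export
choose_and_run_test <- function(a, b, tails = c("two", "one"), alpha = 0.05,
                                direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  if (length(a) < 3 || length(b) < 3) abort("need at least 3 observations per group")

  shapiro_p <- vapply(list(a, b), function(x) {
    if (sd(x) == 0) return(0)  # a constant sample is treated as non-normal
    shapiro.test(x)$p.value
  }, numeric(1))
  levene_p <- brown_forsythe_p(a, b)
  normal_ok <- all(shapiro_p >= 0.05)
  var_ok <- is.na(levene_p) || levene_p >= 0.05

  alternative <- if (tails == "two") "two.sided" else direction
  d <- cohens_d_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))

  if (normal_ok && var_ok) {
    test <- if (tails == "two") "t_two_tailed" else "t_one_tailed"
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      t.test(a, b, alternative = alternative, var.equal = TRUE)$p.value
    }
  } else {
    test <- "mann_whitney"
    p <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                      exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(
    test = test, p = p, cohens_d = d, alpha = alpha,
    significant = p < alpha,
    shapiro_p = shapiro_p, levene_p = levene_p,
    groups = tibble(group = c("a", "b"), n = c(length(a), length(b)),
                    mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b))),
    tails = tails, direction = direction
  ), class = "group_comparison")
}

# Levene's test, Brown-Forsythe variant: one-way ANOVA on absolute
# deviations from the group medians
brown_forsythe_p <- function(a, b) {
  z <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (sd(z) == 0) return(NA_real_)
  stats::anova(aov(z ~ g))[["Pr(>F)"]][1]
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g, Cohen's d = %.3f (%s at alpha = %.4g)\n",
              x$test, x$p, x$cohens_d,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Two-group comparison from printed summary statistics
#'
#' Student's t-test and Cohen's d computed from group means, SDs and sizes
#' only, for re-analysing reported summaries.
#'
#' @inheritParams cohens_d_summary
#' @param tails `"two"` or `"one"` (one-tailed tests `a > b`).
#' @return A tibble with `t`, `df`, `p`, `cohens_d`.
#' @export
compare_groups_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                   tails = c("two", "one")) {
  tails <- match.arg(tails)
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  se <- sp * sqrt(1 / n_a + 1 / n_b)
  tt <- (mean_a - mean_b) / se
  df <- n_a + n_b - 2
  p <- if (tails == "two") 2 * pt(-abs(tt), df) else pt(tt, df, lower.tail = FALSE)
  tibble(t = tt, df = df, p = p,
         cohens_d = cohens_d_summary(mean_a, sd_a, n_a, mean_b, sd_b, n_b))
}

#' Bonferroni-corrected significance level
#'
#' Divides the family-wise alpha by the number of tests; the reported value
#' is rounded to 4 decimals (0.05/18 reports as 0.0028).
#'
#' @param family_alpha Family-wise alpha.
#' @param n_tests Number of tests in the family.
#' @return A tibble with `family_alpha`, `n_tests`, `alpha_corrected`
#'   (exact) and `alpha_reported` (rounded to 4 decimals).
#' @export
#' @examples
#' bonferroni_alpha(0.05, 18)
bonferroni_alpha <- function(family_alpha = 0.05, n_tests = 18) {
  if (family_alpha <= 0 || family_alpha >= 1) abort("family_alpha must be in (0, 1)")
  if (n_tests < 1) abort("n_tests must be >= 1")
  exact <- family_alpha / n_tests
  tibble(family_alpha = family_alpha, n_tests = as.integer(n_tests),
         alpha_corrected = exact, alpha_reported = round(exact, 4))
}

#' Power of an unpaired two-sample t-test at effect size d
#'
#' Noncentral-t power for equal group sizes: noncentrality
#' `ncp = d * sqrt(n/2)`, `df = 2n - 2`.
#'
#' @param d Cohen's d.
#' @param n_per_group Participants per group.
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(d, n_per_group, alpha = 0.05,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp)
  } else {
    q <- qt(1 - alpha / 2, df)
    1 - pt(q, df, ncp) + pt(-q, df, ncp)
  }
}

#' Smallest detectable effect size at a target power
#'
#' Solves (to 1e-6) for the Cohen's d at which an unpaired two-sample t-test
#' attains the target power, using the noncentral t distribution (not the
#' normal approximation).
#'
#' @param n_per_group Participants per group (>= 2).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return Cohen's d.
#' @export
#' @examples
#' smallest_detectable_effect(26, 0.8, 0.05, "one")
smallest_detectable_effect <- function(n_per_group, power, alpha = 0.05,
                                       tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_per_group < 2) abort("need at least 2 per group")
  f <- function(d) power_two_sample_t(d, n_per_group, alpha, tails) - power
  # at d = 0 the rejection rate is already alpha; powers at or below it
  # are attained by a null effect
  if (f(0) >= 0) return(0)
  upper <- 10
  if (f(upper) < 0) abort("target power unattainable at this sample size")
  uniroot(f, c(1e-9, upper), tol = 1e-8)$root
}
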