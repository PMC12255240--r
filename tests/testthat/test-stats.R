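test_that("ICC(2,k) equals the independent ANOVA oracle", {
  for (s in 1:5) {
    tb <- generate_rating_table(52, 2, 3, var_subject = 9, var_rater = 0.25,
                                var_error = 1, seed = s)
    m <- kneeload:::reliability_matrix(tb)
    expect_lt(abs(icc_2k(tb)$icc - icc_aov_oracle(m)), 1e-10)
  }
})

test_that("perfect agreement gives ICC 1 with zero SEM", {
  m <- matrix(rep(c(3, 5, 9, 11), 3), ncol = 3)
  r <- icc_2k(m)
  expect_equal(r$icc, 1)
  expect_equal(r$sem, 0)
  expect_equal(r$ci95, c(1, 1))
})

test_that("the SEM formula matches the printed convention", {
  expect_equal(sem_from_icc(3.0, 0.91), 0.9)
  expect_equal(sem_from_icc(2.0, 1), 0)
  expect_error(sem_from_icc(2, 1.2), "<= 1")
})

test_that("ICC confidence interval brackets the estimate and covers the truth", {
  tb <- generate_rating_table(52, 2, 3, var_subject = 9, var_rater = 0.25,
                              var_error = 1, seed = 3)
  r <- icc_2k(tb)
  expect_lt(r$ci95[1], r$icc)
  expect_gt(r$ci95[2], r$icc)
  covered <- vapply(1:100, function(s) {
    theo <- attr(tb, "theoretical_icc")
    ri <- icc_2k(generate_rating_table(30, 2, 3, 9, 0.25, 1, seed = s))
    ri$ci95[1] <= theo && theo <= ri$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("incomplete grids are rejected", {
  tb <- generate_rating_table(10, 2, 3, seed = 1)
  expect_error(icc_2k(tb[-1, ]), "incomplete")
})

test_that("tidy and glance return one-row summaries", {
  r <- icc_2k(generate_rating_table(20, 2, 3, seed = 2))
  expect_equal(nrow(tidy(r)), 1)
  expect_named(tidy(r), c("icc", "icc_single", "conf_low", "conf_high", "sem"))
  expect_equal(glance(r)$n_subjects, 20)
  cmp <- choose_and_run_test(rnorm(10), rnorm(10))
  expect_equal(nrow(tidy(cmp)), 1)
  expect_equal(glance(cmp)$n_a, 10)
})

test_that("identical samples compare as indistinguishable", {
  a <- c(1.1, 2.3, 0.8, 1.9, 1.5, 2.2)
  cmp <- choose_and_run_test(a, a)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$cohens_d, 0)
  expect_false(cmp$significant)
})

test_that("Cohen's d from printed summaries matches the pooled-SD formula", {
  expect_equal(cohens_d_summary(1.31, 0.19, 26, 1.28, 0.18, 26), 0.162,
               tolerance = 1e-3)
  out <- compare_groups_summary(2.97, 0.56, 26, 2.71, 0.37, 26, tails = "one")
  expect_equal(out$cohens_d, (2.97 - 2.71) /
                 sqrt((25 * 0.56^2 + 25 * 0.37^2) / 50))
  expect_lt(out$p, 0.05)
})

test_that("non-normal samples are routed to the Mann-Whitney test", {
  set.seed(7)
  a <- exp(rnorm(30, 0, 1))
  b <- exp(rnorm(30, 0.2, 1))
  cmp <- choose_and_run_test(a, b)
  expect_equal(cmp$test, "mann_whitney")
  expect_true(any(cmp$shapiro_p < 0.05))
})

test_that("unequal variances are routed to the Mann-Whitney test", {
  set.seed(8)
  a <- rnorm(40, 0, 1)
  b <- rnorm(40, 0, 6)
  cmp <- choose_and_run_test(a, b)
  expect_equal(cmp$test, "mann_whitney")
  expect_lt(cmp$levene_p, 0.05)
})

test_that("the Brown-Forsythe gate agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(9)
  a <- rnorm(25, 0, 1); b <- rnorm(25, 0, 2)
  p_pkg <- kneeload:::brown_forsythe_p(a, b)
  df <- data.frame(y = c(a, b), g = factor(rep(1:2, each = 25)))
  p_car <- car::leveneTest(y ~ g, df, center = median)[1, "Pr(>F)"]
  expect_equal(p_pkg, p_car, tolerance = 1e-10)
})

test_that("gated p-values are uniform under the null", {
  set.seed(123)
  p <- vapply(1:1000, function(i) {
    choose_and_run_test(rnorm(25), rnorm(25))$p
  }, numeric(1))
  # ties arise from the few null draws routed to the rank test
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Bonferroni correction divides and reports to 4 decimals", {
  out <- bonferroni_alpha(0.05, 18)
  expect_equal(out$alpha_reported, 0.0028)
  expect_equal(out$alpha_corrected, 0.05 / 18)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha_reported, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5)$alpha_reported, 0.01)
})

test_that("noncentral-t power calculations match the base-R oracle", {
  for (n in c(10, 26, 60)) {
    d <- smallest_detectable_effect(n, 0.8, 0.05, "one")
    oracle <- power.t.test(n = n, power = 0.8, sig.level = 0.05,
                           alternative = "one.sided")$delta
    expect_equal(d, oracle, tolerance = 1e-4)
  }
})

test_that("smallest detectable effect is monotone in n, alpha and power", {
  d26 <- smallest_detectable_effect(26, 0.8, 0.05, "one")
  expect_lt(smallest_detectable_effect(52, 0.8, 0.05, "one"), d26)
  expect_lt(smallest_detectable_effect(26, 0.8, 0.10, "one"), d26)
  expect_gt(smallest_detectable_effect(26, 0.9, 0.05, "one"), d26)
  expect_gt(smallest_detectable_effect(26, 0.8, 0.05, "two"), d26)
  # as the target power approaches the size of the test, d tends to zero
  expect_lt(smallest_detectable_effect(26, 0.0501, 0.05, "one"), 0.01)
  expect_error(smallest_detectable_effect(26, 1.2, 0.05), "in \\(0, 1\\)")
})
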