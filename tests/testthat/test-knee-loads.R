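test_that("the contact-force balance reproduces hand calculations", {
  # pure resultant: symmetric split across the two condyles
  expect_equal(mjcf_sample(0, -1000, 0, 0.05), 500)
  # adduction moment shifts load to the medial compartment
  expect_equal(mjcf_sample(0, -1000, -25, 0.05), 1000)
  # a knee muscle term adds medial load through its frontal-plane arm
  expect_equal(mjcf_sample(-12.5, -1000, 0, 0.05), 750)
  expect_error(mjcf_sample(0, -1000, 0, 0), "positive")
})

test_that("the balance is linear and monotone in the lever arm", {
  base <- mjcf_sample(-10, -800, -20, 0.05)
  expect_equal(mjcf_sample(-20, -1600, -40, 0.05), 2 * base)
  # larger condylar spacing reduces the moment-derived load
  expect_lt(mjcf_sample(-10, -800, -20, 0.06), base)
})

test_that("bodyweight and moment scaling behave dimensionally", {
  expect_equal(scale_by_bodyweight(1175.2, 587.6), 2)
  expect_equal(scale_by_bodyweight(0, 500), 0)
  expect_equal(scale_by_bodyweight(500, 500), 1)
  expect_error(scale_by_bodyweight(1, 0), "positive")
  expect_equal(scale_moment(50, 587.6, 1.628), 50 / (587.6 * 1.628))
  expect_equal(scale_moment(0, 700, 1.7), 0)
  expect_equal(scale_moment(50, 2 * 587.6, 1.628),
               scale_moment(50, 587.6, 1.628) / 2)
})

test_that("scaled MJCF is invariant when loads scale with bodyweight", {
  sub_small <- subject_profile("female", 1.63, 55, model = model)
  sub_large <- subject_profile("female", 1.63, 110, model = model)
  r <- sub_large$bw_n / sub_small$bw_n
  a <- scale_by_bodyweight(mjcf_sample(-10, -800, -20, 0.05), sub_small$bw_n)
  b <- scale_by_bodyweight(mjcf_sample(-10 * r, -800 * r, -20 * r, 0.05),
                           sub_large$bw_n)
  expect_equal(a, b, tolerance = 1e-12)
})

make_load_series <- function(mjcf, f_rjf = NULL) {
  n <- length(mjcf)
  out <- tibble::tibble(time = (0:(n - 1)) / 1000,
                        f_rjf = f_rjf %||% rep(-500, n),
                        tau_kam = 0, kfm = 0,
                        f_med_n = mjcf * 600, mjcf_bw = mjcf,
                        kam_bwht = mjcf / 50, kfm_bwht = mjcf / 40)
  class(out) <- c("joint_load_series", class(out))
  out
}

test_that("walking peaks split stance in half; other movements take one peak", {
  # symmetric double bump: equal peaks
  u <- seq(0, 1, length.out = 601)
  curve <- sin(pi * u) + 0.5 * sin(3 * pi * u)
  s <- make_load_series(curve)
  w <- phase_window_for_test(1, 601)
  pk <- extract_peaks(s, w, "walk")
  m <- pk[pk$variable == "mjcf_bw", ]
  expect_equal(m$value[m$peak == "peak1"], m$value[m$peak == "peak2"],
               tolerance = 1e-6)
  # monotone ramp: first peak at the midpoint, second at the end
  ramp <- seq(0, 1, length.out = 601)
  pk2 <- extract_peaks(make_load_series(ramp), w, "walk")
  m2 <- pk2[pk2$variable == "mjcf_bw", ]
  expect_equal(m2$value[m2$peak == "peak1"], ramp[301])
  expect_equal(m2$value[m2$peak == "peak2"], 1)
  # single maximum for non-walking movements
  pk3 <- extract_peaks(make_load_series(curve), w, "run_set")
  expect_equal(nrow(pk3), 3)
  expect_equal(pk3$value[pk3$variable == "mjcf_bw"], max(curve))
  # single-sample window returns that sample
  pk4 <- extract_peaks(make_load_series(curve), phase_window_for_test(10, 10),
                       "run_set")
  expect_equal(pk4$value[pk4$variable == "mjcf_bw"], curve[10])
})

test_that("walking peak extraction respects the stance portion of the stride", {
  trial <- generate_gait_trial(gait_trial_spec("walk", subject = female_subject(),
                                               seed = 12), model)
  sub <- attr(trial, "subject")
  loads <- compute_joint_loads(trial, sub, model)
  ev <- trial_ground_truth(trial)$heel_strikes
  wins <- extract_strides(ev, trial)
  pk <- extract_peaks(loads, wins[1, ], "walk")
  expect_equal(nrow(pk), 6)  # 3 variables x 2 peaks
  expect_true(all(pk$value > 0))
})

test_that("percent difference is symmetric and matches hand arithmetic", {
  expect_equal(percent_difference(2, 2), 0)
  expect_equal(percent_difference(2.2, 1.8), 20)
  expect_equal(percent_difference(1, 3), 100)
  expect_equal(percent_difference(1, 3), percent_difference(3, 1))
  expect_error(percent_difference(1, -1), "undefined")
})

test_that("subject profiles default to the cohort condylar geometry", {
  f <- subject_profile("female", 1.63, 60, model = model)
  m <- subject_profile("male", 1.75, 72, model = model)
  expect_equal(f$d_hat_cm, 4.86)
  expect_equal(m$d_hat_cm, 5.53)
  expect_equal(f$bw_n, 60 * 9.81)
  s <- subject_profile("female", 1.63, 60, d_cm = 4.5, model = model)
  expect_equal(s$d_hat_cm, 4.5 * model$condylar_ratio$female)
})
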