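test_that("generators are deterministic under a fixed seed", {
  s <- gait_trial_spec("walk", subject = female_subject(), seed = 42,
                       noise_sd = 3)
  t1 <- generate_gait_trial(s, model)
  t2 <- generate_gait_trial(s, model)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  s2 <- sts_trial_spec(noise_sd = 5, seed = 9)
  expect_identical(as.data.frame(generate_sts_trace(s2)),
                   as.data.frame(generate_sts_trace(s2)))

  r1 <- generate_rating_table(10, 2, 3, seed = 4)
  r2 <- generate_rating_table(10, 2, 3, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  t3 <- generate_gait_trial(gait_trial_spec("walk", subject = female_subject(),
                                            seed = 43, noise_sd = 3), model)
  expect_false(identical(t1$fz, t3$fz))
})

test_that("noise-free moments satisfy moment closure against the planted forces", {
  trial <- generate_gait_trial(gait_trial_spec("walk", subject = male_subject(),
                                               seed = 5), model)
  truth <- trial_ground_truth(trial)$muscle_forces
  sub <- attr(trial, "subject")
  hs <- model_height_scale(model, sub$gender)
  lhs <- moment_arm(model, "ankle", "gastrocnemius", trial$ankle_flex_angle,
                    sub$gender, hs) * truth$gastrocnemius +
    moment_arm(model, "ankle", "soleus", trial$ankle_flex_angle,
               sub$gender, hs) * truth$soleus
  expect_equal(lhs, trial$ankle_pf_moment, tolerance = 1e-12)
  lhs_hip <- moment_arm(model, "hip", "hamstrings", trial$hip_flex_angle,
                        sub$gender, hs) * truth$hamstrings +
    moment_arm(model, "hip", "gluteus_maximus", trial$hip_flex_angle,
               sub$gender, hs) * truth$gluteus_maximus
  expect_equal(lhs_hip, trial$hip_ext_moment, tolerance = 1e-12)
})

test_that("invalid gait specs are rejected", {
  expect_error(gait_trial_spec("walk", stride_duration_s = -1), "positive")
  expect_error(gait_trial_spec("hop"), "should be one of")
  expect_error(gait_trial_spec("walk", noise_sd = -2), "non-negative")
})

test_that("mean recovered quadriceps peak stays within 2% of planted under moment noise", {
  # 5 N m additive noise on the moment channels, 50 seeds; the 6 Hz
  # conditioning leaves the band-limited drive bumps intact, so the only
  # error left is the filtered noise at the peak sample
  ratio <- vapply(1:50, function(s) {
    trial <- generate_gait_trial(
      gait_trial_spec("walk", subject = female_subject(), seed = 100 + s,
                      noise_sd = 5), model)
    cond <- condition_trial(trial, "walk")
    rec <- reduce_muscle_forces(cond, attr(trial, "subject"), model)
    max(rec$quadriceps) / max(trial_ground_truth(trial)$muscle_forces$quadriceps)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.02)
})

test_that("sts traces reject unordered or cramped boundaries", {
  expect_error(sts_trial_spec(phase_boundaries = c(1, 300, 200, 400, 4000)),
               "strictly increasing")
  expect_error(sts_trial_spec(phase_boundaries = c(1, 2001, 3001, 5001, 5600)),
               "descent")
  expect_error(sts_trial_spec(bodyweight_n = -1), "positive")
})

test_that("returned true boundaries are strictly increasing", {
  for (s in 1:5) {
    gt <- trial_ground_truth(generate_sts_trace(sts_trial_spec(seed = s)))
    expect_true(all(diff(gt$true_boundaries) > 0))
  }
})

test_that("tile sets are exact crops with the stated geometry", {
  mu <- make_pseudo_ultrasound(900, 200, seed = 3)
  spec <- tile_set_spec(mu$image, 360, c(0, 250, 500), mu$landmarks, 80)
  ts <- generate_tile_set(spec)
  expect_identical(ts$tiles[[2]], mu$image[, 251:610])
  # planted landmarks 400 px apart at 80 px/cm measure 5 cm
  lm <- list(medial = c(100, 50), lateral = c(500, 50))
  spec2 <- tile_set_spec(mu$image, 360, c(0, 250, 500), lm, 80)
  expect_equal(generate_tile_set(spec2)$true_distance_cm, 5)
  expect_error(tile_set_spec(mu$image, 360, c(0, 300, 601), lm, 80), "overlap")
  expect_error(tile_set_spec(mu$image, 360, c(0, 250, 500),
                             list(c(2000, 50), c(10, 10)), 80), "inside")
})

test_that("rating tables carry the planted-component ICC", {
  # no disagreement at all: perfect reliability
  tb0 <- generate_rating_table(10, 2, 3, var_subject = 4, var_rater = 0,
                               var_error = 0, seed = 1)
  expect_equal(icc_2k(tb0)$icc, 1.0, tolerance = 1e-12)
  # single rater, three repeats: ICC(2,3) = 9 / (9 + 1/3)
  tb <- generate_rating_table(400, 1, 3, var_subject = 9, var_rater = 0,
                              var_error = 1, seed = 8)
  expect_equal(attr(tb, "theoretical_icc"), 9 / (9 + 1 / 3), tolerance = 1e-12)
  expect_equal(icc_2k(tb)$icc, 9 / (9 + 1 / 3), tolerance = 0.02)
  expect_error(generate_rating_table(1, 2, 3), "2 subjects")
  expect_error(generate_rating_table(10, 2, 3, var_subject = -1), "non-negative")
})

test_that("with no subject variance the estimated ICC concentrates near zero", {
  # the mean-square ratio estimator carries a small negative bias under the
  # null, shrinking with n; at n = 40 it sits well inside +/- 0.1
  est <- vapply(1:200, function(s) {
    icc_2k(generate_rating_table(40, 2, 1, var_subject = 0, var_rater = 0.2,
                                 var_error = 4, seed = s))$icc
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.1)
})
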