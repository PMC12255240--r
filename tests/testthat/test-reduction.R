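test_that("single-muscle distribution reduces to moment over arm", {
  f <- distribute_moment(50, arms = list(quadriceps = 0.05),
                         csa_cm2 = c(quadriceps = 180))
  expect_equal(f$quadriceps, 1000)
})

test_that("two muscles share CSA-proportionally and close the moment", {
  f <- distribute_moment(50, arms = list(a = 0.05, b = 0.05),
                         csa_cm2 = c(a = 60, b = 40))
  expect_equal(f$a, 600)
  expect_equal(f$b, 400)
  expect_equal(0.05 * f$a + 0.05 * f$b, 50)
})

test_that("antagonist-direction moments produce zero force and zero arms error", {
  f <- distribute_moment(-10, arms = list(a = 0.05, b = 0.04),
                         csa_cm2 = c(a = 60, b = 40))
  expect_equal(f$a, 0)
  expect_equal(f$b, 0)
  expect_error(distribute_moment(10, arms = list(a = 0), csa_cm2 = c(a = 60)),
               "zero moment arm")
})

test_that("quadriceps force balances demand plus co-contraction and clamps at zero", {
  expect_equal(quadriceps_force(40, list(), list(quadriceps = 0.04)), 1000)
  expect_equal(quadriceps_force(40, list(hamstrings = 500),
                                list(hamstrings = 0.03, quadriceps = 0.04)),
               1375)
  expect_equal(quadriceps_force(-40, list(hamstrings = 100),
                                list(hamstrings = 0.03, quadriceps = 0.04)),
               0)
  expect_error(quadriceps_force(40, list(), list(quadriceps = 0)), "nonzero")
})

test_that("ligament residuals resolve mutually exclusively by sign", {
  z <- ligament_forces(0, 0, model)
  expect_equal(unlist(z), c(ACL = 0, PCL = 0, MCL = 0, LCL = 0))
  a <- ligament_forces(100, 0, model)
  expect_equal(a$PCL, 0)
  expect_equal(a$ACL, 100 / cos(model$ligaments$ACL$orientation_deg * pi / 180))
  b <- ligament_forces(-80, -60, model)
  expect_equal(b$ACL, 0)
  expect_gt(b$PCL, 0)
  expect_equal(b$MCL, 0)
  expect_equal(b$LCL, 60 / cos(model$ligaments$LCL$orientation_deg * pi / 180))
})

test_that("noise-free trials round-trip through the reducer below 1e-9", {
  for (mv in c("walk", "run_selfselect")) {
    trial <- generate_gait_trial(gait_trial_spec(mv, subject = female_subject(),
                                                 seed = 17), model)
    truth <- trial_ground_truth(trial)$muscle_forces
    rec <- reduce_muscle_forces(trial, attr(trial, "subject"), model)
    for (m in names(truth)) {
      denom <- max(truth[[m]])
      expect_lt(max(abs(rec[[m]] - truth[[m]])) / denom, 1e-9)
    }
  }
})

test_that("moment closure holds at every sample of the reduced trial", {
  trial <- generate_gait_trial(gait_trial_spec("walk", subject = male_subject(),
                                               seed = 23), model)
  sub <- attr(trial, "subject")
  rec <- reduce_muscle_forces(trial, sub, model)
  hs <- model_height_scale(model, sub$gender)
  ankle_back <- moment_arm(model, "ankle", "gastrocnemius",
                           trial$ankle_flex_angle, sub$gender, hs) * rec$gastrocnemius +
    moment_arm(model, "ankle", "soleus", trial$ankle_flex_angle,
               sub$gender, hs) * rec$soleus
  pos <- trial$ankle_pf_moment > 0
  expect_equal(ankle_back[pos], trial$ankle_pf_moment[pos], tolerance = 1e-12)
})

test_that("gender variants change the distributed forces when coefficients differ", {
  trial <- generate_gait_trial(gait_trial_spec("walk", subject = female_subject(),
                                               seed = 31), model)
  f_f <- reduce_muscle_forces(trial, female_subject(), model)
  f_m <- reduce_muscle_forces(trial, male_subject(), model)
  expect_gt(max(abs(f_f$quadriceps - f_m$quadriceps)), 0)
})

test_that("all muscle and ligament forces are non-negative on synthetic trials", {
  for (s in c(2, 3)) {
    trial <- generate_gait_trial(gait_trial_spec("run_set",
                                                 subject = male_subject(),
                                                 noise_sd = 5, seed = s), model)
    cond <- condition_trial(trial, "run_set")
    rec <- reduce_muscle_forces(cond, male_subject(), model)
    expect_true(all(as.matrix(rec) >= 0))
  }
})
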