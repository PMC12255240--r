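#' Specification for a synthetic gait trial
#'
#' Describes one walking or running trial: movement class, stride timing,
#' sampling rates (1000 Hz kinetic, 200 Hz kinematic by default), the subject
#' whose bodyweight/gender drive the curves, additive channel noise, and the
#' seed. Curves are built from low-order sinusoid/raised-cosine bases whose
#' spectral content lies well below the conditioning filter cutoffs, so
#' filtering cannot distort the planted ground truth.
#'
#' @param movement One of `"walk"`, `"run_selfselect"`, `"run_set"`.
#' @param stride_duration_s Stride (heel strike to heel strike) duration, s.
#' @param rate_grf_hz Kinetic sampling rate, Hz.
#' @param rate_kin_hz Kinematic sampling rate, Hz (angles are generated on
#'   this clock, then linearly interpolated onto the kinetic clock).
#' @param subject A [subject_profile()].
#' @param n_strides Number of strides in the trial.
#' @param noise_sd Additive Gaussian noise SD. A scalar applies to force (N)
#'   and moment (N m) channels; a named vector sets per-channel SDs.
#' @param seed Integer seed; identical spec + seed gives identical trials.
#' @return A list of class `gait_trial_spec`.
#' @export
gait_trial_spec <- function(movement = c("walk", "run_selfselect", "run_set"),
                            stride_duration_s = NULL,
                            rate_grf_hz = 1000, rate_kin_hz = 200,
                            subject = subject_profile("female", 1.63, 60),
                            n_strides = 5L, noise_sd = 0, seed = 1L) {
  movement <- match.arg(movement)
  if (is.null(stride_duration_s)) {
    stride_duration_s <- if (movement == "walk") 1.10 else 0.72
  }
  if (stride_duration_s <= 0) abort("stride duration must be positive")
  if (rate_grf_hz <= 0 || rate_kin_hz <= 0) abort("sampling rates must be positive")
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")
  structure(list(movement = movement, stride_duration_s = stride_duration_s,
                 rate_grf_hz = rate_grf_hz, rate_kin_hz = rate_kin_hz,
                 subject = subject, n_strides = as.integer(n_strides),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gait_trial_spec")
}

# raised-cosine activation bump on stance phase u in [u0, u0 + w]
rc_bump <- function(u, u0, w) {
  inside <- u >= u0 & u <= u0 + w
  out <- numeric(length(u))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (u[inside] - u0) / w))
  out
}

#' Generate a synthetic gait trial with known muscle-force ground truth
#'
#' Plants smooth per-muscle force curves (CSA-proportional within each joint
#' group, so the reduction is exactly invertible) and constructs the net
#' ankle, hip and knee moments from them through the same moment-arm model
#' the reducer uses: `M(t) = sum_m r_m(theta_t) F_m(t)`. The vertical ground
#' reaction force crosses the 20 N contact threshold at known heel-strike
#' samples. With `noise_sd = 0` the generated moments and planted forces
#' satisfy moment closure at every sample to numerical precision.
#'
#' @param spec A [gait_trial_spec()].
#' @param model A `moment_arm_model` shared with the downstream reducer.
#' @return A `knee_trial` tibble. The planted ground truth (per-sample true
#'   muscle forces, heel-strike indices, stride duration, trial speed) is
#'   attached and retrievable with [trial_ground_truth()].
#' @export
#' @examples
#' trial <- generate_gait_trial(gait_trial_spec("walk", seed = 7))
#' trial_ground_truth(trial)$heel_strikes
generate_gait_trial <- function(spec, model = load_model_config()) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  set.seed(spec$seed)
  sub <- spec$subject
  bw <- sub$bw_n
  ht <- sub$height_m
  fs <- spec$rate_grf_hz
  Tst <- spec$stride_duration_s
  lead_in <- 0.3
  tail <- 0.3
  stance_frac <- if (spec$movement == "walk") 0.62 else 0.35
  run <- spec$movement != "walk"
  # include the closing heel strike: n strides span n+1 initial contacts
  n <- round((lead_in + (spec$n_strides + stance_frac) * Tst + tail) * fs)
  t <- (0:(n - 1)) / fs

  # stride phase s in [0,1) and stance phase u in [0,1); u = NA in swing
  s_ph <- (t - lead_in) / Tst
  in_gait <- s_ph >= 0 & s_ph < spec$n_strides + stance_frac
  frac <- ifelse(in_gait, s_ph - floor(s_ph), NA_real_)
  u <- ifelse(!is.na(frac) & frac < stance_frac, frac / stance_frac, NA_real_)
  uz <- ifelse(is.na(u), 0, u)
  in_stance <- !is.na(u)

  # vertical GRF: double bump (walk) or single bump (run)
  fz <- numeric(n)
  fz[in_stance] <- if (run) {
    2.3 * bw * sin(pi * uz[in_stance])
  } else {
    bw * (1.25 * sin(pi * uz[in_stance]) + 0.35 * sin(3 * pi * uz[in_stance]))
  }
  fy <- numeric(n)
  fy[in_stance] <- -(if (run) 0.25 else 0.15) * bw * sin(2 * pi * uz[in_stance])
  fx <- 0.05 * bw * sin(2 * pi * s_ph) * in_gait

  # band-limited angle curves on the kinematic clock, upsampled linearly
  tk <- seq(0, t[n], by = 1 / spec$rate_kin_hz)
  sk <- (tk - lead_in) / Tst
  upsample <- function(xk) approx(tk, xk, xout = t, rule = 2)$y
  hip_k <- 0.45 + 0.35 * sin(2 * pi * sk)
  knee_k <- 0.60 - 0.50 * cos(2 * pi * sk)
  kadd_k <- 0.05 * sin(2 * pi * sk)
  ank_k <- 0.20 * sin(2 * pi * sk + 1)
  hip_flex <- upsample(hip_k)
  knee_flex <- upsample(knee_k)
  knee_add <- upsample(kadd_k)
  ankle_flex <- upsample(ank_k)

  # CSA-proportional planted forces from per-group activation drives,
  # with mild trial-to-trial amplitude variability
  amp <- if (run) c(ankle = 14, hip = 9, quad = 14) else c(ankle = 8, hip = 5, quad = 8)
  amp <- amp * runif(3, 0.92, 1.08)
  drive_ankle <- rc_bump(uz, 0.35, 0.65) * in_stance * amp[["ankle"]]
  drive_hip <- rc_bump(uz, 0.00, 0.55) * in_stance * amp[["hip"]]
  drive_quad <- rc_bump(uz, 0.05, 0.60) * in_stance * amp[["quad"]]
  csa <- model$csa_cm2
  truth <- tibble(
    gastrocnemius = csa$gastrocnemius * drive_ankle,
    soleus = csa$soleus * drive_ankle,
    hamstrings = csa$hamstrings * drive_hip,
    gluteus_maximus = csa$gluteus_maximus * drive_hip,
    quadriceps = csa$quadriceps * drive_quad
  )

  # construct net moments through the shared moment-arm model
  hs <- model_height_scale(model, sub$gender)
  arm <- function(joint, muscle, angle) moment_arm(model, joint, muscle, angle,
                                                  sub$gender, hs)
  ankle_pf <- arm("ankle", "gastrocnemius", ankle_flex) * truth$gastrocnemius +
    arm("ankle", "soleus", ankle_flex) * truth$soleus
  hip_ext <- arm("hip", "hamstrings", hip_flex) * truth$hamstrings +
    arm("hip", "gluteus_maximus", hip_flex) * truth$gluteus_maximus
  knee_flex_m <- moment_arm(model, "knee", "quadriceps", knee_flex, sub$gender) *
    truth$quadriceps -
    moment_arm(model, "knee", "hamstrings", knee_flex, sub$gender) * truth$hamstrings -
    moment_arm(model, "knee", "gastrocnemius", knee_flex, sub$gender) * truth$gastrocnemius

  # external knee adduction moment: negative = adduction in the model frame
  kam_scale <- (if (run) 0.055 else 0.035) * runif(1, 0.9, 1.1)
  knee_add_m <- -kam_scale * bw * ht * sin(pi * uz) * in_stance

  pelvis_vz <- 0.12 * sin(4 * pi * s_ph)

  ideal_fz <- fz
  df <- tibble(
    time = t, fx = fx, fy = fy, fz = fz,
    hip_flex_angle = hip_flex, knee_flex_angle = knee_flex,
    knee_add_angle = knee_add, ankle_flex_angle = ankle_flex,
    hip_ext_moment = hip_ext, knee_flex_moment = knee_flex_m,
    knee_add_moment = knee_add_m, ankle_pf_moment = ankle_pf,
    pelvis_vz = pelvis_vz
  )

  df <- add_channel_noise(df, spec$noise_sd)

  # ground-truth heel strikes: first ideal sample at/above the 20 N threshold
  hs_idx <- run_starts(ideal_fz >= 20, 1L)
  hs_idx <- hs_idx[hs_idx > 1L]

  speed <- switch(spec$movement,
    walk = 1.30 + stats::rnorm(1, 0, 0.01),
    run_selfselect = 2.85 + stats::rnorm(1, 0, 0.05),
    run_set = 3.00 + stats::rnorm(1, 0, 0.015)
  )

  new_knee_trial(df, rate_hz = fs, movement = spec$movement, subject = sub,
                 speed_mps = speed,
                 ground_truth = list(
                   muscle_forces = truth,
                   heel_strikes = hs_idx,
                   stride_duration_s = Tst,
                   stance_frac = stance_frac,
                   speed_mps = speed
                 ))
}

# scalar noise_sd -> force/moment channels; named vector -> as named
add_channel_noise <- function(df, noise_sd) {
  n <- nrow(df)
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    if (noise_sd > 0) {
      for (ch in c("fx", "fy", "fz", "hip_ext_moment", "knee_flex_moment",
                   "knee_add_moment", "ankle_pf_moment")) {
        if (ch %in% names(df)) df[[ch]] <- df[[ch]] + rnorm(n, 0, noise_sd)
      }
    }
  } else {
    for (ch in names(noise_sd)) {
      if (ch %in% names(df) && noise_sd[[ch]] > 0) {
        df[[ch]] <- df[[ch]] + rnorm(n, 0, noise_sd[[ch]])
      }
    }
  }
  df
}
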