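#' Specification for a synthetic sit-to-stand / stand-to-sit trace
#'
#' `phase_boundaries` anchors the five segments on the kinetic clock
#' (quiet-sit start, rise onset, quiet-stand start, descent onset,
#' quiet-sit-again start), strictly increasing. The generated vertical force
#' is piecewise linear-with-plateaus: seat-supported quiet sitting at 25% of
#' bodyweight on the floor plate, a constant-rate rise to bodyweight, quiet
#' standing at bodyweight, a fast drop (4x the rise rate) back to the seated
#' level, and quiet sitting. The anterior-posterior force and pelvis vertical
#' velocity carry the matching derivative structure that the phase-boundary
#' equations consume.
#'
#' @param phase_boundaries Integer vector of 5 strictly increasing sample
#'   indices. The rise (2nd to 3rd) must span at least 0.3 s and the descent
#'   anchor gap (4th to 5th) at least 1.5 s so the pelvis-velocity settle
#'   profile fits.
#' @param bodyweight_n Bodyweight, N.
#' @param seat_height_cm Stool seat height, cm (recorded as metadata; the
#'   seat reaction force itself is not modelled -- only the floor plate is).
#' @param height_m Subject height, m (scales the synthetic moment bumps).
#' @param rate_hz Sampling rate, Hz.
#' @param noise_sd Additive Gaussian noise SD on force channels, N.
#' @param seed Integer seed.
#' @return A list of class `sts_trial_spec`.
#' @export
sts_trial_spec <- function(phase_boundaries = c(1L, 2001L, 3001L, 5001L, 6601L),
                           bodyweight_n = 700, seat_height_cm = 44,
                           height_m = 1.69, rate_hz = 1000,
                           noise_sd = 0, seed = 1L) {
  b <- as.integer(phase_boundaries)
  if (length(b) != 5 || any(diff(b) <= 0)) {
    abort("phase_boundaries must be 5 strictly increasing sample indices")
  }
  if (bodyweight_n <= 0) abort("bodyweight must be positive")
  if ((b[3] - b[2]) / rate_hz < 0.3) abort("rise (boundaries 2-3) must span at least 0.3 s")
  if ((b[5] - b[4]) / rate_hz < 1.5) abort("descent (boundaries 4-5) must span at least 1.5 s")
  structure(list(phase_boundaries = b, bodyweight_n = bodyweight_n,
                 seat_height_cm = seat_height_cm, height_m = height_m,
                 rate_hz = rate_hz, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sts_trial_spec")
}

# piecewise-linear interpolator over (sample index, value) knots
pw_linear <- function(n, knots_i, knots_v) {
  approx(knots_i, knots_v, xout = seq_len(n), rule = 2)$y
}

#' Generate a synthetic sit-to-stand / stand-to-sit force trace
#'
#' Builds the trace described in [sts_trial_spec()] and returns the analytic
#' ground-truth boundary indices defined by the phase equations on the clean
#' trace: the rise onset (vertical force rate surge), the quiet-standing
#' start (force entering the 1% bodyweight band), the descent onset (force
#' crossing 0.98 bodyweight), and the quiet-sitting start (pelvis vertical
#' velocity magnitude crossing 0.02 m/s). These are crossing times computed
#' in closed form from the piecewise construction, independent of the
#' detection code, so detector tests are genuine recovery tests.
#'
#' @param spec An [sts_trial_spec()].
#' @return A `knee_trial` tibble; `trial_ground_truth()` returns
#'   `true_boundaries` (named integer vector `sts_start`, `sts_end`,
#'   `s2s_start`, `s2s_end`) and the construction anchors.
#' @export
generate_sts_trace <- function(spec) {
  stopifnot(inherits(spec, "sts_trial_spec"))
  set.seed(spec$seed)
  b <- spec$phase_boundaries
  bw <- spec$bodyweight_n
  fs <- spec$rate_hz
  ht <- spec$height_m
  sit <- 0.25 * bw
  t_rise <- (b[3] - b[2]) / fs
  slope_r <- 0.75 * bw / t_rise            # N/s
  slope_d <- 4 * slope_r                   # descent drop is 4x faster
  n_drop <- round(0.75 * bw / slope_d * fs)
  n <- b[5] + round(1.2 * fs)
  t <- (0:(n - 1)) / fs

  fz <- pw_linear(n, c(1, b[2], b[3], b[4], b[4] + n_drop, n),
                  c(sit, sit, bw, bw, sit, sit))

  # anterior-posterior force: monotone ramps whose derivative stays clear of
  # the 1%-of-peak-to-peak quiet threshold until after the vz settle point
  a1 <- 0.04 * bw
  a2 <- 0.05 * bw
  y_end <- b[5] + round(0.2 * fs)
  fy <- pw_linear(n, c(1, b[2], b[3], b[4], y_end, n),
                  c(0, 0, a1, a1, a1 - a2, a1 - a2))

  # pelvis vertical velocity: rise bump, then a descent trapezoid whose
  # final up-ramp crosses -0.02 m/s exactly at the planted quiet-sit boundary
  v_desc <- 0.4
  overshoot <- 0.05
  t_u <- 1.5
  frac <- (v_desc - 0.02) / (v_desc + overshoot)
  u0 <- b[5] - round(frac * t_u * fs)
  u1 <- u0 + round(t_u * fs)
  vz <- numeric(n)
  rise_idx <- b[2]:b[3]
  vz[rise_idx] <- 0.45 * sin(pi * (rise_idx - b[2]) / (b[3] - b[2]))
  vz <- vz + pw_linear(n, c(1, b[4], b[4] + round(0.2 * fs), u0, u1,
                            u1 + round(0.3 * fs), n),
                       c(0, 0, -v_desc, -v_desc, overshoot, 0, 0))

  # smooth joint kinematics/kinetics driven by the normalised body position
  p <- (fz - sit) / (0.75 * bw)
  bump <- 4 * p * (1 - p)
  knee_flex <- 1.40 - 1.25 * p
  hip_flex <- 1.50 - 1.30 * p
  ankle_flex <- 0.15 - 0.10 * p
  knee_add <- 0.03 * (1 - p)
  kfm <- 0.09 * bw * ht * bump
  df <- tibble(
    time = t, fx = 0.01 * bw * bump, fy = fy, fz = fz,
    hip_flex_angle = hip_flex, knee_flex_angle = knee_flex,
    knee_add_angle = knee_add, ankle_flex_angle = ankle_flex,
    hip_ext_moment = 1.2 * kfm, knee_flex_moment = kfm,
    knee_add_moment = -0.03 * bw * ht * bump, ankle_pf_moment = 0.25 * kfm,
    pelvis_vz = vz
  )
  df <- add_channel_noise(df, spec$noise_sd)

  true_boundaries <- c(
    sts_start = b[2],
    sts_end = b[3] - round(0.01 * bw / slope_r * fs),
    s2s_start = b[4] + round(0.02 * bw / slope_d * fs),
    s2s_end = b[5]
  )

  new_knee_trial(df, rate_hz = fs, movement = "sts",
                 subject = NULL,
                 ground_truth = list(
                   true_boundaries = true_boundaries,
                   anchors = b,
                   bodyweight_n = bw,
                   seat_height_cm = spec$seat_height_cm
                 ))
}
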