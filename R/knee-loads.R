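#' Medial tibiofemoral contact force at one sample
#'
#' Balances moments about the lateral tibiofemoral contact point in the
#' frontal plane:
#' `F_med = -( sum_i(r_i F_i) / d_hat + F_RJF / 2 + tau_KAM / d_hat )`,
#' where `r_i` and `F_i` are the frontal-plane lever arm and force of the
#' i-th knee-crossing muscle or ligament, `F_RJF` the resultant knee joint
#' force, `tau_KAM` the knee adduction moment, and `d_hat` the distance
#' between the medial and lateral tibiofemoral contact points.
#'
#' Sign conventions (one frame governs every term): compressive resultant
#' `F_RJF < 0`; `tau_KAM < 0` for adduction; frontal-plane muscle/ligament
#' lever arms are negative when the structure adds medial load. Under
#' physiological compression the leading minus sign then yields
#' `F_med >= 0`.
#'
#' @param knee_moment_sum_nm `sum_i r_i F_i`, N m (vectorised).
#' @param f_rjf_n Resultant knee joint force, N (compression negative).
#' @param tau_kam_nm Knee adduction moment, N m (adduction negative).
#' @param d_hat_m Midcondylar contact-point distance, m.
#' @return Medial contact force, N.
#' @export
#' @examples
#' mjcf_sample(0, -1000, 0, 0.05)        # symmetric split: 500 N
#' mjcf_sample(0, -1000, -25, 0.05)      # adduction loads medially: 1000 N
mjcf_sample <- function(knee_moment_sum_nm, f_rjf_n, tau_kam_nm, d_hat_m) {
  if (any(d_hat_m <= 0)) abort("contact-point distance d_hat must be positive")
  -(knee_moment_sum_nm / d_hat_m + f_rjf_n / 2 + tau_kam_nm / d_hat_m)
}

#' Scale a force by bodyweight
#' @param force_n Force, N.
#' @param bw_n Bodyweight, N.
#' @return Force as a dimensionless multiple of bodyweight.
#' @export
scale_by_bodyweight <- function(force_n, bw_n) {
  if (any(bw_n <= 0)) abort("bodyweight must be positive")
  force_n / bw_n
}

#' Scale a moment by bodyweight x height
#' @param moment_nm Moment, N m.
#' @param bw_n Bodyweight, N.
#' @param ht_m Height, m.
#' @return Dimensionless normalised moment (units of BW Ht).
#' @export
scale_moment <- function(moment_nm, bw_n, ht_m) {
  if (any(bw_n <= 0) || any(ht_m <= 0)) abort("bodyweight and height must be positive")
  moment_nm / (bw_n * ht_m)
}

#' Compute the per-sample joint load series for a trial
#'
#' Evaluates the contact-force balance at every sample: muscle forces from
#' [reduce_muscle_forces()] (or supplied), frontal-plane lever arms from the
#' model, the resultant knee joint force (by default approximated as the
#' negated vertical ground reaction force, i.e. compression during contact),
#' and the knee adduction moment channel. Outputs both raw (N, N m) and
#' scaled (BW, BW Ht) series.
#'
#' @param trial A (conditioned) trial tibble.
#' @param subject A [subject_profile()].
#' @param model A `moment_arm_model`.
#' @param forces Optional precomputed `muscle_force_set`.
#' @param f_rjf_n Optional resultant knee joint force series, N (compression
#'   negative); defaults to `-trial$fz`.
#' @return A `joint_load_series` tibble with columns `time`, `f_rjf`,
#'   `tau_kam`, `kfm`, `f_med_n`, `mjcf_bw`, `kam_bwht`, `kfm_bwht`.
#' @export
compute_joint_loads <- function(trial, subject, model = load_model_config(),
                                forces = NULL, f_rjf_n = NULL) {
  if (is.null(forces)) forces <- reduce_muscle_forces(trial, subject, model)
  if (is.null(f_rjf_n)) f_rjf_n <- -trial$fz
  gender <- subject$gender
  theta <- trial$knee_flex_angle
  structures <- c("quadriceps", "hamstrings", "gastrocnemius",
                  "ACL", "PCL", "MCL", "LCL")
  msum <- rep(0, nrow(trial))
  for (s in structures) {
    r <- moment_arm(model, "frontal", s, theta, gender)
    msum <- msum + r * forces[[s]]
  }
  d_hat_m <- subject$d_hat_cm / 100
  tau <- trial$knee_add_moment
  f_med <- mjcf_sample(msum, f_rjf_n, tau, d_hat_m)
  out <- tibble(
    time = trial$time,
    f_rjf = f_rjf_n,
    tau_kam = tau,
    kfm = trial$knee_flex_moment,
    f_med_n = f_med,
    mjcf_bw = scale_by_bodyweight(f_med, subject$bw_n),
    kam_bwht = scale_moment(-tau, subject$bw_n, subject$height_m),
    kfm_bwht = scale_moment(trial$knee_flex_moment, subject$bw_n,
                            subject$height_m)
  )
  attr(out, "rate_hz") <- trial_rate(trial)
  attr(out, "subject") <- subject
  class(out) <- c("joint_load_series", class(out))
  out
}

#' Extract per-window load peaks
#'
#' Walking exhibits two load peaks within stance; the stance portion of the
#' window (contiguous samples with compressive resultant force above 20 N
#' from the window start) is split in half and the maximum of each half is
#' reported (`peak1` includes the midpoint sample). Running and sit-to-stand
#' movements yield a single maximum over the window.
#'
#' @param series A `joint_load_series`.
#' @param window A one-row `phase_window`.
#' @param movement Movement class label.
#' @return A tibble with columns `movement`, `variable` (`mjcf_bw`,
#'   `kam_bwht`, `kfm_bwht`), `peak` (`peak1`/`peak2` for walking, `peak`
#'   otherwise) and `value`.
#' @export
extract_peaks <- function(series, window,
                          movement = c("walk", "run_selfselect", "run_set",
                                       "sit_to_stand", "stand_to_sit")) {
  movement <- match.arg(movement)
  if (nrow(window) != 1) abort("window must be a single phase window")
  i0 <- window$start_index
  i1 <- window$end_index
  if (i1 < i0) abort("empty window")
  if (i0 < 1 || i1 > nrow(series)) abort("window out of bounds for series")
  idx <- i0:i1
  vars <- c("mjcf_bw", "kam_bwht", "kfm_bwht")
  if (movement == "walk") {
    # stance = contiguous loaded samples from window start
    loaded <- series$f_rjf[idx] <= -20
    n_st <- which(!loaded)[1]
    n_st <- if (is.na(n_st)) length(idx) else max(n_st - 1L, 1L)
    stance <- idx[seq_len(n_st)]
    mid <- stance[ceiling(length(stance) / 2)]
    first <- stance[stance <= mid]
    second <- stance[stance > mid]
    if (!length(second)) second <- mid
    rows <- purrr::map_dfr(vars, function(v) {
      tibble(variable = v, peak = c("peak1", "peak2"),
             value = c(max(series[[v]][first]), max(series[[v]][second])))
    })
  } else {
    rows <- purrr::map_dfr(vars, function(v) {
      tibble(variable = v, peak = "peak", value = max(series[[v]][idx]))
    })
  }
  dplyr::mutate(rows, movement = movement, .before = 1)
}

#' Symmetric percent difference between two group means
#'
#' `|a - b| / ((a + b)/2) * 100`: the absolute difference relative to the
#' mean of the two means.
#'
#' @param mean_a,mean_b Group means (nonzero sum).
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(2.2, 1.8)  # 20
percent_difference <- function(mean_a, mean_b) {
  denom <- (mean_a + mean_b) / 2
  if (any(denom == 0)) abort("percent difference undefined when the mean of means is zero")
  abs(mean_a - mean_b) / denom * 100
}
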