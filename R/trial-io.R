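#' Trial channel names
#'
#' The canonical channel order of a trial table: time (s), ground reaction
#' force components (N; `fy` is anterior-posterior, `fz` vertical), joint
#' angles (rad), net joint moments (N m), and vertical pelvis velocity (m/s).
#' One row per kinetic sample.
#' @export
TRIAL_CHANNELS <- c(
  "time", "fx", "fy", "fz",
  "hip_flex_angle", "knee_flex_angle", "knee_add_angle", "ankle_flex_angle",
  "hip_ext_moment", "knee_flex_moment", "knee_add_moment", "ankle_pf_moment",
  "pelvis_vz"
)

GRF_CHANNELS <- c("fx", "fy", "fz")
KIN_CHANNELS <- setdiff(TRIAL_CHANNELS, c("time", GRF_CHANNELS))

new_knee_trial <- function(df, rate_hz, movement = NA_character_,
                           subject = NULL, ground_truth = NULL,
                           speed_mps = NA_real_) {
  out <- as_tibble(df)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "movement") <- movement
  attr(out, "subject") <- subject
  attr(out, "ground_truth") <- ground_truth
  attr(out, "speed_mps") <- speed_mps
  class(out) <- c("knee_trial", class(out))
  out
}

#' Ground truth planted in a synthetic trial
#'
#' @param trial A trial generated by [generate_gait_trial()] or
#'   [generate_sts_trace()].
#' @return The generator's ground-truth list (planted muscle forces, event
#'   indices, ...), or `NULL` for real data.
#' @export
trial_ground_truth <- function(trial) attr(trial, "ground_truth")

#' Write / read a trial table as TSV
#'
#' Plain tab-separated text with the canonical header
#' `time  fx  fy  fz ... pelvis_vz`, SI units, one row per kinetic sample.
#' The sampling rate is recovered from the `time` column on read.
#'
#' @param trial A trial tibble with the [TRIAL_CHANNELS] columns.
#' @param path File path.
#' @return `write_trial_tsv()` returns `path` invisibly; `read_trial_tsv()`
#'   returns a `knee_trial` tibble.
#' @export
write_trial_tsv <- function(trial, path) {
  missing <- setdiff(TRIAL_CHANNELS, names(trial))
  if (length(missing)) abort(paste0("trial missing channels: ", paste(missing, collapse = ", ")))
  readr::write_tsv(trial[TRIAL_CHANNELS], path)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(TRIAL_CHANNELS, names(df))
  if (length(missing)) abort(paste0(path, " is not a trial table; missing: ",
                                    paste(missing, collapse = ", ")))
  rate <- 1 / median(diff(df$time))
  new_knee_trial(df[TRIAL_CHANNELS], rate_hz = round(rate))
}

#' Condition a trial's channels
#'
#' Applies the dual-pass Butterworth conventions to every channel: 45 Hz to
#' the ground reaction forces and the movement-class kinematic cutoff (10 Hz
#' running, 6 Hz otherwise) to angles, net moments and pelvis velocity.
#'
#' @param trial A trial tibble.
#' @param movement Movement class; defaults to the trial's own label.
#' @return The trial with filtered channels.
#' @export
condition_trial <- function(trial, movement = NULL) {
  movement <- movement %||% attr(trial, "movement") %||% "walk"
  rate <- trial_rate(trial)
  cut <- default_cutoffs(movement)
  out <- trial
  for (ch in intersect(GRF_CHANNELS, names(out))) {
    out[[ch]] <- filter_dual_pass(out[[ch]], rate, cut$grf)
  }
  for (ch in intersect(KIN_CHANNELS, names(out))) {
    out[[ch]] <- filter_dual_pass(out[[ch]], rate, cut$kinematic)
  }
  out
}

#' Write detected phase windows as TSV
#'
#' @param windows A `phase_window` tibble (may combine several trials).
#' @param path File path.
#' @param trial_id Optional trial identifier column value.
#' @export
write_windows_tsv <- function(windows, path, trial_id = NA_character_) {
  out <- dplyr::mutate(windows, trial = trial_id, .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}
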