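#' Filter specification for trial conditioning
#'
#' The conditioning convention used throughout the pipeline: a 4th-order
#' Butterworth filter applied in two passes (forward and backward, zero
#' phase). Ground reaction forces are filtered at 45 Hz; kinematic channels
#' (angles, pelvis velocity) and net joint moments at 10 Hz for running and
#' 6 Hz for other movements. No cutoff-frequency correction is applied, so
#' the attenuation at the nominal cutoff is 0.5 (the squared -3 dB point of
#' the cascaded passes), matching common filtfilt practice.
#'
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order per pass (default 4).
#' @param passes Number of passes (fixed at 2; forward-backward).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz, order = 4L, passes = 2L) {
  if (cutoff_hz <= 0) abort("cutoff must be positive")
  if (passes != 2L) abort("only dual-pass (forward-backward) filtering is supported")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 passes = 2L), class = "filter_spec")
}

#' Default cutoffs by movement class
#'
#' @param movement One of `"walk"`, `"run_selfselect"`, `"run_set"`,
#'   `"sit_to_stand"`, `"stand_to_sit"`, `"sts"`.
#' @return A list with `grf` and `kinematic` filter specs (45 Hz GRF; 10 Hz
#'   kinematics for running, 6 Hz otherwise).
#' @export
default_cutoffs <- function(movement) {
  kin <- if (movement %in% c("run_selfselect", "run_set")) 10 else 6
  list(grf = filter_spec(45), kinematic = filter_spec(kin))
}

#' Zero-phase dual-pass Butterworth filtering
#'
#' Applies a Butterworth low-pass filter forward and backward, yielding a
#' zero-phase output of the same length. Edge transients are controlled by
#' odd-reflection padding at both ends before filtering (the padding is
#' removed afterwards).
#'
#' @param x Numeric vector, one uniformly sampled channel.
#' @param rate_hz Sampling rate, Hz.
#' @param spec A [filter_spec()], or a cutoff in Hz.
#' @return Filtered vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' x <- sin(2 * pi * 5 * t) + rnorm(length(t), sd = 0.2)
#' y <- filter_dual_pass(x, rate_hz = 1000, spec = filter_spec(45))
filter_dual_pass <- function(x, rate_hz, spec) {
  if (is.numeric(spec)) spec <- filter_spec(spec)
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- rate_hz / 2
  if (spec$cutoff_hz >= nyq) {
    abort(paste0("cutoff (", spec$cutoff_hz, " Hz) must be below the Nyquist frequency (",
                 nyq, " Hz)"))
  }
  n <- length(x)
  if (n <= 3 * spec$order) abort("signal too short to filter (need length > 3 x order)")
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")

  # odd reflection about the end points suppresses start/end transients;
  # the pad must outlast the slowest pole's impulse response, which grows
  # as the cutoff drops relative to the sampling rate
  npad <- min(n - 1L, max(9L * round(rate_hz / spec$cutoff_hz), 9L * spec$order))
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(pre, x, post)
  yp <- signal::filtfilt(bf, xp)
  yp[(npad + 1):(npad + n)]
}
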