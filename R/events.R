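#' @noRd
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 3) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# start indices of TRUE runs of at least min_len samples
run_starts <- function(cond, min_len = 1L) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths >= min_len]
}

trial_rate <- function(series) {
  rt <- attr(series, "rate_hz")
  if (!is.null(rt)) return(rt)
  if (!"time" %in% names(series)) abort("series must carry a rate_hz attribute or a time column")
  1 / median(diff(series$time))
}

phase_window <- function(label, start_index, end_index, rate_hz) {
  out <- tibble(
    label = label,
    start_index = as.integer(start_index),
    end_index = as.integer(end_index),
    start_time = (start_index - 1) / rate_hz,
    end_time = (end_index - 1) / rate_hz
  )
  class(out) <- c("phase_window", class(out))
  out
}

no_event <- function(label, rate_hz) {
  inform(paste0("no event: no qualifying ", label, " phase found"))
  phase_window(character(), integer(), integer(), rate_hz)
}

#' Detect heel strikes from the vertical ground reaction force
#'
#' Initial foot contact is the first sample at which the (filtered) vertical
#' force rises to or above a 20 N threshold and stays above it for at least
#' 10 ms. Crossings are resolved to the first discrete sample satisfying the
#' condition; no sub-sample interpolation is performed.
#'
#' @param fz Vertical ground reaction force channel, N (already filtered).
#' @param rate_hz Sampling rate, Hz.
#' @param threshold_n Contact threshold, N (default 20).
#' @param min_contact_s Minimum time above threshold for a valid contact, s.
#' @return Integer vector of strictly increasing event sample indices (may be
#'   empty).
#' @export
detect_heel_strikes <- function(fz, rate_hz, threshold_n = 20,
                                min_contact_s = 0.010) {
  if (threshold_n <= 0) abort("threshold must be positive")
  min_len <- max(1L, ceiling(min_contact_s * rate_hz))
  starts <- run_starts(fz >= threshold_n, min_len)
  starts[starts > 1L]   # a trace starting in contact is not an upward crossing
}

#' Extract clean strides between consecutive heel strikes
#'
#' Builds heel-strike-to-heel-strike windows and retains at most the first
#' five clean ones. A stride is clean when its force channel has no gaps
#' (no missing samples) and its duration lies within 2 SD of the trial median
#' stride duration.
#'
#' @param events Heel-strike indices from [detect_heel_strikes()].
#' @param series Optional trial tibble used for the gap check (column `fz`)
#'   and the time base.
#' @param rate_hz Sampling rate, Hz (taken from `series` if omitted).
#' @param max_strides Maximum number of clean strides retained (default 5).
#' @return A `phase_window` tibble, one row per retained stride.
#' @export
extract_strides <- function(events, series = NULL, rate_hz = NULL,
                            max_strides = 5L) {
  if (length(events) < 2) abort("no stride: need at least 2 heel-strike events")
  if (is.null(rate_hz)) {
    rate_hz <- if (!is.null(series)) trial_rate(series) else 1
  }
  start <- events[-length(events)]
  end <- events[-1]
  dur <- end - start
  med <- median(dur)
  s <- sd(dur)
  ok_dur <- if (length(dur) < 2 || is.na(s) || s == 0) rep(TRUE, length(dur)) else abs(dur - med) <= 2 * s
  ok_gap <- rep(TRUE, length(dur))
  if (!is.null(series) && "fz" %in% names(series)) {
    ok_gap <- vapply(seq_along(start), function(i) {
      !anyNA(series$fz[start[i]:end[i]])
    }, logical(1))
  }
  keep <- which(ok_dur & ok_gap)
  keep <- head(keep, max_strides)
  phase_window(rep("stride", length(keep)), start[keep], end[keep], rate_hz)
}

# 10 Hz smoothed detection copy used for derivative and band logic; the
# 45 Hz conditioned force retains too much broadband noise for stable
# derivative thresholding.
DETECT_CUTOFF_HZ <- 10
# derivative = central difference averaged over a centred 100 ms window
# (a local-slope estimate); raw sample-to-sample differences amplify
# whatever noise survives the smoothing
DERIV_WINDOW_S <- 0.100
# one-sided differences and filter start-up make trace edges unreliable
EDGE_TRIM_S <- 0.200

local_slope <- function(x, rate_hz) {
  d <- central_diff(x, 1 / rate_hz)
  w <- max(1L, round(DERIV_WINDOW_S * rate_hz))
  if (w %% 2 == 0) w <- w + 1L
  d <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  d[is.na(d)] <- 0
  trim <- min(length(d), max(1L, round(EDGE_TRIM_S * rate_hz)))
  d[seq_len(trim)] <- 0
  d[seq(length(d) - trim + 1L, length(d))] <- 0
  d
}

detect_channels <- function(series, rate_hz) {
  sm <- function(x) filter_dual_pass(x, rate_hz, filter_spec(DETECT_CUTOFF_HZ))
  fz10 <- sm(series$fz)
  fy10 <- if ("fy" %in% names(series)) sm(series$fy) else NULL
  list(
    fz10 = fz10, d_fz = local_slope(fz10, rate_hz),
    fy10 = fy10, d_fy = if (is.null(fy10)) NULL else local_slope(fy10, rate_hz)
  )
}

#' Detect the sit-to-stand phase
#'
#' The phase starts at the seat-unloading surge, defined by the vertical force
#' rate `dFz/dt` reaching 10% of its trial peak-to-peak value: the detector
#' locates the global maximum of the (smoothed) derivative and walks backward
#' to the first sample of the contiguous supra-threshold region. The phase
#' ends at the start of quiet standing, the first subsequent sample where `Fz`
#' stays within (1 +/- 0.01) x bodyweight for a sustained 200 ms window.
#'
#' @param series Trial tibble with channels `fz` (and optionally `fy`,
#'   `pelvis_vz`), conditioned with [filter_dual_pass()].
#' @param bodyweight_n Subject bodyweight, N.
#' @param sustain_s Sustain requirement for the quiet-standing band, s.
#' @return A one-row `phase_window` labelled `"sit_to_stand"`, or a zero-row
#'   window when no qualifying event exists.
#' @export
detect_sit_to_stand <- function(series, bodyweight_n, sustain_s = 0.200) {
  if (bodyweight_n <= 0) abort("bodyweight must be positive")
  rate_hz <- trial_rate(series)
  ch <- detect_channels(series, rate_hz)
  pp <- diff(range(ch$d_fz))
  thr <- 0.10 * pp
  imax <- which.max(ch$d_fz)
  # a genuine seat-unloading surge moves a meaningful fraction of bodyweight
  # per second; a flat trace's residual derivative is not an event
  if (thr <= 0 || ch$d_fz[imax] < max(thr, 0.05 * bodyweight_n)) {
    return(no_event("sit_to_stand", rate_hz))
  }
  above <- ch$d_fz >= thr
  start <- imax
  while (start > 1 && above[start - 1]) start <- start - 1L

  min_len <- max(1L, ceiling(sustain_s * rate_hz))
  inband <- abs(ch$fz10 - bodyweight_n) <= 0.01 * bodyweight_n
  ends <- run_starts(inband[(start + 1):length(inband)], min_len)
  if (!length(ends)) return(no_event("sit_to_stand", rate_hz))
  phase_window("sit_to_stand", start, start + ends[1], rate_hz)
}

#' Detect the stand-to-sit phase
#'
#' The phase starts after the quiet-standing period, at the first sample
#' where `Fz` drops to or below 0.98 x bodyweight (sustained 50 ms to reject
#' noise transients). It ends at the beginning of quiet sitting: the first
#' subsequent sample where either `|dFy/dt|` falls to or below 1% of its
#' trial peak-to-peak value, or the vertical pelvis velocity magnitude falls
#' below 0.02 m/s -- whichever occurs first. Absolute derivative values are
#' used throughout.
#'
#' @inheritParams detect_sit_to_stand
#' @param end_sustain_s Sustain requirement for the end clauses, s.
#' @return A one-row `phase_window` labelled `"stand_to_sit"`, or a zero-row
#'   window when no qualifying event exists.
#' @export
detect_stand_to_sit <- function(series, bodyweight_n, sustain_s = 0.200,
                                end_sustain_s = 0.100) {
  if (bodyweight_n <= 0) abort("bodyweight must be positive")
  rate_hz <- trial_rate(series)
  ch <- detect_channels(series, rate_hz)
  min_len <- max(1L, ceiling(sustain_s * rate_hz))

  inband <- abs(ch$fz10 - bodyweight_n) <= 0.01 * bodyweight_n
  quiet <- run_starts(inband, min_len)
  if (!length(quiet)) return(no_event("stand_to_sit", rate_hz))
  q0 <- quiet[1]

  min_start <- max(1L, ceiling(0.050 * rate_hz))
  below <- ch$fz10 <= 0.98 * bodyweight_n
  starts <- run_starts(below, min_start)
  starts <- starts[starts > q0]
  if (!length(starts)) return(no_event("stand_to_sit", rate_hz))
  start <- starts[1]

  n <- nrow(series)
  min_end <- max(1L, ceiling(end_sustain_s * rate_hz))
  quiet_cond <- rep(FALSE, n)
  if (!is.null(ch$d_fy)) {
    pp_y <- diff(range(ch$d_fy))
    quiet_cond <- quiet_cond | (abs(ch$d_fy) <= 0.01 * pp_y)
  }
  if ("pelvis_vz" %in% names(series)) {
    quiet_cond <- quiet_cond | (abs(series$pelvis_vz) < 0.02)
  }
  ends <- run_starts(quiet_cond[(start + 1):n], min_end)
  if (!length(ends)) return(no_event("stand_to_sit", rate_hz))
  phase_window("stand_to_sit", start, start + ends[1], rate_hz)
}
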