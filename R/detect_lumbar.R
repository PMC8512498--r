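#' Configuration for the lower-back event detector
#'
#' @param lowpass_cutoff Butterworth low-pass cut-off, Hz (default 20).
#' @param filter_order Butterworth order (default 4; applied forward and
#'   backward, so the effective attenuation doubles but no phase delay is
#'   introduced).
#' @param wavelet Differentiating wavelet; only the first-order Gaussian
#'   (`"gaus1"`) is shipped.
#' @param cwt_scale_ref Wavelet scale in samples at the 100 Hz reference
#'   rate (default 10); the scale actually used is
#'   `cwt_scale_ref * fs / 100`, so the analysed frequency band is the same
#'   at every sampling rate.
#' @param min_event_separation Minimum spacing between detected events, s
#'   (default 0.25, about the shortest plausible step time at 8 km/h).
#' @param gravity_removal Subtract the channel mean before integration?
#' @param min_prominence_frac Height gate as a fraction of the dominant
#'   extremum's magnitude; suppresses shallow spurious extrema between
#'   steps (default 0.2).
#' @param boundary_scales Events closer than `boundary_scales * scale`
#'   samples to either end are discarded (wavelet support; default 4).
#' @return Object of class `lumbar_detector_config`.
#' @export
lumbar_detector_config <- function(lowpass_cutoff = 20, filter_order = 4,
                                   wavelet = "gaus1", cwt_scale_ref = 10,
                                   min_event_separation = 0.25,
                                   gravity_removal = TRUE,
                                   min_prominence_frac = 0.2,
                                   boundary_scales = 4) {
  if (!identical(wavelet, "gaus1")) stop("unsupported wavelet '", wavelet, "'")
  if (lowpass_cutoff <= 0) stop("lowpass_cutoff must be > 0")
  if (cwt_scale_ref <= 0) stop("cwt_scale_ref must be > 0")
  structure(list(lowpass_cutoff = lowpass_cutoff, filter_order = filter_order,
                 wavelet = wavelet, cwt_scale_ref = cwt_scale_ref,
                 min_event_separation = min_event_separation,
                 gravity_removal = gravity_removal,
                 min_prominence_frac = min_prominence_frac,
                 boundary_scales = boundary_scales),
            class = "lumbar_detector_config")
}

#' Detected gait events from one placement/side
#'
#' @param placement Sensor placement string.
#' @param side `"L"`, `"R"` or `"unassigned"`.
#' @param ic_times,fc_times Ascending event times, s.
#' @param diagnostics Free-form list of per-stage counts.
#' @return Object of class `event_series`.
#' @export
event_series <- function(placement, side, ic_times, fc_times,
                         diagnostics = list()) {
  if (is.unsorted(ic_times, strictly = TRUE) && length(ic_times) > 1) {
    stop("ic_times must be strictly ascending")
  }
  if (is.unsorted(fc_times, strictly = TRUE) && length(fc_times) > 1) {
    stop("fc_times must be strictly ascending")
  }
  structure(list(placement = placement, side = side,
                 ic_times = as.numeric(ic_times), fc_times = as.numeric(fc_times),
                 diagnostics = diagnostics),
            class = "event_series")
}

#' Tilt-correct a lumbar recording to the horizontal-vertical frame
#'
#' Estimates the sensor tilt from the mean acceleration direction (the
#' quasi-static gravity estimate, in the spirit of the classic trunk-
#' accelerometry tilt correction) and rotates all samples so the mean
#' acceleration is aligned with the vertical axis.  The rotation is
#' norm-preserving per sample; the returned vertical channel has mean +g.
#'
#' @param rec An [imu_recording()] with an accelerometer block and at least
#'   2 s of data.
#' @return List with `vertical` (numeric), `horizontal` (n x 2 matrix) and
#'   `rotation` (3 x 3 matrix).
#' @export
tilt_correct_to_vertical <- function(rec) {
  validate_imu_recording(rec)
  if (is.null(rec$accel)) stop("recording has no accelerometer block")
  if (n_samples(rec) < 2 * rec$fs) stop("recording must contain at least 2 s of data")
  m <- colMeans(rec$accel)
  mag <- sqrt(sum(m^2))
  if (mag < 0.5 * STANDARD_GRAVITY || mag > 1.5 * STANDARD_GRAVITY) {
    stop("mean acceleration magnitude ", signif(mag, 4),
         " m/s^2 outside 0.5-1.5 g: sensor not quasi-static / wrong units")
  }
  u <- m / mag
  ez <- c(0, 0, 1)
  v <- c(u[2] * ez[3] - u[3] * ez[2],
         u[3] * ez[1] - u[1] * ez[3],
         u[1] * ez[2] - u[2] * ez[1])      # u x ez
  s <- sqrt(sum(v^2)); cth <- sum(u * ez)
  if (s < 1e-12) {
    R <- diag(3) * sign(cth)
    if (cth < 0) R[1, 1] <- 1               # antipodal: flip z and y only
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)   # Rodrigues
  }
  rotated <- rec$accel %*% t(R)
  list(vertical = rotated[, 3], horizontal = rotated[, 1:2, drop = FALSE],
       rotation = R)
}

#' Detect gait events from lumbar vertical acceleration
#'
#' The lower-back pipeline: optional gravity (mean) removal, zero-phase
#' Butterworth low-pass, cumulative trapezoidal integration to a vertical
#' velocity, differentiation by a first-order-Gaussian continuous wavelet
#' transform at scale `cwt_scale_ref * fs/100` (initial contacts at the
#' local minima), and a second wavelet differentiation of that output
#' (final contacts at the local maxima, at most one per IC-to-IC cycle).
#'
#' @param vertical_accel Vertical acceleration channel, m/s^2.
#' @param fs Sampling rate, Hz.
#' @param config A [lumbar_detector_config()].
#' @return An [event_series()] with `side = "unassigned"`.  Diagnostics
#'   report candidate and dropped-event counts.
#' @export
detect_events_lumbar <- function(vertical_accel, fs,
                                 config = lumbar_detector_config()) {
  stopifnot(inherits(config, "lumbar_detector_config"))
  if (config$lowpass_cutoff >= fs / 2) {
    stop("lowpass_cutoff must be below the Nyquist frequency fs/2")
  }
  v <- as.numeric(vertical_accel)
  n <- length(v)
  if (n < 2 * fs) stop("signal must be at least 2 s long")
  if (config$gravity_removal) v <- v - mean(v)
  bf <- signal::butter(config$filter_order, config$lowpass_cutoff / (fs / 2),
                       type = "low")
  v <- signal::filtfilt(bf, v)
  # cumulative trapezoidal integration, initial value 0
  vel <- c(0, cumsum((v[-1] + v[-n]) / 2)) / fs
  scale <- config$cwt_scale_ref * fs / 100
  y <- cwt_gaus1(vel, scale)          # ~ smoothed vertical acceleration
  z <- cwt_gaus1(y, scale)            # ~ smoothed jerk
  sep <- round(config$min_event_separation * fs)
  guard <- ceiling(config$boundary_scales * scale)

  ic_idx <- find_extrema(y, "min", min_separation = sep,
                         threshold = if (min(y) < 0) config$min_prominence_frac * min(y) else NULL)
  # FC candidates carry no separation gate: during short double-support
  # phases the true toe-off maximum sits close to the heel-strike recovery
  # flank, and the per-cycle dominant-maximum selection below adjudicates
  fc_idx <- find_extrema(z, "max", min_separation = 1,
                         threshold = if (max(z) > 0) config$min_prominence_frac * max(z) else NULL)
  in_bounds <- function(i) i[i > guard & i <= n - guard]
  ic_idx <- in_bounds(ic_idx); fc_idx <- in_bounds(fc_idx)

  diagnostics <- list(n_ic_candidates = length(ic_idx),
                      n_fc_candidates = length(fc_idx))
  if (!length(ic_idx)) {
    warning("no initial-contact minima found; returning empty event series")
    return(event_series("L5", "unassigned", numeric(0), numeric(0), diagnostics))
  }
  # keep at most one FC per IC-to-IC cycle: the dominant maximum inside it
  kept_fc <- integer(0)
  if (length(ic_idx) >= 2 && length(fc_idx)) {
    for (k in seq_len(length(ic_idx) - 1)) {
      inside <- fc_idx[fc_idx > ic_idx[k] & fc_idx < ic_idx[k + 1]]
      if (length(inside)) kept_fc <- c(kept_fc, inside[which.max(z[inside])])
    }
  }
  diagnostics$n_fc_dropped <- length(fc_idx) - length(kept_fc)
  tvec <- (seq_len(n) - 1) / fs
  event_series("L5", "unassigned", tvec[ic_idx], tvec[kept_fc], diagnostics)
}
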