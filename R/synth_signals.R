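# Add a Gaussian-shaped component to a sampled signal.  Only the +/- 6 sigma
# neighbourhood is touched, so per-event accumulation stays cheap.
add_gaussian <- function(x, fs, center, amplitude, sigma) {
  n <- length(x)
  i0 <- max(1L, floor((center - 6 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((center + 6 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  t <- (i0:i1 - 1) / fs
  x[i0:i1] <- x[i0:i1] + amplitude * exp(-(t - center)^2 / (2 * sigma^2))
  x
}

# Odd (derivative-of-Gaussian-like) transient: (tau/sigma) * exp(-tau^2/2sigma^2).
# Its time derivative is maximal exactly at `center`.
add_odd_transient <- function(x, fs, center, amplitude, sigma) {
  n <- length(x)
  i0 <- max(1L, floor((center - 6 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((center + 6 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  t <- (i0:i1 - 1) / fs
  u <- (t - center) / sigma
  x[i0:i1] <- x[i0:i1] + amplitude * u * exp(-u^2 / 2)
  x
}

# Gaussian-smoothed white noise (correlated noise floor for the horizontal
# channels); sd refers to the output standard deviation.
smoothed_noise <- function(n, fs, sd, smooth_s = 0.05) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  k <- ceiling(3 * smooth_s * fs)
  if (k >= 1) {
    kern <- exp(-((-k:k) / (smooth_s * fs))^2 / 2)
    kern <- kern / sqrt(sum(kern^2))
    w <- as.numeric(stats::filter(reflect_pad(w, k, k), rev(kern), sides = 2))[(k + 1):(k + n)]
  }
  sd * w
}

# Rotation matrix for a sensor tilt: pitch about the lateral (y) axis then
# roll about the anterior (x) axis, degrees.
tilt_rotation <- function(pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180; r <- roll_deg * pi / 180
  Ry <- matrix(c(cos(p), 0, sin(p), 0, 1, 0, -sin(p), 0, cos(p)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(r), -sin(r), 0, sin(r), cos(r)), 3, 3, byrow = TRUE)
  Rx %*% Ry
}

# Per-event local step time: spacing to the nearest neighbouring IC of
# either side, used to scale transient widths with cadence.
local_step_times <- function(script) {
  all_ic <- sort(c(script$ic$L, script$ic$R))
  if (length(all_ic) < 2) return(function(t) 0.55)
  gaps <- diff(all_ic)
  med <- stats::median(gaps[gaps < 2])
  function(t) {
    i <- findInterval(t, all_ic)
    g <- c(if (i >= 1 && i < length(all_ic)) all_ic[i + 1] - all_ic[i],
           if (i >= 2) all_ic[i] - all_ic[i - 1])
    g <- g[g < 2]
    if (length(g)) min(g) else med
  }
}

#' Synthesize a lumbar (L5) acceleration recording from a gait script
#'
#' Builds the vertical acceleration the lower-back detector assumes: gravity
#' plus, at every initial contact of either side, a positive-then-negative
#' impact transient (a difference of two Gaussians: an anticipatory positive
#' lobe followed by a heel-strike deceleration dip whose minimum sits at the
#' scripted IC; widths scale with the local step time), and at every final
#' contact an odd push-off transient whose rate of change peaks exactly at
#' the scripted FC (the feature the detector's second differentiation stage
#' keys on).  The three channels are then rotated by a fixed sensor tilt
#' (so tilt correction is exercised), and white noise is added.
#'
#' @param script A `gait_script` from [make_gait_script()].
#' @param fs Sampling rate, Hz (>= 30).
#' @param noise_sd White-noise SD added to all channels, m/s^2.
#' @param seed Integer seed for the noise streams.
#' @param tilt_deg Length-2 vector: sensor tilt (pitch, roll) in degrees.
#' @param morphology Named list of waveform scalars; see defaults in source.
#' @return An [imu_recording()] with placement `"L5"` (accelerometer only).
#' @export
synthesize_lumbar_accel <- function(script, fs = 100, noise_sd = 0.3, seed = 1,
                                    tilt_deg = c(5, 3),
                                    morphology = list()) {
  stopifnot(inherits(script, "gait_script"))
  if (fs < 30) stop("fs must be >= 30 Hz")
  ev <- c(script$ic$L, script$ic$R, script$fc$L, script$fc$R)
  if (!length(ev)) stop("script contains no events")
  set.seed(as.integer(seed))
  mor <- utils::modifyList(list(
    ic_dip_amp = 3.0,      # m/s^2, heel-strike deceleration dip
    ic_dip_sigma = 0.050,  # fraction of local step time
    ic_lobe_sigma = 0.28,
    ic_lobe_lead = 0.50,   # lobe centre lead, fraction of local step time
    fc_amp = 3.0,          # push-off odd-transient amplitude, m/s^2
    fc_sigma = 0.09,       # fraction of local step time
    hor_noise_sd = 0.4), morphology)
  # anticipatory lobe amplitude balances the dip area so each IC transient
  # integrates to zero and the vertical channel keeps its gravity baseline
  lobe_amp <- mor$ic_dip_amp * mor$ic_dip_sigma / mor$ic_lobe_sigma

  dur <- max(ev) + 1.5
  n <- ceiling(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  vz <- rep(STANDARD_GRAVITY, n)
  step_of <- local_step_times(script)
  for (tic in sort(c(script$ic$L, script$ic$R))) {
    st <- step_of(tic)
    vz <- add_gaussian(vz, fs, tic - mor$ic_lobe_lead * st,
                       lobe_amp, mor$ic_lobe_sigma * st)
    vz <- add_gaussian(vz, fs, tic, -mor$ic_dip_amp, mor$ic_dip_sigma * st)
  }
  for (tfc in sort(c(script$fc$L, script$fc$R))) {
    st <- step_of(tfc)
    vz <- add_odd_transient(vz, fs, tfc, mor$fc_amp, mor$fc_sigma * st)
  }
  ax <- smoothed_noise(n, fs, mor$hor_noise_sd)
  ay <- smoothed_noise(n, fs, mor$hor_noise_sd)
  accel <- cbind(x = ax, y = ay, z = vz)
  if (any(tilt_deg != 0)) {
    R <- tilt_rotation(tilt_deg[1], tilt_deg[2])
    accel <- accel %*% t(R)
    colnames(accel) <- c("x", "y", "z")
  }
  if (noise_sd > 0) accel <- accel + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  imu_recording(fs = fs, accel = accel, gyro = NULL, placement = "L5",
                subject_id = "", metadata = list(
                  cohort = script$cohort, environment = script$environment,
                  source = "synthetic", tilt_deg = tilt_deg,
                  noise_sd = noise_sd, seed = as.integer(seed)))
}

# Mid-swing anchor times of one side: the positive shank angular-velocity
# peak sits at FC + tms_swing_frac * (next IC - FC).  Placed in the first
# part of swing so the downstream IC search window (which opens 0.25 s
# after the anchor) still contains the next IC at typical cadences.
midswing_times <- function(script, side, tms_swing_frac = 0.28) {
  tt <- script$ic[[side]]; ff <- script$fc[[side]]
  if (length(tt) < 1) return(numeric(0))
  nxt <- c(tt[-1], NA)
  swing <- nxt - ff
  nominal_swing <- stats::median(swing[!is.na(swing) & swing < 1.5], na.rm = TRUE)
  if (!is.finite(nominal_swing)) nominal_swing <- 0.35 * script$params$stride_mean
  swing[is.na(swing) | swing > 1.5] <- nominal_swing
  ff + tms_swing_frac * swing
}

#' Synthesize a shank angular-velocity recording from a gait script
#'
#' Builds the sagittal-plane shank signal the shank detector assumes: per
#' gait cycle a large positive mid-swing lobe plus negative notches at the
#' scripted IC and FC, a linear gyroscope drift, optional tremor (PD), and
#' white noise.  The waveform is linear in its amplitude parameters.
#'
#' @param script A `gait_script`.
#' @param side `"L"` or `"R"`.
#' @param fs Sampling rate, Hz (>= 30).
#' @param noise_sd White-noise SD, deg/s.
#' @param drift_rate Linear drift, deg/s per second.
#' @param seed Integer seed.
#' @param morphology Named list of waveform scalars; see defaults in source.
#' @return An [imu_recording()] with placement `shank_left`/`shank_right`.
#' @export
synthesize_shank_gyro <- function(script, side = c("L", "R"), fs = 100,
                                  noise_sd = 5, drift_rate = 0.1, seed = 1,
                                  morphology = list()) {
  side <- match.arg(side)
  stopifnot(inherits(script, "gait_script"))
  if (fs < 30) stop("fs must be >= 30 Hz")
  if (!length(script$ic[[side]])) stop("side ", side, " absent from script")
  set.seed(as.integer(seed) + (if (side == "L") 0L else 1L))
  p <- script$params$cohort
  mor <- utils::modifyList(list(
    midswing_sigma = 0.06,  # fraction of swing time
    ic_sigma = 0.022,       # s
    fc_sigma = 0.050,       # s
    tms_swing_frac = 0.28,
    crosstalk = 0.08), morphology)

  ev <- c(script$ic$L, script$ic$R, script$fc$L, script$fc$R)
  dur <- max(ev) + 1.5
  n <- ceiling(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  w <- numeric(n)
  tt <- script$ic[[side]]; ff <- script$fc[[side]]
  tms <- midswing_times(script, side, mor$tms_swing_frac)
  nxt <- c(tt[-1], NA)
  swing <- nxt - ff
  nominal_swing <- stats::median(swing[!is.na(swing) & swing < 1.5], na.rm = TRUE)
  if (!is.finite(nominal_swing)) nominal_swing <- 0.35 * script$params$stride_mean
  swing[is.na(swing) | swing > 1.5] <- nominal_swing
  for (k in seq_along(tt)) {
    w <- add_gaussian(w, fs, tms[k], p$midswing_amplitude, mor$midswing_sigma * swing[k])
    w <- add_gaussian(w, fs, tt[k], -p$ic_notch_depth, mor$ic_sigma)
    w <- add_gaussian(w, fs, ff[k], -p$fc_notch_depth, mor$fc_sigma)
  }
  if (drift_rate != 0) w <- w + drift_rate * t
  if (p$tremor_amplitude > 0) {
    w <- w + p$tremor_amplitude * sin(2 * pi * 5 * t + stats::runif(1, 0, 2 * pi))
  }
  if (noise_sd > 0) w <- w + stats::rnorm(n, 0, noise_sd)
  gx <- smoothed_noise(n, fs, max(noise_sd, 1)) + mor$crosstalk * w
  gy <- smoothed_noise(n, fs, max(noise_sd, 1))
  gyro <- cbind(x = gx, y = gy, z = w)
  # nominal accelerometer block so the recording is a complete IMU stream
  accel <- cbind(x = smoothed_noise(n, fs, 0.2), y = smoothed_noise(n, fs, 0.2),
                 z = STANDARD_GRAVITY + smoothed_noise(n, fs, 0.3))
  imu_recording(fs = fs, accel = accel, gyro = gyro,
                placement = if (side == "L") "shank_left" else "shank_right",
                subject_id = "", metadata = list(
                  cohort = script$cohort, environment = script$environment,
                  source = "synthetic", side = side, noise_sd = noise_sd,
                  drift_rate = drift_rate, seed = as.integer(seed)))
}
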