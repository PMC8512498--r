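#' Cohort preset for the synthetic gait generator
#'
#' Bundles the timing statistics and waveform morphology scalars that the
#' generator uses for a cohort.  Default stride timing (mean, within-subject
#' SD, between-subject SDs, stance fraction, step asymmetry) follows the
#' indoor lower-back estimates reported for each cohort: young adults (YA)
#' stride 1.096 s, older adults (OA) 1.162 s, Parkinson's disease (PD)
#' 1.168 s, with the corresponding variability and asymmetry magnitudes.
#' Waveform amplitudes (mid-swing angular-velocity peak, event notch depths,
#' lumbar transient scalars) are not reported quantities; they are set to
#' typical literature magnitudes, with the PD mid-swing amplitude reduced to
#' emulate a shuffling, lower-amplitude shank swing.
#'
#' @param name `"YA"`, `"OA"` or `"PD"`.
#' @param ... Named overrides for any preset field.
#' @return Object of class `cohort_preset`.
#' @export
cohort_preset <- function(name = c("YA", "OA", "PD"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    YA = list(
      stride_mean = 1.096, stride_sd = 0.040,
      stride_mean_between_sd = 0.138, stride_sd_between_sd = 0.020,
      stance_fraction = 0.631, stance_fraction_between_sd = 0.020,
      stance_fraction_cycle_sd = 0.010,
      step_asymmetry_offset = 0.005, step_asymmetry_between_sd = 0.006,
      midswing_amplitude = 400, ic_notch_depth = 90, fc_notch_depth = 130,
      tremor_amplitude = 0),
    OA = list(
      stride_mean = 1.162, stride_sd = 0.086,
      stride_mean_between_sd = 0.077, stride_sd_between_sd = 0.030,
      stance_fraction = 0.608, stance_fraction_between_sd = 0.020,
      stance_fraction_cycle_sd = 0.012,
      step_asymmetry_offset = 0.001, step_asymmetry_between_sd = 0.002,
      midswing_amplitude = 330, ic_notch_depth = 75, fc_notch_depth = 110,
      tremor_amplitude = 0),
    PD = list(
      stride_mean = 1.168, stride_sd = 0.083,
      stride_mean_between_sd = 0.096, stride_sd_between_sd = 0.040,
      stance_fraction = 0.603, stance_fraction_between_sd = 0.025,
      stance_fraction_cycle_sd = 0.015,
      step_asymmetry_offset = 0.002, step_asymmetry_between_sd = 0.006,
      midswing_amplitude = 260, ic_notch_depth = 60, fc_notch_depth = 90,
      tremor_amplitude = 5))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown cohort preset field(s): ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  base$name <- name
  if (base$stride_mean <= 0) stop("stride_mean must be > 0")
  if (base$stride_sd < 0) stop("stride_sd must be >= 0")
  if (base$midswing_amplitude < 0 || base$ic_notch_depth < 0 ||
      base$fc_notch_depth < 0 || base$tremor_amplitude < 0) {
    stop("amplitudes must be >= 0")
  }
  structure(base, class = "cohort_preset")
}

#' Environment preset for the synthetic gait generator
#'
#' Describes a walking protocol as a sequence of bouts with per-bout speed
#' factors (multipliers on the cohort stride time) and event-free inter-bout
#' gaps:
#' \describe{
#'   \item{treadmill}{7 contiguous one-minute stages, belt speed ramped
#'     2 to 8 km/h in 1 km/h steps; cadence follows the heuristic
#'     stride time proportional to speed^(-1/2), referenced to 4 km/h.}
#'   \item{indoor}{4 repeated 10-20 m walks (normal, slow, fast, normal
#'     self-selected speed) modelled as 15 s bouts separated by 2 s turn
#'     gaps.}
#'   \item{outdoor}{2 longer 40-80 m walks at a single self-selected speed,
#'     modelled as 40 s bouts separated by a 5 s gap.}
#' }
#'
#' @param name `"treadmill"`, `"indoor"` or `"outdoor"`.
#' @param ... Named overrides (`bouts` data frame with columns `duration_s`
#'   and `speed_factor`, or `gap_s`).
#' @return Object of class `environment_preset`.
#' @export
environment_preset <- function(name = c("treadmill", "indoor", "outdoor"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    treadmill = list(
      bouts = data.frame(duration_s = rep(60, 7),
                         speed_kmh = 2:8,
                         speed_factor = (2:8 / 4)^(-0.5)),
      gap_s = 0),
    indoor = list(
      bouts = data.frame(duration_s = rep(15, 4),
                         speed_kmh = NA_real_,
                         speed_factor = c(1.0, 1.10, 0.92, 1.0)),
      gap_s = 2),
    outdoor = list(
      bouts = data.frame(duration_s = rep(40, 2),
                         speed_kmh = NA_real_,
                         speed_factor = c(1.0, 1.0)),
      gap_s = 5))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown environment preset field(s): ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  base$name <- name
  if (any(base$bouts$duration_s <= 0)) stop("bout durations must be > 0")
  if (name == "treadmill" && nrow(base$bouts) != 7 && !length(over)) {
    stop("treadmill ramp must have 7 stages")
  }
  structure(base, class = "environment_preset")
}
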