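#' Configuration for the shank event detector
#'
#' The shank pipeline decomposes the sagittal angular velocity with a
#' 10-level coif5 wavelet decomposition, removes drift (deep smooth) and
#' high-frequency artefacts (finest details) in an initial approximation,
#' and forms two further approximations: `a1`, retaining a slightly
#' sharper band for initial-contact search, and `a2`, slightly smoother
#' for final-contact search.  Band selections are stated as detail levels
#' at the 100 Hz reference rate and shifted by `round(log2(fs/100))`
#' levels at other rates so the analysed frequency band is unchanged.
#'
#' @param wavelet Only `"coif5"` is shipped.
#' @param decomposition_levels Decomposition depth (default 10).
#' @param ic_window Search window for ICs relative to the mid-swing anchor,
#'   s after tms; default `c(0.25, 2)`.
#' @param fc_window Search window for FCs, s relative to tms (negative =
#'   before); default `c(-2, -0.05)`.
#' @param midswing_min_height Minimum mid-swing peak height, deg/s; `NULL`
#'   means adaptive 0.2 x the maximum of the denoised signal.
#' @param midswing_min_separation Minimum spacing between mid-swing peaks, s.
#' @param baseline_levels Detail levels (at 100 Hz) kept in the denoised
#'   initial approximation used for mid-swing detection.
#' @param a1_levels,a2_levels Detail levels (at 100 Hz) kept in the IC and
#'   FC search approximations.
#' @return Object of class `shank_detector_config`.
#' @export
shank_detector_config <- function(wavelet = "coif5", decomposition_levels = 10,
                                  ic_window = c(0.25, 2),
                                  fc_window = c(-2, -0.05),
                                  midswing_min_height = NULL,
                                  midswing_min_separation = 0.5,
                                  baseline_levels = 3:8,
                                  a1_levels = 2:4,
                                  a2_levels = 4:6,
                                  anchor_margin = c(0.35, 0.15)) {
  if (!identical(wavelet, "coif5")) stop("unsupported wavelet '", wavelet, "'")
  if (decomposition_levels < 1) stop("decomposition_levels must be >= 1")
  if (!(ic_window[1] > 0 && ic_window[2] > ic_window[1])) {
    stop("ic_window offsets must be positive and ordered")
  }
  if (!(fc_window[1] < fc_window[2] && fc_window[2] < 0)) {
    stop("fc_window offsets must be negative and ordered")
  }
  structure(list(wavelet = wavelet, decomposition_levels = decomposition_levels,
                 ic_window = ic_window, fc_window = fc_window,
                 midswing_min_height = midswing_min_height,
                 midswing_min_separation = midswing_min_separation,
                 baseline_levels = baseline_levels,
                 a1_levels = a1_levels, a2_levels = a2_levels,
                 anchor_margin = anchor_margin),
            class = "shank_detector_config")
}

# Shift reference-rate level selections to the recording rate and clamp to
# the available depth.
shift_levels <- function(levels, fs, depth) {
  shift <- round(log2(fs / 100))
  out <- unique(pmin(pmax(levels + shift, 1L), depth))
  sort(out)
}

#' Wavelet approximations of a shank angular-velocity signal
#'
#' Runs the multi-level coif5 decomposition and returns the three band
#' reconstructions the event search uses: the denoised baseline (drift and
#' sensor noise suppressed), `a1` (sharper band, IC search) and `a2`
#' (smoother band, FC search).
#'
#' @param sagittal_gyro Sagittal angular-velocity channel, deg/s.
#' @param fs Sampling rate, Hz.
#' @param config A [shank_detector_config()].
#' @return Object of class `shank_detection_intermediate` with elements
#'   `baseline`, `a1`, `a2`, `fs`, and (once detected) `tms_times`.
#' @export
wavelet_denoise_shank <- function(sagittal_gyro, fs,
                                  config = shank_detector_config()) {
  stopifnot(inherits(config, "shank_detector_config"))
  x <- as.numeric(sagittal_gyro)
  J <- config$decomposition_levels
  # modwt_band_reconstruct validates depth and names the feasible maximum
  baseline <- modwt_band_reconstruct(x, J, shift_levels(config$baseline_levels, fs, J))
  a1 <- modwt_band_reconstruct(x, J, shift_levels(config$a1_levels, fs, J))
  a2 <- modwt_band_reconstruct(x, J, shift_levels(config$a2_levels, fs, J))
  structure(list(baseline = baseline, a1 = a1, a2 = a2, fs = fs, raw = x,
                 tms_times = NULL), class = "shank_detection_intermediate")
}

#' Detect per-cycle mid-swing peaks
#'
#' Finds the positive mid-swing angular-velocity peaks in the denoised
#' approximation: one dominant maximum per gait cycle, gated by a height
#' threshold (adaptive 0.2 x signal maximum by default) and a minimum
#' separation.  A literal single global maximum would yield one anchor per
#' recording; the per-cycle reading is required to anchor every stride's
#' event search.
#'
#' @param intermediate A `shank_detection_intermediate`.
#' @param fs Sampling rate, Hz (defaults to the intermediate's).
#' @param config A [shank_detector_config()].
#' @return Ascending mid-swing times, s.
#' @export
detect_midswing_peaks <- function(intermediate, fs = intermediate$fs,
                                  config = shank_detector_config()) {
  stopifnot(inherits(intermediate, "shank_detection_intermediate"))
  b <- intermediate$baseline
  height <- config$midswing_min_height
  if (is.null(height)) height <- 0.2 * max(b)
  if (max(b) <= 0 || height <= 0) {
    warning("no positive mid-swing peaks above threshold")
    return(numeric(0))
  }
  idx <- find_extrema(b, "max",
                      min_separation = round(config$midswing_min_separation * fs),
                      threshold = height)
  # a mid-swing peak is a positive angular velocity: drift removal can lift
  # parts of an all-negative signal above zero, so gate on the raw samples
  if (!is.null(intermediate$raw)) idx <- idx[intermediate$raw[idx] > 0]
  if (!length(idx)) {
    warning("no positive mid-swing peaks above threshold")
    return(numeric(0))
  }
  (idx - 1) / fs
}

# Most-negative local minimum of `x` between sample indices lo..hi
# (1-based, inclusive); ties broken toward `anchor`.  Falls back to the
# window's minimum sample when no interior local minimum exists.  Returns
# NA when the window is empty or contains no sample below -depth_floor
# (a scale-invariant floor that rejects numerical band-pass ringing).
most_negative_peak <- function(x, lo, hi, anchor, depth_floor = 0) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (hi < lo) return(NA_integer_)
  seg <- x[lo:hi]
  cand <- integer(0)
  if (length(seg) >= 3) {
    core <- 2:(length(seg) - 1)
    cand <- core[seg[core] < seg[core - 1] & seg[core] < seg[core + 1]]
  }
  cand <- cand[seg[cand] < -depth_floor]
  if (!length(cand)) {
    j <- which.min(seg)
    if (seg[j] >= -depth_floor) return(NA_integer_)
    return(lo + j - 1L)
  }
  best <- min(seg[cand])
  ties <- cand[abs(seg[cand] - best) <= 1e-12]
  j <- ties[which.min(abs((lo + ties - 1L) - anchor))]
  lo + j - 1L
}

#' Detect gait events from shank sagittal angular velocity
#'
#' Full shank pipeline: wavelet approximations, per-cycle mid-swing anchors,
#' then for each anchor the initial contact is the most-negative peak of
#' `a1` in the window (tms + 0.25 s, tms + 2 s) and the final contact the
#' most-negative peak of `a2` in (tms - 2 s, tms - 0.05 s).  Windows are
#' truncated at the recording boundaries and at the neighbouring anchors so
#' no event can be assigned to two cycles.  Cycles missing either event are
#' dropped from pairing but any found event is still reported; drop counts
#' are in the diagnostics.
#'
#' @param sagittal_gyro Sagittal angular-velocity channel, deg/s.
#' @param fs Sampling rate, Hz.
#' @param config A [shank_detector_config()].
#' @param side `"L"` or `"R"` (stamped on the output).
#' @return An [event_series()] for the given side.
#' @export
detect_events_shank <- function(sagittal_gyro, fs,
                                config = shank_detector_config(),
                                side = "L") {
  stopifnot(inherits(config, "shank_detector_config"))
  inter <- wavelet_denoise_shank(sagittal_gyro, fs, config)
  tms <- detect_midswing_peaks(inter, fs, config)
  n <- length(inter$a1)
  if (!length(tms)) {
    return(event_series(if (side == "L") "shank_left" else "shank_right",
                        side, numeric(0), numeric(0),
                        list(n_tms = 0L, n_dropped_cycles = 0L)))
  }
  ic_idx <- rep(NA_integer_, length(tms))
  fc_idx <- rep(NA_integer_, length(tms))
  floor_a1 <- 0.01 * max(abs(inter$a1))
  floor_a2 <- 0.01 * max(abs(inter$a2))
  for (k in seq_along(tms)) {
    anchor <- round(tms[k] * fs) + 1L
    # IC window after the anchor, stopped a safety margin before the next
    # anchor (a window may never cross the neighbouring anchor; the margin
    # additionally keeps the next swing peak's own support out of the search)
    lo <- anchor + ceiling(config$ic_window[1] * fs)
    hi <- anchor + floor(config$ic_window[2] * fs)
    if (k < length(tms)) {
      hi <- min(hi, round((tms[k + 1] - config$anchor_margin[1]) * fs))
    }
    ic_idx[k] <- most_negative_peak(inter$a1, lo, hi, anchor, floor_a1)
    # FC window before the anchor, stopped after the previous anchor
    lo <- anchor + ceiling(config$fc_window[1] * fs)
    hi <- anchor + floor(config$fc_window[2] * fs)
    if (k > 1) {
      lo <- max(lo, round((tms[k - 1] + config$anchor_margin[2]) * fs) + 1L)
    }
    fc_idx[k] <- most_negative_peak(inter$a2, lo, hi, anchor, floor_a2)
  }
  dropped <- sum(is.na(ic_idx) | is.na(fc_idx))
  tvec <- (seq_len(n) - 1) / fs
  ic <- sort(unique(tvec[ic_idx[!is.na(ic_idx)]]))
  fc <- sort(unique(tvec[fc_idx[!is.na(fc_idx)]]))
  event_series(if (side == "L") "shank_left" else "shank_right", side, ic, fc,
               list(n_tms = length(tms), n_dropped_cycles = dropped,
                    tms_times = tms))
}
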