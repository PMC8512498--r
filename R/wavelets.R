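# Orthonormal scaling (low-pass) filter of the 5th-order Coiflet, 30 taps.
# Frozen numeric constants of the standard coif5 filter bank; the wavelet
# (high-pass) filter is derived by the quadrature-mirror relation below.
coif5_dec_lo <- c(
  -9.6040101127678941e-08, -1.6237995172048338e-07,
   2.0612203985788783e-06,  3.7007277113394796e-06,
  -2.1270221672515614e-05, -4.1219861924265501e-05,
   1.4035632812373243e-04,  3.0185794166824478e-04,
  -6.3755892612588115e-04, -1.6616273039298788e-03,
   2.4315754425382886e-03,  6.7615202206204169e-03,
  -9.1595073386761625e-03, -1.9758391600965465e-02,
   3.2674799467057355e-02,  4.1287530472117834e-02,
  -1.0556315130733723e-01, -6.2037751574981960e-02,
   4.3798230665916338e-01,  7.7429362286032744e-01,
   4.2157126673075435e-01, -5.2046670253554764e-02,
  -9.1921588060086087e-02,  2.8169744270532353e-02,
   2.3408322118927783e-02, -1.0131584846900276e-02,
  -4.1593126275786402e-03,  2.1782943778456947e-03,
   3.5857774116175768e-04, -2.1208186206749400e-04)

#' Wavelet filter bank for the maximal-overlap discrete wavelet transform
#'
#' Returns the MODWT-rescaled scaling and wavelet filters (original
#' orthonormal filters divided by sqrt(2)) for the supported wavelet.
#'
#' @param wavelet Filter name; only `"coif5"` is shipped.
#' @return List with elements `h` (scaling) and `g` (wavelet).
#' @keywords internal
modwt_filters <- function(wavelet = "coif5") {
  if (!identical(wavelet, "coif5")) {
    stop("unsupported wavelet '", wavelet, "'; available: coif5")
  }
  lo <- coif5_dec_lo
  L <- length(lo)
  # quadrature mirror: g_l = (-1)^l h_{L-1-l}
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(h = lo / sqrt(2), g = hi / sqrt(2))
}

# Reflection-pad a signal by nl samples on the left and nr on the right.
# Reflections are tiled so pads longer than the signal are permitted.
reflect_pad <- function(x, nl, nr) {
  n <- length(x)
  tile <- c(x, rev(x))            # period-2n reflection tiling
  idx_left <- ((-(nl:1)) %% (2 * n)) + 1
  idx_right <- ((n + seq_len(nr) - 1) %% (2 * n)) + 1
  c(tile[idx_left], x, tile[idx_right])
}

#' Maximal-overlap wavelet multiresolution transfer functions
#'
#' Computes the squared-magnitude (zero-phase) transfer function of each
#' multiresolution detail level and of the level-J smooth for a circular
#' MODWT of length `n`.  Because every detail transfer is real and
#' non-negative, reconstructions from any subset of levels preserve the
#' timing of signal features exactly (no phase distortion).
#'
#' @param n Signal length (samples).
#' @param levels Number of decomposition levels J.
#' @param wavelet Filter name passed to [modwt_filters()].
#' @return A `(levels + 1) x n` matrix; rows `1..levels` are detail
#'   transfers D1..DJ, the last row is the smooth SJ.  Rows sum to 1 at
#'   every frequency.
#' @keywords internal
modwt_mra_transfer <- function(n, levels, wavelet = "coif5") {
  flt <- modwt_filters(wavelet)
  Hf <- stats::fft(c(flt$h, rep(0, n - length(flt$h))))
  Gf <- stats::fft(c(flt$g, rep(0, n - length(flt$g))))
  H2 <- Re(Hf * Conj(Hf))
  G2 <- Re(Gf * Conj(Gf))
  out <- matrix(0, nrow = levels + 1, ncol = n)
  cumA <- rep(1, n)
  k <- 0:(n - 1)
  for (j in seq_len(levels)) {
    idx <- ((2^(j - 1) * k) %% n) + 1
    out[j, ] <- G2[idx] * cumA
    cumA <- cumA * H2[idx]
  }
  out[levels + 1, ] <- cumA
  out
}

#' Multiresolution band reconstruction with the MODWT
#'
#' Decomposes `x` into `levels` maximal-overlap wavelet detail levels
#' (coif5 by default) and reconstructs the component carried by the
#' selected detail levels (optionally plus the deep smooth).  Level `j`
#' spans roughly the frequency octave `fs/2^(j+1)` to `fs/2^j`.
#' The signal is reflection-padded before the circular transform so
#' boundary wrap-around does not leak into the reconstruction.
#'
#' @param x Numeric signal.
#' @param levels Total decomposition depth J (must satisfy 2^J <= length(x)).
#' @param keep Integer vector of detail levels to retain (subset of 1..J).
#' @param keep_smooth Retain the level-J smooth (drift/DC) as well?
#' @param wavelet Filter name.
#' @return Numeric vector, same length as `x`.
#' @export
modwt_band_reconstruct <- function(x, levels, keep, keep_smooth = FALSE,
                                   wavelet = "coif5") {
  n <- length(x)
  if (n < 4) stop("signal too short for wavelet decomposition")
  max_levels <- floor(log2(n))
  if (levels > max_levels) {
    stop("decomposition_levels = ", levels,
         " too deep for signal of length ", n,
         "; maximum feasible depth is ", max_levels)
  }
  if (length(keep) && (min(keep) < 1 || max(keep) > levels)) {
    stop("'keep' levels must lie in 1..", levels)
  }
  pad <- min(n, 4096L)
  m0 <- n + 2L * pad
  m <- stats::nextn(m0, c(2, 3, 5))
  xp <- reflect_pad(x, pad, pad + (m - m0))
  tr <- modwt_mra_transfer(m, levels, wavelet)
  sel <- rep(0, m)
  for (j in keep) sel <- sel + tr[j, ]
  if (keep_smooth) sel <- sel + tr[levels + 1, ]
  y <- Re(stats::fft(stats::fft(xp) * sel, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

#' Continuous wavelet transform with a first-derivative-of-Gaussian wavelet
#'
#' Correlates the signal with the odd wavelet `psi(u) = u * exp(-u^2/2)`
#' dilated to `scale` samples, i.e. a smoothed differentiator: the output
#' is proportional to the derivative of the Gaussian-smoothed signal.
#' Boundaries are handled by reflection padding.
#'
#' @param x Numeric signal.
#' @param scale Wavelet scale in samples (> 0).
#' @return Numeric vector, same length as `x`.
#' @export
cwt_gaus1 <- function(x, scale) {
  if (scale <= 0) stop("scale must be positive")
  K <- ceiling(5 * scale)
  u <- (-K:K) / scale
  psi <- u * exp(-u^2 / 2)
  psi <- psi / sqrt(scale)
  xp <- reflect_pad(x, K, K)
  # cross-correlation: y[t] = sum_k x[t + k] * psi[k]
  y <- stats::filter(xp, rev(psi), method = "convolution", sides = 2)
  as.numeric(y[(K + 1):(K + length(x))])
}
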