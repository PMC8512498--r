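#' Strict local extrema with magnitude-priority minimum separation
#'
#' Finds strict local maxima (or minima) of a sampled signal and enforces a
#' minimum separation between accepted extrema: candidates are visited in
#' order of decreasing magnitude and accepted only if no already-accepted
#' extremum lies within `min_separation` samples.  This greedy rule keeps
#' the dominant extremum when two candidates crowd each other, which is the
#' behaviour wanted when suppressing spurious secondary peaks.
#'
#' @param x Numeric signal.
#' @param mode `"max"` or `"min"`.
#' @param min_separation Minimum distance between accepted extrema, samples.
#' @param threshold Optional height gate: maxima must exceed it, minima must
#'   fall below it (same sign convention as the signal).
#' @return Integer vector of accepted extremum indices, ascending.
#' @keywords internal
find_extrema <- function(x, mode = c("max", "min"), min_separation = 1,
                         threshold = NULL) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- if (mode == "max") x else -x
  core <- 2:(n - 1)
  cand <- core[s[core] > s[core - 1] & s[core] > s[core + 1]]
  if (!is.null(threshold)) {
    thr <- if (mode == "max") threshold else -threshold
    cand <- cand[s[cand] > thr]
  }
  if (!length(cand)) return(integer(0))
  cand <- cand[order(s[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || min(abs(accepted - i)) >= min_separation) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}
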