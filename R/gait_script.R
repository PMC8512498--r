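# Truncated-normal draws: truncation at +/- trunc_sd standard deviations,
# then a hard floor.  Inverse-CDF sampling keeps the stream reproducible.
rtruncnorm_floor <- function(n, mean, sd, trunc_sd = 3, floor_at = 0.2) {
  if (sd <= 0) return(pmax(rep(mean, n), floor_at))
  lo <- stats::pnorm(-trunc_sd)
  hi <- stats::pnorm(trunc_sd)
  x <- mean + sd * stats::qnorm(lo + stats::runif(n) * (hi - lo))
  pmax(x, floor_at)
}

#' Generate a ground-truth gait event schedule
#'
#' Draws a bilateral initial-contact / final-contact schedule for one
#' synthetic subject walking a given protocol.  Subject-level parameters
#' (personal mean stride time, within-subject stride SD, stance fraction,
#' step asymmetry) are first drawn around the cohort preset's population
#' values; step times are then drawn per step from a truncated normal
#' (truncation at 3 SD, floor 0.2 s), left/right strictly interleaved, the
#' asymmetry offset split +a/2 / -a/2 between the sides so the mean stride
#' time is unchanged, and each final contact placed at the cycle's stance
#' fraction of the way to the next same-side initial contact.  Inter-bout
#' gaps contain no events.
#'
#' @param cohort A [cohort_preset()] (or cohort name).
#' @param environment An [environment_preset()] (or environment name).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param lead_in_s Quiet time before the first bout, s.
#' @return Object of class `gait_script`: per-side IC/FC times (s), bout
#'   boundaries, and the generator parameters used.
#' @export
make_gait_script <- function(cohort, environment, seed, lead_in_s = 2) {
  if (missing(seed) || is.null(seed)) stop("seed is required (reproducibility is mandatory)")
  if (is.character(cohort)) cohort <- cohort_preset(cohort)
  if (is.character(environment)) environment <- environment_preset(environment)
  stopifnot(inherits(cohort, "cohort_preset"), inherits(environment, "environment_preset"))
  set.seed(as.integer(seed))

  # subject-level draws around cohort population values
  subj <- list(
    stride_mean = rtruncnorm_floor(1, cohort$stride_mean,
                                   cohort$stride_mean_between_sd, floor_at = 0.5),
    stride_sd = if (cohort$stride_sd > 0 && cohort$stride_sd_between_sd > 0) {
      # lognormal keeps the within-subject SD positive and right-skewed
      m <- cohort$stride_sd; s <- cohort$stride_sd_between_sd
      sdlog <- sqrt(log(1 + (s / m)^2)); meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(1, meanlog, sdlog)
    } else cohort$stride_sd,
    stance_fraction = min(0.75, max(0.45,
      stats::rnorm(1, cohort$stance_fraction, cohort$stance_fraction_between_sd))),
    step_asymmetry = max(0, stats::rnorm(1, cohort$step_asymmetry_offset,
                                          cohort$step_asymmetry_between_sd)))

  ic <- list(L = numeric(0), R = numeric(0))
  fc <- list(L = numeric(0), R = numeric(0))
  bouts <- data.frame(start = numeric(0), end = numeric(0))
  cursor <- lead_in_s
  side <- "L"
  for (b in seq_len(nrow(environment$bouts))) {
    dur <- environment$bouts$duration_s[b]
    sf_speed <- environment$bouts$speed_factor[b]
    bout_start <- cursor
    bout_end <- bout_start + dur
    t <- bout_start + 0.5 * subj$stride_mean * sf_speed  # settle-in before first IC
    while (t < bout_end) {
      ic[[side]] <- c(ic[[side]], t)
      step_mean <- subj$stride_mean * sf_speed / 2 +
        (if (side == "L") 1 else -1) * subj$step_asymmetry / 2
      step <- rtruncnorm_floor(1, step_mean, subj$stride_sd / sqrt(2))
      side <- if (side == "L") "R" else "L"
      t <- t + step
    }
    bouts <- rbind(bouts, data.frame(start = bout_start, end = bout_end))
    cursor <- bout_end + environment$gap_s
  }

  # final contacts at the cycle stance fraction; the last cycle of each side
  # (no following IC) uses the nominal stride length
  for (s in c("L", "R")) {
    tt <- ic[[s]]
    if (!length(tt)) next
    nxt <- c(tt[-1], NA)
    # strides across bout gaps get the nominal stride, not the gap span
    stride <- nxt - tt
    nominal <- subj$stride_mean
    stride[is.na(stride) | stride > 1.8 * nominal + 0.5] <- nominal
    sf <- pmin(0.78, pmax(0.42,
      stats::rnorm(length(tt), subj$stance_fraction, cohort$stance_fraction_cycle_sd)))
    # swing time is comparatively speed-invariant in human gait: cap the
    # stance fraction of short strides so swing never collapses below ~0.38 s
    sf <- pmax(0.42, pmin(sf, 1 - 0.38 / stride))
    fc[[s]] <- tt + sf * stride
  }

  structure(list(ic = ic, fc = fc, bouts = bouts,
                 params = c(subj, list(cohort = cohort, environment = environment,
                                       seed = as.integer(seed))),
                 cohort = cohort$name, environment = environment$name),
            class = "gait_script")
}

#' Validate the ordering invariants of a gait script
#'
#' Checks per side that IC(k) < FC(k) < IC(k+1), that every complete cycle's
#' stance fraction lies in (0.4, 0.8), and that left and right initial
#' contacts alternate within each bout.
#'
#' @param script A `gait_script`.
#' @return `script`, invisibly; errors otherwise.
#' @export
validate_gait_script <- function(script) {
  stopifnot(inherits(script, "gait_script"))
  for (s in c("L", "R")) {
    tt <- script$ic[[s]]; ff <- script$fc[[s]]
    if (length(tt) != length(ff)) stop("IC/FC count mismatch on side ", s)
    if (any(ff <= tt)) stop("FC must follow its IC on side ", s)
    if (length(tt) > 1) {
      if (any(ff[-length(ff)] >= tt[-1])) stop("FC must precede the next IC on side ", s)
      stride <- diff(tt)
      frac <- (ff[-length(ff)] - tt[-length(tt)]) / stride
      in_bout <- stride < 2.5   # cycles spanning bout gaps are not constrained
      if (any(in_bout & (frac <= 0.4 | frac >= 0.8))) {
        stop("stance fraction outside (0.4, 0.8) on side ", s)
      }
    }
  }
  for (b in seq_len(nrow(script$bouts))) {
    lo <- script$bouts$start[b]; hi <- script$bouts$end[b]
    ev <- rbind(data.frame(t = script$ic$L, s = "L"),
                data.frame(t = script$ic$R, s = "R"))
    ev <- ev[ev$t >= lo & ev$t <= hi, ]
    ev <- ev[order(ev$t), ]
    if (nrow(ev) > 1 && any(ev$s[-1] == ev$s[-nrow(ev)])) {
      stop("left/right ICs do not alternate within bout ", b)
    }
  }
  invisible(script)
}

#' Ground-truth events of a script as a tidy data frame
#' @param script A `gait_script`.
#' @param subject_id Identifier to stamp on each row.
#' @return Data frame with columns `subject_id`, `side`, `event_type`, `time_s`.
#' @export
script_events <- function(script, subject_id = "") {
  out <- do.call(rbind, lapply(c("L", "R"), function(s) {
    rbind(data.frame(subject_id = subject_id, side = s, event_type = "IC",
                     time_s = script$ic[[s]], stringsAsFactors = FALSE),
          data.frame(subject_id = subject_id, side = s, event_type = "FC",
                     time_s = script$fc[[s]], stringsAsFactors = FALSE))
  }))
  out[order(out$side, out$time_s), ]
}
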