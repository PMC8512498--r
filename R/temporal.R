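#' Pair detected events into gait cycles
#'
#' Per side, cycles are formed from consecutive initial-contact pairs with
#' the unique final contact strictly between them.  Cycles with no FC or
#' more than one FC inside (the "extra FCs" failure mode) are dropped and
#' counted, as are cycles spanning an event-free gap longer than `max_gap`
#' (turns, bout boundaries).  Each cycle also carries the contralateral IC
#' falling strictly inside the cycle (the step-time reference: in
#' alternating gait exactly one opposite-foot contact occurs between a
#' foot's consecutive contacts) when one exists.
#'
#' @param left,right [event_series()] objects for the two sides.
#' @param max_gap Longest credible stride; longer IC-to-IC spans are treated
#'   as walking interruptions (default 2.5 s).
#' @return Data frame (class `cycle_table`) with columns `side`,
#'   `cycle_index`, `ic`, `fc`, `next_ic`, `contra_ic` (NA when absent);
#'   attribute `diagnostics` carries drop counts.
#' @export
build_gait_cycles <- function(left, right, max_gap = 2.5) {
  sides <- list(L = left, R = right)
  for (s in names(sides)) {
    es <- sides[[s]]
    if (is.unsorted(es$ic_times) || is.unsorted(es$fc_times)) {
      stop("event series for side ", s, " is not ordered")
    }
  }
  diag <- list(n_no_fc = 0L, n_extra_fc = 0L, n_gap = 0L)
  rows <- list()
  for (s in names(sides)) {
    ic <- sides[[s]]$ic_times
    fc <- sides[[s]]$fc_times
    contra <- sides[[if (s == "L") "R" else "L"]]$ic_times
    if (length(ic) < 2) next
    for (k in seq_len(length(ic) - 1)) {
      a <- ic[k]; b <- ic[k + 1]
      if (b - a > max_gap) { diag$n_gap <- diag$n_gap + 1L; next }
      inside <- fc[fc > a & fc < b]
      if (length(inside) == 0) { diag$n_no_fc <- diag$n_no_fc + 1L; next }
      if (length(inside) > 1) { diag$n_extra_fc <- diag$n_extra_fc + 1L; next }
      mid <- contra[contra > a & contra < b]
      rows[[length(rows) + 1]] <- data.frame(
        side = s, cycle_index = k, ic = a, fc = inside, next_ic = b,
        contra_ic = if (length(mid)) mid[1] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(0), cycle_index = integer(0), ic = numeric(0),
               fc = numeric(0), next_ic = numeric(0), contra_ic = numeric(0))
  out <- out[order(out$side, out$ic), ]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  class(out) <- c("cycle_table", class(out))
  out
}

#' Per-cycle temporal gait parameters
#'
#' Standard definitions: stride = IC-to-next-same-side-IC, stance =
#' IC-to-FC, swing = FC-to-next-IC (so stride = stance + swing exactly),
#' step = interval from the cycle's IC to the contralateral IC inside the
#' cycle (absent when no contralateral reference exists).  Step times
#' require contacts of both feet; each row's step is the opposite foot's
#' step time, so pooled and per-side-contrast summaries cover every step
#' exactly once.
#'
#' @param cycles A `cycle_table` from [build_gait_cycles()].
#' @return Data frame (class `temporal_series`) with columns `side`,
#'   `stride_time`, `stance_time`, `swing_time`, `step_time` (s).
#' @export
compute_temporal_series <- function(cycles) {
  out <- data.frame(
    side = cycles$side,
    stride_time = cycles$next_ic - cycles$ic,
    stance_time = cycles$fc - cycles$ic,
    swing_time = cycles$next_ic - cycles$fc,
    step_time = cycles$contra_ic - cycles$ic,
    stringsAsFactors = FALSE)
  class(out) <- c("temporal_series", class(out))
  out
}

#' Subject-level summary of temporal gait parameters
#'
#' For each parameter (stride, stance, swing, step time) computes the mean
#' over all cycles (both sides pooled), the variability, and the left-right
#' asymmetry.  Variability defaults to the sample SD of the pooled per-cycle
#' values; asymmetry defaults to |left mean - right mean|.  Entries whose
#' preconditions fail (fewer than 2 cycles for variability, fewer than 2
#' cycles on each side for asymmetry) are NA, not zero.
#'
#' @param series A `temporal_series`.
#' @param variability `"pooled_sd"` (default) or `"mean_side_sd"` (mean of
#'   the per-side SDs).
#' @param asymmetry `"mean_diff"` (default, |mean_L - mean_R|) or
#'   `"per_cycle"` (mean |L - R| over side-paired consecutive cycles).
#' @return Data frame (class `temporal_summary`) with columns `parameter`,
#'   `mean`, `variability`, `asymmetry`, `n_cycles`.
#' @export
summarize_temporal <- function(series,
                               variability = c("pooled_sd", "mean_side_sd"),
                               asymmetry = c("mean_diff", "per_cycle")) {
  variability <- match.arg(variability)
  asymmetry <- match.arg(asymmetry)
  params <- c(stride = "stride_time", stance = "stance_time",
              swing = "swing_time", step = "step_time")
  rows <- lapply(names(params), function(p) {
    x <- series[[params[p]]]
    side <- series$side[!is.na(x)]
    x <- x[!is.na(x)]
    n <- length(x)
    mean_p <- if (n >= 1) mean(x) else NA_real_
    var_p <- if (n >= 2) {
      if (variability == "pooled_sd") stats::sd(x) else {
        sds <- tapply(x, side, stats::sd)
        mean(sds, na.rm = TRUE)
      }
    } else NA_real_
    xl <- x[side == "L"]; xr <- x[side == "R"]
    asym_p <- if (length(xl) >= 2 && length(xr) >= 2) {
      if (asymmetry == "mean_diff") abs(mean(xl) - mean(xr)) else {
        m <- min(length(xl), length(xr))
        mean(abs(xl[seq_len(m)] - xr[seq_len(m)]))
      }
    } else NA_real_
    data.frame(parameter = p, mean = mean_p, variability = var_p,
               asymmetry = asym_p, n_cycles = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("temporal_summary", class(out))
  out
}
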