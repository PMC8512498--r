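es <- function(side, ic, fc) {
  event_series("L5", side, ic, fc)
}

test_that("the minimal bilateral case builds one correct left cycle", {
  left <- es("L", c(0.0, 1.2), 0.7)
  right <- es("R", 0.6, numeric(0))
  cyc <- build_gait_cycles(left, right)
  lrow <- cyc[cyc$side == "L", ]
  expect_equal(nrow(lrow), 1)
  expect_equal(unlist(lrow[, c("ic", "fc", "next_ic", "contra_ic")]),
               c(ic = 0, fc = 0.7, next_ic = 1.2, contra_ic = 0.6))
  ts <- compute_temporal_series(cyc)
  tl <- ts[ts$side == "L", ]
  expect_equal(tl$stride_time, 1.2)
  expect_equal(tl$stance_time, 0.7)
  expect_equal(tl$swing_time, 0.5)
  expect_equal(tl$step_time, 0.6)
})

test_that("cycles with zero or multiple interior FCs are dropped and counted", {
  left <- es("L", c(0, 1.2, 2.4), c(0.5, 0.9))   # two FCs in the first cycle
  right <- es("R", numeric(0), numeric(0))
  cyc <- build_gait_cycles(left, right)
  d <- attr(cyc, "diagnostics")
  expect_equal(d$n_extra_fc, 1)
  expect_equal(d$n_no_fc, 1)                      # second cycle has no FC
  expect_equal(nrow(cyc), 0)
  unordered <- structure(list(placement = "L5", side = "L",
                              ic_times = c(2, 1), fc_times = numeric(0),
                              diagnostics = list()), class = "event_series")
  expect_error(build_gait_cycles(unordered, right), "ordered")
})

test_that("cycles spanning long event-free gaps are excluded", {
  left <- es("L", c(0, 1.1, 5.0, 6.1), c(0.7, 5.7))
  right <- es("R", numeric(0), numeric(0))
  cyc <- build_gait_cycles(left, right)
  expect_equal(nrow(cyc), 2)
  expect_equal(attr(cyc, "diagnostics")$n_gap, 1)
})

test_that("stride decomposes exactly into stance plus swing everywhere", {
  fix <- clean_ya_subject()
  for (alg in c("events_a1", "events_a2")) {
    ev <- fix$result[[alg]]
    cyc <- build_gait_cycles(ev$L, ev$R)
    ts <- compute_temporal_series(cyc)
    expect_equal(ts$stance_time + ts$swing_time, ts$stride_time,
                 tolerance = 1e-12)
    sm <- summarize_temporal(ts)
    expect_equal(sm$mean[sm$parameter == "stride"],
                 sm$mean[sm$parameter == "stance"] + sm$mean[sm$parameter == "swing"],
                 tolerance = 1e-12)
  }
})

test_that("summaries reproduce hand-computed two-cycle statistics", {
  ts <- structure(data.frame(side = c("L", "L", "R", "R"),
                             stride_time = c(1.0, 1.2, 1.0, 1.2),
                             stance_time = c(0.6, 0.7, 0.6, 0.7),
                             swing_time = c(0.4, 0.5, 0.4, 0.5),
                             step_time = c(0.5, 0.6, 0.5, 0.6)),
                  class = c("temporal_series", "data.frame"))
  sm <- summarize_temporal(ts)
  expect_equal(sm$mean[sm$parameter == "stride"], 1.1)
  expect_equal(sm$variability[sm$parameter == "stride"], sd(c(1, 1.2, 1, 1.2)))
  expect_equal(sm$asymmetry[sm$parameter == "stride"], 0)
})

test_that("too few cycles yield flagged absent summaries, not zeros", {
  ts <- structure(data.frame(side = "L", stride_time = 1.1,
                             stance_time = 0.7, swing_time = 0.4,
                             step_time = NA_real_),
                  class = c("temporal_series", "data.frame"))
  sm <- summarize_temporal(ts)
  expect_true(is.na(sm$variability[sm$parameter == "stride"]))
  expect_true(is.na(sm$asymmetry[sm$parameter == "stride"]))
  expect_true(is.na(sm$mean[sm$parameter == "step"]))
})

test_that("summaries are invariant to a global time shift", {
  fix <- clean_ya_subject()
  ev <- fix$result$events_a2
  shift <- function(e, dt) event_series(e$placement, e$side,
                                        e$ic_times + dt, e$fc_times + dt)
  s0 <- summarize_temporal(compute_temporal_series(build_gait_cycles(ev$L, ev$R)))
  s1 <- summarize_temporal(compute_temporal_series(
    build_gait_cycles(shift(ev$L, 17.3), shift(ev$R, 17.3))))
  expect_equal(s0$mean, s1$mean, tolerance = 1e-9)
  expect_equal(s0$variability, s1$variability, tolerance = 1e-9)
})

test_that("ground-truth schedules recover the generator's parameters", {
  co <- cohort_preset("YA", stride_mean_between_sd = 0, stride_sd_between_sd = 0,
                      step_asymmetry_offset = 0.02, step_asymmetry_between_sd = 0,
                      stance_fraction = 0.6, stance_fraction_between_sd = 0)
  sc <- make_gait_script(co, steady_walk(240), seed = 17)
  tr <- truth_series(sc)
  cyc <- build_gait_cycles(tr$L, tr$R)
  expect_equal(nrow(cyc[cyc$side == "L", ]), length(sc$ic$L) - 1)
  ts <- compute_temporal_series(cyc)
  sm <- summarize_temporal(ts)
  n <- sm$n_cycles[sm$parameter == "stride"]
  expect_gt(n, 200)
  se <- sm$variability[sm$parameter == "stride"] / sqrt(n)
  expect_lt(abs(sm$mean[sm$parameter == "stride"] - 1.096), 2 * se + 1e-9)
  # variability recovers the generator SD within 10 %
  expect_lt(abs(sm$variability[sm$parameter == "stride"] - sc$params$stride_sd),
            0.1 * sc$params$stride_sd)
  # step asymmetry recovers the scripted offset
  expect_gt(sm$asymmetry[sm$parameter == "step"], 0.015)
  expect_lt(sm$asymmetry[sm$parameter == "step"], 0.025)
  # mean stance fraction matches the scripted value
  expect_equal(sm$mean[sm$parameter == "stance"] / sm$mean[sm$parameter == "stride"],
               sc$params$stance_fraction, tolerance = 0.02)
})

test_that("a perfectly symmetric script has zero asymmetry everywhere", {
  co <- cohort_preset("YA", stride_sd = 0, stride_mean_between_sd = 0,
                      stride_sd_between_sd = 0, step_asymmetry_offset = 0,
                      step_asymmetry_between_sd = 0,
                      stance_fraction_between_sd = 0, stance_fraction_cycle_sd = 0)
  sc <- make_gait_script(co, steady_walk(30), seed = 2)
  tr <- truth_series(sc)
  sm <- summarize_temporal(compute_temporal_series(build_gait_cycles(tr$L, tr$R)))
  expect_true(all(sm$asymmetry < 1e-9))
})
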