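test_that("degenerate inputs yield empty intermediates and anchor lists", {
  cfg <- shank_detector_config(decomposition_levels = 6)
  z <- wavelet_denoise_shank(rep(0, 400), 100, cfg)
  expect_true(all(z$baseline == 0) && all(z$a1 == 0) && all(z$a2 == 0))
  expect_warning(tms <- detect_midswing_peaks(z, 100, cfg), "no positive")
  expect_length(tms, 0)
  neg <- wavelet_denoise_shank(-abs(rnorm(400)) - 50, 100, cfg)
  expect_warning(tms2 <- detect_midswing_peaks(neg, 100, cfg), "no positive")
  expect_length(tms2, 0)
})

test_that("a single synthetic cycle anchors exactly one mid-swing peak", {
  fs <- 100
  t <- (0:1499) / fs
  x <- 300 * exp(-(t - 7.5)^2 / (2 * 0.04^2)) -
    80 * exp(-(t - 8)^2 / (2 * 0.03^2)) - 100 * exp(-(t - 7.35)^2 / (2 * 0.05^2))
  inter <- wavelet_denoise_shank(x, fs)
  tms <- detect_midswing_peaks(inter, fs)
  expect_length(tms, 1)
  expect_lte(abs(tms - 7.5), 0.01)
})

test_that("a 30-stride bout yields one anchor per stride with consistent spacing", {
  sc <- make_gait_script(cohort_preset("YA", stride_mean_between_sd = 0,
                                       stride_sd_between_sd = 0),
                         steady_walk(34), seed = 21)
  rec <- synthesize_shank_gyro(sc, "L", fs = 100, noise_sd = 0,
                               drift_rate = 0, seed = 1)
  inter <- wavelet_denoise_shank(rec$gyro[, 3], 100)
  tms <- detect_midswing_peaks(inter, 100)
  expect_gte(length(sc$ic$L), 30)
  expect_equal(length(tms), length(sc$ic$L))
  truth <- imugait:::midswing_times(sc, "L")
  sd_true <- sd(diff(truth))
  sd_est <- sd(diff(tms))
  se <- sd_true / sqrt(2 * (length(tms) - 1))
  expect_lt(abs(sd_est - sd_true), 4 * se + 0.005)
})

test_that("noise-free shank events are recovered accurately on both sides", {
  fix <- clean_ya_subject()
  sc <- fix$subject$script
  for (side in c("L", "R")) {
    es <- fix$result$events_a2[[side]]
    mi <- match_events(es$ic_times, sc$ic[[side]], tol = 0.05)
    mf <- match_events(es$fc_times, sc$fc[[side]], tol = 0.05)
    expect_gte(mi$match_rate, 0.95)
    expect_gte(mf$match_rate, 0.95)
    expect_lt(mi$median_abs_error, 0.03)
    expect_lt(mf$median_abs_error, 0.03)
  }
})

test_that("every emitted cycle orders FC before its anchor before the next IC", {
  fix <- clean_ya_subject()
  for (side in c("L", "R")) {
    es <- fix$result$events_a2[[side]]
    tms <- es$diagnostics$tms_times
    for (tm in tms) {
      ic_after <- es$ic_times[es$ic_times > tm]
      fc_before <- es$fc_times[es$fc_times < tm]
      if (length(ic_after) && length(fc_before)) {
        expect_gt(min(ic_after) - tm, 0.2)
        expect_lt(tm - max(fc_before), 2)
      }
    }
  }
})

test_that("a cycle whose IC window is truncated away reports a dropped cycle", {
  fs <- 100
  t <- (0:1199) / fs
  # one cycle near the end of the recording: FC notch, then mid-swing lobe;
  # the IC window (anchor + 0.25 s onward) falls beyond the signal end
  x <- 300 * exp(-(t - 11.8)^2 / (2 * 0.04^2)) -
    120 * exp(-(t - 11.65)^2 / (2 * 0.05^2))
  es <- detect_events_shank(x, fs, side = "L")
  expect_length(es$ic_times, 0)
  expect_length(es$fc_times, 1)
  expect_equal(es$diagnostics$n_dropped_cycles, 1)
})

test_that("shank detections shift exactly with a time-shifted input", {
  fix <- clean_ya_subject()
  x <- fix$subject$shank_left$gyro[, 3]
  k <- 100  # 1.00 s
  xs <- c(rep(x[1], k), x[1:(length(x) - k)])
  a <- detect_events_shank(x, 100, side = "L")
  b <- detect_events_shank(xs, 100, side = "L")
  aa <- a$ic_times[a$ic_times > 3 & a$ic_times < 38]
  bb <- b$ic_times[b$ic_times > 4 & b$ic_times < 39]
  expect_equal(bb, aa + 1, tolerance = 1e-9)
})

test_that("shank event times are invariant to positive amplitude scaling", {
  fix <- clean_ya_subject()
  x <- fix$subject$shank_left$gyro[, 3]
  a <- detect_events_shank(x, 100, side = "L")
  b <- detect_events_shank(x * 2.3, 100, side = "L")
  expect_identical(a$ic_times, b$ic_times)
  expect_identical(a$fc_times, b$fc_times)
})

test_that("moderate gyro noise still allows near-complete recovery", {
  sc <- make_gait_script("YA", steady_walk(35), seed = 31)
  rec <- synthesize_shank_gyro(sc, "L", fs = 100, noise_sd = 5,
                               drift_rate = 0.1, seed = 2)
  es <- detect_events_shank(rec$gyro[, 3], 100, side = "L")
  mi <- match_events(es$ic_times, sc$ic$L, tol = 0.03)
  expect_gte(mi$match_rate, 0.95)
})
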