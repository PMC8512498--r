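test_that("a degenerate preset yields perfectly regular stride and step times", {
  co <- cohort_preset("YA", stride_sd = 0, stride_mean_between_sd = 0,
                      stride_sd_between_sd = 0, step_asymmetry_offset = 0,
                      step_asymmetry_between_sd = 0,
                      stance_fraction_between_sd = 0,
                      stance_fraction_cycle_sd = 0)
  sc <- make_gait_script(co, steady_walk(30), seed = 1)
  strides <- diff(sc$ic$L)
  expect_equal(strides, rep(1.096, length(strides)), tolerance = 1e-12)
  steps <- diff(sort(c(sc$ic$L, sc$ic$R)))
  expect_equal(steps, rep(1.096 / 2, length(steps)), tolerance = 1e-12)
})

test_that("generated stride times match the preset statistics", {
  # calibration of the stride-time mean: the 2-SE z-score of each seeded
  # 60 s walk should behave like a standard normal draw
  co <- cohort_preset("YA", stride_mean_between_sd = 0, stride_sd_between_sd = 0)
  zs <- vapply(1:12, function(seed) {
    sc <- make_gait_script(co, steady_walk(60), seed = seed)
    strides <- diff(sc$ic$L)   # one side: non-overlapping, independent strides
    (mean(strides) - 1.096) / (sd(strides) / sqrt(length(strides)))
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.8)
  expect_lt(abs(mean(zs)) / (1 / sqrt(12)), 3)   # no systematic bias

  # Monte-Carlo SD check at n = 5000 strides
  co2 <- cohort_preset("YA", stride_sd = 0.04, stride_mean_between_sd = 0,
                       stride_sd_between_sd = 0)
  sc2 <- make_gait_script(co2, steady_walk(5500), seed = 12)
  strides2 <- c(diff(sc2$ic$L), diff(sc2$ic$R))
  expect_gt(length(strides2), 5000)
  expect_gt(sd(strides2), 0.038)
  expect_lt(sd(strides2), 0.042)
})

test_that("scripts respect event ordering and stance-fraction invariants", {
  for (seed in 1:12) {
    for (env in c("treadmill", "indoor", "outdoor")) {
      co <- sample(c("YA", "OA", "PD"), 1)
      expect_no_error(validate_gait_script(make_gait_script(co, env, seed = seed)))
    }
  }
})

test_that("a seed is mandatory and fully determines scripts and waveforms", {
  expect_error(make_gait_script("YA", "indoor"), "seed")
  a <- make_gait_script("PD", "indoor", seed = 7)
  b <- make_gait_script("PD", "indoor", seed = 7)
  expect_identical(a$ic, b$ic)
  expect_identical(a$fc, b$fc)
  wa <- synthesize_shank_gyro(a, "L", fs = 100, noise_sd = 5, seed = 3)
  wb <- synthesize_shank_gyro(b, "L", fs = 100, noise_sd = 5, seed = 3)
  expect_identical(wa$gyro, wb$gyro)
})

test_that("the lumbar vertical channel keeps its gravity baseline", {
  sc <- make_gait_script("YA", steady_walk(20), seed = 5)
  rec <- synthesize_lumbar_accel(sc, fs = 100, noise_sd = 0, seed = 1,
                                 tilt_deg = c(0, 0))
  expect_lt(abs(mean(rec$accel[, 3]) - 9.81), 1e-6)
})

test_that("a tilted recording is recovered exactly by tilt correction", {
  sc <- make_gait_script("YA", steady_walk(20), seed = 5)
  flat <- synthesize_lumbar_accel(sc, fs = 100, noise_sd = 0, seed = 1,
                                  tilt_deg = c(0, 0),
                                  morphology = list(hor_noise_sd = 0))
  tilted <- synthesize_lumbar_accel(sc, fs = 100, noise_sd = 0, seed = 1,
                                    tilt_deg = c(10, 0),
                                    morphology = list(hor_noise_sd = 0))
  tc <- tilt_correct_to_vertical(tilted)
  amp <- diff(range(flat$accel[, 3]))
  expect_lt(sqrt(mean((tc$vertical - flat$accel[, 3])^2)), 1e-6 * amp)
})

test_that("shank waveform maxima sit at the scripted mid-swing anchors", {
  sc <- make_gait_script("YA", steady_walk(20), seed = 8)
  rec <- synthesize_shank_gyro(sc, "L", fs = 100, noise_sd = 0,
                               drift_rate = 0, seed = 1)
  x <- rec$gyro[, 3]
  tms <- imugait:::midswing_times(sc, "L")
  for (tm in tms[2:(length(tms) - 1)]) {
    idx <- round(tm * 100) + 1 + (-20:20)
    expect_lte(abs(which.max(x[idx]) - 21), 1)
  }
})

test_that("shank synthesis is linear in the mid-swing amplitude", {
  co1 <- cohort_preset("YA", ic_notch_depth = 0, fc_notch_depth = 0,
                       midswing_amplitude = 200)
  co2 <- cohort_preset("YA", ic_notch_depth = 0, fc_notch_depth = 0,
                       midswing_amplitude = 400)
  s1 <- make_gait_script(co1, steady_walk(15), seed = 4)
  s2 <- make_gait_script(co2, steady_walk(15), seed = 4)
  w1 <- synthesize_shank_gyro(s1, "L", fs = 100, noise_sd = 0, drift_rate = 0, seed = 1)
  w2 <- synthesize_shank_gyro(s2, "L", fs = 100, noise_sd = 0, drift_rate = 0, seed = 1)
  expect_equal(2 * w1$gyro[, 3], w2$gyro[, 3], tolerance = 1e-10)
})

test_that("gyroscope drift is produced as specified and removed by denoising", {
  sc <- make_gait_script("YA", steady_walk(118), seed = 6)
  rec <- synthesize_shank_gyro(sc, "L", fs = 100, noise_sd = 0,
                               drift_rate = 0.5, seed = 1)
  x <- rec$gyro[, 3]
  n <- length(x)
  expect_gt(n / 100, 119)
  # raw endpoint offset ~ drift_rate * t
  expect_equal(0.5 * (n - 1) / 100, x[n] - x[1], tolerance = 3)
  inter <- wavelet_denoise_shank(x, 100)
  expect_lt(abs(mean(inter$baseline)), 2)
})

test_that("synthesizers reject empty or side-less scripts", {
  sc <- make_gait_script("YA", steady_walk(20), seed = 5)
  sc$ic$L <- numeric(0)
  expect_error(synthesize_shank_gyro(sc, "L", seed = 1), "absent")
  sc$ic$R <- numeric(0); sc$fc <- list(L = numeric(0), R = numeric(0))
  expect_error(synthesize_lumbar_accel(sc, seed = 1), "no events")
})
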