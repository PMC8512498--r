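test_that("tilt correction is the identity for an untilted recording and preserves norms", {
  sc <- make_gait_script("YA", steady_walk(10), seed = 2)
  clean <- synthesize_lumbar_accel(sc, fs = 100, noise_sd = 0, seed = 1,
                                   tilt_deg = c(0, 0),
                                   morphology = list(hor_noise_sd = 0))
  tc0 <- tilt_correct_to_vertical(clean)
  expect_equal(tc0$vertical, unname(clean$accel[, 3]), tolerance = 1e-9)
  noisy <- synthesize_lumbar_accel(sc, fs = 100, noise_sd = 0.1, seed = 1,
                                   tilt_deg = c(7, 4))
  tc <- tilt_correct_to_vertical(noisy)
  norms_in <- sqrt(rowSums(noisy$accel^2))
  norms_out <- sqrt(rowSums(cbind(tc$horizontal, tc$vertical)^2))
  expect_lt(max(abs(norms_out / norms_in - 1)), 1e-9)
})

test_that("tilt correction rejects non-quasi-static or wrongly scaled input", {
  rec <- imu_recording(fs = 100, accel = matrix(rep(c(0, 0, 1), each = 300), ncol = 3))
  expect_error(tilt_correct_to_vertical(rec), "quasi-static")
  short <- imu_recording(fs = 100, accel = matrix(rep(c(0, 0, 9.81), each = 100), ncol = 3))
  expect_error(tilt_correct_to_vertical(short), "2 s")
})

test_that("a constant signal yields an empty event series with a warning", {
  cfg <- lumbar_detector_config()
  expect_warning(es <- detect_events_lumbar(rep(9.81, 500), 100, cfg), "empty")
  expect_length(es$ic_times, 0)
  expect_length(es$fc_times, 0)
})

test_that("a pure 1 Hz sinusoid yields one IC and one FC per second", {
  fs <- 100
  t <- (0:1199) / fs
  x <- 2 * sin(2 * pi * t)
  es <- detect_events_lumbar(x, fs)
  # interior events at exactly 1 s spacing (boundary guard trims the ends)
  expect_gte(length(es$ic_times), 9)
  expect_gte(length(es$fc_times), 9)
  expect_equal(diff(es$ic_times), rep(1, length(es$ic_times) - 1),
               tolerance = 0.011)
  expect_equal(diff(es$fc_times), rep(1, length(es$fc_times) - 1),
               tolerance = 0.011)
  # at most one FC between consecutive ICs
  counts <- vapply(seq_len(length(es$ic_times) - 1), function(k) {
    sum(es$fc_times > es$ic_times[k] & es$fc_times < es$ic_times[k + 1])
  }, integer(1))
  expect_true(all(counts <= 1))
})

test_that("event times are invariant to positive amplitude scaling", {
  fix <- clean_ya_subject()
  v <- fix$subject$lumbar$accel[, 3]
  a <- detect_events_lumbar(v, 100)
  b <- detect_events_lumbar(v * 3.7, 100)
  expect_identical(a$ic_times, b$ic_times)
  expect_identical(a$fc_times, b$fc_times)
})

test_that("event times are equivariant to a time shift", {
  fix <- clean_ya_subject()
  v <- fix$subject$lumbar$accel[, 3]
  k <- 150  # 1.5 s
  vs <- c(rep(v[1], k), v[1:(length(v) - k)])
  a <- detect_events_lumbar(v, 100)
  b <- detect_events_lumbar(vs, 100)
  aa <- a$ic_times[a$ic_times > 3 & a$ic_times < 38]
  bb <- b$ic_times[b$ic_times > 3 + 1.5 & b$ic_times < 38 + 1.5]
  expect_equal(bb, aa + 1.5, tolerance = 1e-9)
})

test_that("noise-free synthetic events are recovered accurately", {
  fix <- clean_ya_subject()
  sc <- fix$subject$script
  v <- fix$subject$lumbar$accel[, 3]
  es <- detect_events_lumbar(v, 100)
  mi <- match_events(es$ic_times, sort(c(sc$ic$L, sc$ic$R)), tol = 0.05)
  expect_gte(mi$match_rate, 0.95)
  # this fixture is a deliberately slow, long-double-support walker; the
  # fixed-scale pipeline's timing error grows with double support
  expect_lt(mi$median_abs_error, 0.035)
})

test_that("a cutoff at or above Nyquist is a configuration error", {
  expect_error(detect_events_lumbar(rnorm(500), 30, lumbar_detector_config(lowpass_cutoff = 20)),
               "Nyquist")
})

test_that("the same walk sampled at 60 and 128 Hz yields matching events", {
  sc <- make_gait_script("YA", steady_walk(30), seed = 5)
  mk <- function(fs) synthesize_lumbar_accel(sc, fs = fs, noise_sd = 0, seed = 1,
                                             tilt_deg = c(0, 0),
                                             morphology = list(hor_noise_sd = 0))
  e60 <- detect_events_lumbar(mk(60)$accel[, 3], 60)
  e128 <- detect_events_lumbar(mk(128)$accel[, 3], 128)
  m <- match_events(e60$ic_times, e128$ic_times, tol = 1 / 60)
  expect_gte(m$match_rate, 0.95)
})
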