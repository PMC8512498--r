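#!/usr/bin/env Rscript
# Step 2 -- run both event-detection algorithms on the example subjects and
# score them against the ground-truth schedules.
#
# Reads the per-cell example recordings written by 01_simulate.R, detects
# initial/final contacts with the lower-back (A1) and shank (A2) pipelines,
# writes the detected event tables, and reports match rates and timing
# errors against the simulator's schedules.

library(imugait)

in_root <- "results/simulated"
out_root <- "results/events"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

cells <- list.dirs(in_root, recursive = FALSE)
score_rows <- list()
for (dir in cells) {
  cell <- basename(dir)
  cm_acc <- list(accel_x = "accel_x", accel_y = "accel_y", accel_z = "accel_z",
                 time = "time_s")
  cm_gyr <- list(gyro_x = "gyro_x", gyro_y = "gyro_y", gyro_z = "gyro_z",
                 time = "time_s")
  lum <- read_imu_csv(file.path(dir, "lumbar_L5.csv"), cm_acc, placement = "L5")
  shl <- read_imu_csv(file.path(dir, "shank_left.csv"), cm_gyr,
                      placement = "shank_left")
  shr <- read_imu_csv(file.path(dir, "shank_right.csv"), cm_gyr,
                      placement = "shank_right")
  res <- suppressWarnings(analyze_subject(
    list(lumbar = lum, shank_left = shl, shank_right = shr)))

  ev <- do.call(rbind, lapply(c("L", "R"), function(s) rbind(
    data.frame(subject_id = cell, placement = "L5", side = s,
               event_type = "IC", time_s = res$events_a1[[s]]$ic_times),
    data.frame(subject_id = cell, placement = "L5", side = s,
               event_type = "FC", time_s = res$events_a1[[s]]$fc_times),
    data.frame(subject_id = cell, placement = res$events_a2[[s]]$placement,
               side = s, event_type = "IC", time_s = res$events_a2[[s]]$ic_times),
    data.frame(subject_id = cell, placement = res$events_a2[[s]]$placement,
               side = s, event_type = "FC", time_s = res$events_a2[[s]]$fc_times))))
  write_event_csv(ev, file.path(out_root, paste0(cell, "_events.csv")))

  truth <- read_event_csv(file.path(dir, "ground_truth_events.csv"))
  for (alg in c("a1", "a2")) {
    evs <- res[[paste0("events_", alg)]]
    for (type in c("IC", "FC")) {
      det <- sort(c(if (type == "IC") c(evs$L$ic_times, evs$R$ic_times)
                    else c(evs$L$fc_times, evs$R$fc_times)))
      tru <- sort(truth$time_s[truth$event_type == type])
      m <- match_events(det, tru, tol = 0.05)
      score_rows[[length(score_rows) + 1]] <- data.frame(
        cell = cell, algorithm = toupper(alg), event = type,
        n_true = m$n_true, match_rate = m$match_rate,
        median_abs_error_ms = 1000 * m$median_abs_error)
    }
  }
}
scores <- do.call(rbind, score_rows)
write.csv(scores, file.path(out_root, "detection_scores.csv"), row.names = FALSE)

cat("Event detection scored against ground truth (tolerance 50 ms):\n")
print(scores, row.names = FALSE, digits = 3)
cat("\nNote the treadmill cell: the fixed-scale lower-back pipeline loses",
    "final contacts at the fastest belt speeds, and bout-initial strides",
    "lack a mid-swing anchor for the shank pipeline -- both are properties",
    "of the algorithms, not of the simulator.\n")
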