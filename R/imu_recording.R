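#' Standard gravity used for unit conversion (m/s^2)
#'
#' Canonical internal units are m/s^2 for acceleration and deg/s for
#' angular velocity; 1 g is taken as exactly 9.81 m/s^2.
#' @export
STANDARD_GRAVITY <- 9.81

#' Construct an IMU recording
#'
#' Container for a uniformly sampled tri-axial accelerometer/gyroscope
#' stream from one sensor placement.  Timestamps are seconds from the
#' start of the recording (`t[1] = 0`); acceleration is in m/s^2 and
#' angular velocity in deg/s.
#'
#' @param fs Sampling rate, Hz (> 0).
#' @param accel `n x 3` matrix of acceleration (m/s^2) or `NULL`.
#' @param gyro `n x 3` matrix of angular velocity (deg/s) or `NULL`.
#' @param placement One of `"L5"`, `"shank_right"`, `"shank_left"`.
#' @param t Optional timestamp vector; defaults to a uniform grid at `fs`.
#' @param axis_convention Named list declaring which column index holds the
#'   device-vertical acceleration axis (`vertical_accel`) and the
#'   sagittal-plane gyroscope axis (`sagittal_gyro`), with sign multipliers
#'   `vertical_sign` / `sagittal_sign`.
#' @param subject_id Opaque subject identifier.
#' @param metadata Free-form key/value list (cohort, environment, notes).
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(fs, accel = NULL, gyro = NULL,
                          placement = c("L5", "shank_right", "shank_left"),
                          t = NULL,
                          axis_convention = list(vertical_accel = 3L,
                                                 vertical_sign = 1,
                                                 sagittal_gyro = 3L,
                                                 sagittal_sign = 1),
                          subject_id = "", metadata = list()) {
  placement <- match.arg(placement)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  n <- if (!is.null(accel)) nrow(accel) else if (!is.null(gyro)) nrow(gyro) else 0L
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  rec <- structure(list(placement = placement, fs = fs, t = t,
                        accel = accel, gyro = gyro,
                        axis_convention = axis_convention,
                        subject_id = subject_id, metadata = metadata),
                   class = "imu_recording")
  validate_imu_recording(rec)
  rec
}

#' Validate an IMU recording's invariants
#'
#' Checks positive sampling rate, strictly increasing timestamps uniform to
#' within 1e-6 s, equal channel lengths, and finite samples.
#'
#' @param rec An [imu_recording()].
#' @return `rec`, invisibly; errors otherwise.
#' @export
validate_imu_recording <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$fs <= 0) stop("fs must be > 0")
  n <- length(rec$t)
  for (ch in c("accel", "gyro")) {
    m <- rec[[ch]]
    if (is.null(m)) next
    if (!is.matrix(m) || nrow(m) != n) stop(ch, " must be an n x 3 matrix matching t")
    if (!all(is.finite(m))) stop(ch, " contains non-finite samples")
  }
  if (n >= 2) {
    dt <- diff(rec$t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / rec$fs)) > 1e-6) {
      stop("timestamps deviate from a uniform 1/fs grid by more than 1e-6 s")
    }
  }
  invisible(rec)
}

#' Number of samples in a recording
#' @param rec An [imu_recording()].
#' @export
n_samples <- function(rec) length(rec$t)

#' Read an IMU recording from a delimited text file
#'
#' Parses a per-sensor CSV/TSV export, converts units to the canonical
#' m/s^2 and deg/s, and returns an [imu_recording()].  Either sensor block
#' (accelerometer or gyroscope) may be absent from `column_map`; missing
#' blocks are flagged in the recording metadata.
#'
#' @param path File path.
#' @param column_map Named list mapping channel roles to column names, e.g.
#'   `list(accel_x = "ax", accel_y = "ay", accel_z = "az",
#'   gyro_x = "gx", gyro_y = "gy", gyro_z = "gz", time = "t")`.
#'   The `time` role is optional; without it a uniform grid at `fs` is used.
#' @param fs Sampling rate in Hz (required when no `time` column is mapped).
#' @param accel_unit `"m_s2"` or `"g"`.
#' @param gyro_unit `"deg_s"` or `"rad_s"`.
#' @param placement,subject_id,axis_convention,metadata Passed through to
#'   [imu_recording()].
#' @param sep Field separator (default `,`).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, column_map, fs = NULL,
                         accel_unit = c("m_s2", "g"),
                         gyro_unit = c("deg_s", "rad_s"),
                         placement = "L5", subject_id = "",
                         axis_convention = NULL, metadata = list(),
                         sep = ",") {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  accel_roles <- paste0("accel_", c("x", "y", "z"))
  gyro_roles <- paste0("gyro_", c("x", "y", "z"))
  get_block <- function(roles) {
    present <- roles[roles %in% names(column_map)]
    if (!length(present)) return(NULL)
    if (length(present) < 3) {
      stop("column_map must name all three channels of a block; missing: ",
           paste(setdiff(roles, present), collapse = ", "))
    }
    cols <- unlist(column_map[roles])
    absent <- cols[!cols %in% names(df)]
    if (length(absent)) {
      role <- roles[match(absent[1], cols)]
      stop("column '", absent[1], "' (role ", role, ") not found in header of ", path)
    }
    m <- vapply(cols, function(cn) suppressWarnings(as.numeric(df[[cn]])),
                numeric(nrow(df)))
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df))
    bad <- which(apply(!is.finite(m), 1, any))
    if (length(bad)) {
      stop("malformed row ", bad[1] + 1L, " in ", path,
           " (non-numeric or missing value)")
    }
    colnames(m) <- c("x", "y", "z")
    m
  }
  accel <- get_block(accel_roles)
  gyro <- get_block(gyro_roles)
  if (is.null(accel) && is.null(gyro)) stop("column_map names neither an accel nor a gyro block")
  if (!is.null(accel) && accel_unit == "g") accel <- accel * STANDARD_GRAVITY
  if (!is.null(gyro) && gyro_unit == "rad_s") gyro <- gyro * 180 / pi
  n <- if (!is.null(accel)) nrow(accel) else nrow(gyro)
  t <- NULL
  if ("time" %in% names(column_map)) {
    tc <- column_map$time
    if (!tc %in% names(df)) stop("column '", tc, "' (role time) not found in header of ", path)
    t_raw <- as.numeric(df[[tc]])
    if (anyNA(t_raw)) stop("malformed row ", which(is.na(t_raw))[1] + 1L, " in ", path,
                           " (non-numeric time)")
    dt <- diff(t_raw)
    if (any(dt <= 0)) stop("timing error: timestamps in ", path, " are not strictly increasing")
    fs_est <- 1 / stats::median(dt)
    if (is.null(fs)) fs <- fs_est
    if (max(abs(dt - 1 / fs)) > 1e-4) {
      stop("timing error: timestamps in ", path,
           " deviate from a uniform 1/fs grid beyond tolerance")
    }
    t <- (t_raw - t_raw[1])
    # snap to the exact uniform grid (declared clock)
    t <- (seq_len(n) - 1) / fs
  } else if (is.null(fs)) {
    stop("fs must be given when column_map has no 'time' role")
  }
  metadata$missing_accel <- is.null(accel)
  metadata$missing_gyro <- is.null(gyro)
  args <- list(fs = fs, accel = accel, gyro = gyro, placement = placement,
               t = t, subject_id = subject_id, metadata = metadata)
  if (!is.null(axis_convention)) args$axis_convention <- axis_convention
  do.call(imu_recording, args)
}

#' Write an IMU recording to CSV
#'
#' Writes time plus present channel blocks with full double precision so a
#' write/read round trip is lossless to float precision.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  validate_imu_recording(rec)
  df <- data.frame(time_s = rec$t)
  if (!is.null(rec$accel)) {
    df$accel_x <- rec$accel[, 1]; df$accel_y <- rec$accel[, 2]; df$accel_z <- rec$accel[, 3]
  }
  if (!is.null(rec$gyro)) {
    df$gyro_x <- rec$gyro[, 1]; df$gyro_y <- rec$gyro[, 2]; df$gyro_z <- rec$gyro[, 3]
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform grid at a new rate
#'
#' Channels are linearly interpolated onto a uniform grid at `target_fs`
#' spanning the original time range.  No anti-alias filter is applied when
#' downsampling; the downstream detectors low-pass filter their inputs, and
#' this limitation is documented.
#'
#' @param rec An [imu_recording()].
#' @param target_fs Target sampling rate, Hz.
#' @return A resampled [imu_recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  validate_imu_recording(rec)
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (n_samples(rec) < 2) stop("recording too short to resample (< 2 samples)")
  t_new <- seq(rec$t[1], rec$t[length(rec$t)], by = 1 / target_fs)
  interp_block <- function(m) {
    if (is.null(m)) return(NULL)
    out <- vapply(seq_len(ncol(m)),
                  function(j) stats::approx(rec$t, m[, j], xout = t_new)$y,
                  numeric(length(t_new)))
    colnames(out) <- colnames(m)
    out
  }
  imu_recording(fs = target_fs, accel = interp_block(rec$accel),
                gyro = interp_block(rec$gyro), placement = rec$placement,
                t = t_new - t_new[1], axis_convention = rec$axis_convention,
                subject_id = rec$subject_id, metadata = rec$metadata)
}

#' Write a gait event table to CSV
#'
#' @param events Data frame with columns `subject_id`, `placement`, `side`,
#'   `event_type` (`"IC"`/`"FC"`) and `time_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(events, path) {
  need <- c("subject_id", "placement", "side", "event_type", "time_s")
  if (!all(need %in% names(events))) {
    stop("event table must have columns: ", paste(need, collapse = ", "))
  }
  utils::write.csv(events[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gait event table written by [write_event_csv()]
#' @param path Input path.
#' @return Data frame of events ordered by time within subject/side.
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "placement", "side", "event_type", "time_s")
  if (!all(need %in% names(df))) {
    stop("not an event table (expected columns ", paste(need, collapse = ", "), ")")
  }
  df[order(df$subject_id, df$side, df$time_s), need]
}
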