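IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct an IMU recording
#'
#' An `imu_recording` is a tibble of timestamped six-axis samples — triaxial
#' accelerometer (`ax`, `ay`, `az`, units g) and triaxial gyroscope
#' (`gx`, `gy`, `gz`, units degrees/second) — with the sampling rate, sensor
#' ranges and subject id carried as attributes.  Axis convention for a watch
#' on the left wrist: y points toward the hand, x up, z out of the watch face.
#' Values outside the sensor range are clipped at ingest and counted rather
#' than rejected; posture transitions are gentle movements, so saturation is
#' rare and a clipped sample is still informative.
#'
#' @param samples Data frame with column `t` (seconds, strictly increasing)
#'   and channel columns `ax, ay, az, gx, gy, gz`; an optional `label` column
#'   is preserved verbatim.
#' @param sampling_rate_hz Nominal sampling rate in Hz.  The median timestamp
#'   spacing must agree with `1/sampling_rate_hz` within 1%.
#' @param subject_id Opaque subject identifier.
#' @param accel_range_g,gyro_range_dps Sensor full-scale ranges; samples are
#'   clipped to `[-range, range]`.
#' @return A tibble of class `imu_recording` with attributes
#'   `sampling_rate_hz`, `subject_id`, `accel_range_g`, `gyro_range_dps` and
#'   `n_clipped` (number of clipped values).
#' @export
#' @examples
#' t <- seq(0, 0.99, by = 0.01)
#' rec <- imu_recording(
#'   data.frame(t = t, ax = 0, ay = 1, az = 0, gx = 0, gy = 0, gz = 0),
#'   sampling_rate_hz = 100, subject_id = "s1"
#' )
#' sampling_rate(rec)
imu_recording <- function(samples, sampling_rate_hz, subject_id = "unknown",
                          accel_range_g = 2, gyro_range_dps = 300) {
  stopifnot(is.data.frame(samples))
  missing <- setdiff(c("t", IMU_CHANNELS), names(samples))
  if (length(missing) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "wristpose_schema_error"
    )
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be a positive number",
          class = "wristpose_parameter_error")
  }
  keep <- intersect(c("t", IMU_CHANNELS, "label"), names(samples))
  out <- tibble::as_tibble(samples[keep])

  n <- nrow(out)
  if (n >= 2) {
    dt <- diff(out$t)
    if (any(dt <= 0)) {
      abort("timestamps must be strictly increasing",
            class = "wristpose_format_error")
    }
    med <- median(dt)
    if (abs(med - 1 / sampling_rate_hz) > 0.01 / sampling_rate_hz) {
      abort(sprintf(
        "median timestamp spacing %.6g s is inconsistent with %g Hz",
        med, sampling_rate_hz
      ), class = "wristpose_format_error")
    }
  }

  n_clipped <- 0L
  for (ch in c("ax", "ay", "az")) {
    v <- out[[ch]]
    bad <- abs(v) > accel_range_g
    n_clipped <- n_clipped + sum(bad)
    out[[ch]] <- pmin(pmax(v, -accel_range_g), accel_range_g)
  }
  for (ch in c("gx", "gy", "gz")) {
    v <- out[[ch]]
    bad <- abs(v) > gyro_range_dps
    n_clipped <- n_clipped + sum(bad)
    out[[ch]] <- pmin(pmax(v, -gyro_range_dps), gyro_range_dps)
  }

  structure(
    out,
    class = c("imu_recording", class(out)),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    subject_id = as.character(subject_id),
    accel_range_g = as.numeric(accel_range_g),
    gyro_range_dps = as.numeric(gyro_range_dps),
    n_clipped = as.integer(n_clipped)
  )
}

#' @rdname imu_recording
#' @param rec An `imu_recording`.
#' @export
sampling_rate <- function(rec) attr(rec, "sampling_rate_hz")

#' @rdname imu_recording
#' @export
n_clipped <- function(rec) attr(rec, "n_clipped")

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> subject %s: %d samples at %g Hz (%d clipped)\n",
    attr(x, "subject_id"), nrow(x), attr(x, "sampling_rate_hz"),
    attr(x, "n_clipped")
  ))
  NextMethod()
}

#' Read an IMU recording from CSV
#'
#' Expects a comma-separated file with a header row and columns
#' `t,ax,ay,az,gx,gy,gz` (an optional trailing `label` column is kept).
#' Units: seconds, g, degrees/second; `.` decimal separator.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate_hz Sampling rate of the stream; if `NULL`, inferred
#'   from the median timestamp spacing.
#' @param schema Optional named character vector mapping the canonical column
#'   names to the names used in the file, e.g. `c(t = "time_s")`.
#' @inheritParams imu_recording
#' @return An [imu_recording].
#' @export
read_imu_csv <- function(path, sampling_rate_hz = NULL, schema = NULL,
                         subject_id = "unknown",
                         accel_range_g = 2, gyro_range_dps = 300) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      idx <- match(schema[[canonical]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canonical
    }
  }
  missing <- setdiff(c("t", IMU_CHANNELS), names(df))
  if (length(missing) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "wristpose_schema_error"
    )
  }
  if (is.null(sampling_rate_hz)) {
    if (nrow(df) < 2) {
      abort("cannot infer sampling rate from fewer than 2 samples",
            class = "wristpose_format_error")
    }
    sampling_rate_hz <- 1 / median(diff(df$t))
  }
  imu_recording(df, sampling_rate_hz, subject_id = subject_id,
                accel_range_g = accel_range_g, gyro_range_dps = gyro_range_dps)
}

#' Write an IMU recording to CSV
#'
#' Channel values are written with enough digits that a read/write round trip
#' reproduces them to at least six decimal places.  An annotation `label`
#' column, if present, is preserved verbatim.
#'
#' @param rec An [imu_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- tibble::as_tibble(unclass(rec)[intersect(
    c("t", IMU_CHANNELS, "label"), names(rec)
  )])
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Reduce the sampling rate of a recording
#'
#' Keeps every k-th sample (starting from the first) of all channels, where
#' `k = sampling_rate / target_rate_hz` must be an integer.  This mimics
#' polling the sensor at a reduced rate on the device; the 1-s moving-average
#' filter applied before windowing acts as the anti-alias stage.  Timestamps
#' are regenerated as `t[1] + i/target_rate_hz` to avoid accumulated drift.
#'
#' @param rec An [imu_recording].
#' @param target_rate_hz Target rate in Hz; must divide the current rate.
#' @return An [imu_recording] at the target rate with `ceiling(n/k)` samples.
#' @export
#' @examples
#' t <- seq(0, 4.99, by = 0.01)
#' rec <- imu_recording(
#'   data.frame(t = t, ax = sin(t), ay = 1, az = 0, gx = 0, gy = 0, gz = 0),
#'   sampling_rate_hz = 100
#' )
#' nrow(decimate_recording(rec, 10))  # 50
decimate_recording <- function(rec, target_rate_hz) {
  stopifnot(inherits(rec, "imu_recording"))
  rate <- sampling_rate(rec)
  k <- rate / target_rate_hz
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort(sprintf(
      "target rate %g Hz does not evenly divide the sampling rate %g Hz",
      target_rate_hz, rate
    ), class = "wristpose_parameter_error")
  }
  k <- as.integer(round(k))
  idx <- seq(1, nrow(rec), by = k)
  out <- tibble::as_tibble(unclass(rec)[intersect(
    c("t", IMU_CHANNELS, "label"), names(rec)
  )])[idx, ]
  t0 <- if (nrow(out) > 0) out$t[1] else 0
  out$t <- t0 + (seq_len(nrow(out)) - 1) / target_rate_hz
  imu_recording(out, target_rate_hz,
                subject_id = attr(rec, "subject_id"),
                accel_range_g = attr(rec, "accel_range_g"),
                gyro_range_dps = attr(rec, "gyro_range_dps"))
}

#' Read a movement-annotation sidecar file
#'
#' Annotations mark the start and end of each movement in a recording, with
#' one row per movement: `start_s,end_s,label`.
#'
#' @param path Path to the annotation CSV.
#' @return Tibble with columns `start_s`, `end_s`, `label`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("start_s", "end_s", "label"), names(df))
  if (length(missing) > 0) {
    abort(
      paste0("missing annotation column(s): ", paste(missing, collapse = ", ")),
      class = "wristpose_schema_error"
    )
  }
  validate_annotations(df)
  tibble::as_tibble(df)
}

validate_annotations <- function(annotations) {
  if (any(annotations$end_s <= annotations$start_s)) {
    abort("annotation end must be after its start",
          class = "wristpose_annotation_error")
  }
  bad <- setdiff(unique(annotations$label), ALL_LABELS)
  if (length(bad) > 0) {
    abort(paste0("unknown movement label(s): ", paste(bad, collapse = ", ")),
          class = "wristpose_annotation_error")
  }
  invisible(annotations)
}
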