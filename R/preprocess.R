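#' Causal moving-average filter
#'
#' Smooths a channel with a trailing (causal) moving average: each output
#' sample is the mean of the current sample and the `w - 1` preceding ones,
#' with a shorter window at the start of the series.  A causal filter is used
#' rather than a centred one so the same preprocessing could run in a
#' real-time recogniser.  The default window is 1 s, i.e. 100 points at
#' 100 Hz, 10 points at 10 Hz.
#'
#' @param x Numeric channel series.
#' @param window_s Filter window length in seconds (default 1).
#' @param rate_hz Sampling rate of `x` in Hz.
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' moving_average_filter(c(0, 10), window_s = 2, rate_hz = 1)  # c(0, 5)
moving_average_filter <- function(x, window_s = 1, rate_hz) {
  w <- round(window_s * rate_hz)
  if (w < 1) {
    abort("filter window must span at least one sample",
          class = "wristpose_parameter_error")
  }
  n <- length(x)
  if (n == 0) return(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)                     # exclusive lower index into cs
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Euclidean magnitude of a sensor triad
#'
#' Per-sample magnitude `sqrt(x^2 + y^2 + z^2)`.  For the accelerometer this
#' is the acceleration magnitude in g, the seventh signal channel of the
#' feature bank; at rest it sits near 1 g regardless of wrist orientation.
#'
#' @param x,y,z Equal-length numeric series (the three axes).
#' @return Numeric series of magnitudes.
#' @export
triad_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x)) {
    abort("triad axes must have equal length", class = "wristpose_shape_error")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Apply the moving-average filter to all channels of a recording
#'
#' Filtering is done on the continuous stream, before any windows are cut,
#' so window edges see the same smoothed signal as their neighbourhood.
#'
#' @param rec An [imu_recording].
#' @param window_s Filter window in seconds (default 1).
#' @return A filtered [imu_recording].
#' @export
filter_recording <- function(rec, window_s = 1) {
  stopifnot(inherits(rec, "imu_recording"))
  rate <- sampling_rate(rec)
  out <- rec
  for (ch in IMU_CHANNELS) {
    out[[ch]] <- moving_average_filter(rec[[ch]], window_s, rate)
  }
  out
}

#' Cut annotated movement windows from a recording
#'
#' Each annotation marks the start and end of one movement; a fixed-duration
#' window (default 5 s, the mean movement length across the collection
#' protocol) is cut centred on the annotation midpoint.  Windows that reach
#' past the edge of the recording are zero-padded and flagged.  The
#' moving-average filter is applied to the whole stream first (see
#' [filter_recording]); pass `filter_window_s = NULL` to skip filtering.
#'
#' @param rec An [imu_recording].
#' @param annotations Data frame with columns `start_s`, `end_s`, `label`
#'   (see [read_annotations]).
#' @param duration_s Window duration in seconds; the window holds
#'   `round(duration_s * rate)` samples (500 at 100 Hz, 50 at 10 Hz).
#' @param filter_window_s Moving-average window in seconds applied to the
#'   stream before cutting, or `NULL` for no filtering.
#' @return A window collection: tibble with one row per annotation and
#'   columns `subject_id`, `label`, `sampling_rate_hz`, `padded` (logical,
#'   TRUE when zero-padding was needed) and `data` (list column of per-window
#'   sample tibbles with the six channels).
#' @export
cut_windows <- function(rec, annotations, duration_s = 5,
                        filter_window_s = 1) {
  stopifnot(inherits(rec, "imu_recording"))
  validate_annotations(annotations)
  rate <- sampling_rate(rec)
  if (!is.null(filter_window_s)) {
    rec <- filter_recording(rec, filter_window_s)
  }
  n <- nrow(rec)
  len <- as.integer(round(duration_s * rate))
  t0 <- rec$t[1]

  rows <- purrr::pmap(
    list(annotations$start_s, annotations$end_s, annotations$label),
    function(start_s, end_s, label) {
      mid <- (start_s + end_s) / 2
      # first sample index of the window, 1-based
      first <- as.integer(round((mid - t0) * rate)) - len %/% 2L + 1L
      idx <- first:(first + len - 1L)
      inside <- idx >= 1L & idx <= n
      dat <- matrix(0, nrow = len, ncol = length(IMU_CHANNELS),
                    dimnames = list(NULL, IMU_CHANNELS))
      for (ch in IMU_CHANNELS) {
        dat[inside, ch] <- rec[[ch]][idx[inside]]
      }
      list(
        label = label,
        padded = any(!inside),
        data = tibble::as_tibble(as.data.frame(dat))
      )
    }
  )

  tibble::tibble(
    subject_id = attr(rec, "subject_id"),
    label = purrr::map_chr(rows, "label"),
    sampling_rate_hz = rate,
    padded = purrr::map_lgl(rows, "padded"),
    data = purrr::map(rows, "data")
  )
}
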