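# Canonical feature and channel bookkeeping.  25 features per channel over
# the 7 channels ax, ay, az, gx, gy, gz and the acceleration magnitude give
# the fixed 175-entry vector.  Feature columns are named <feature>__<channel>.

FEATURE_NAMES <- c(
  "min", "max", "sum", "mean", "std", "kurtosis", "skewness", "energy",
  "variance", "median", "rms", "avg_difference", "iqr",
  "zero_crossing_rate", "mean_crossing_rate",
  "eigenvalues", "cagh", "avg_mean_intensity", "avg_rotation_angles",
  "dominant_frequency", "peak_difference", "peak_rms", "root_sum_squares",
  "first_peak", "second_peak"
)

CHANNEL_NAMES <- c("ax", "ay", "az", "gx", "gy", "gz", "amag")

#' Names of the 175 feature columns
#'
#' The canonical ordering of the feature bank: the 25 per-window features
#' crossed with the 7 signal channels (six axes plus acceleration
#' magnitude), named `<feature>__<channel>`.
#'
#' @return Character vector of length 175.
#' @export
feature_names <- function() {
  as.vector(t(outer(FEATURE_NAMES, CHANNEL_NAMES, paste, sep = "__")))
}

check_window_length <- function(x, min_n) {
  if (length(x) < min_n) {
    abort(sprintf("window too short: need at least %d samples", min_n),
          class = "wristpose_window_error")
  }
}

#' Time-domain summary statistics of a channel
#'
#' The order statistics and moments of a single channel over a movement
#' window.  Conventions are fixed so the features are reproducible:
#' `std`/`variance` use the n-1 denominator, `skewness` is m3/m2^1.5 and
#' `kurtosis` excess (Fisher) kurtosis m4/m2^2 - 3 with central moments
#' m_k, and `iqr` uses linear-interpolation quantiles.  A constant series
#' has undefined standardised moments; they fall back to 0.
#'
#' @param x Numeric channel series, length >= 2.
#' @return Named numeric vector: `min`, `max`, `sum`, `mean`, `std`,
#'   `kurtosis`, `skewness`, `variance`, `median`, `rms`, `iqr`.
#' @export
#' @examples
#' time_stats(1:5)[c("mean", "rms")]
time_stats <- function(x) {
  check_window_length(x, 2)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(
    min = min(x), max = max(x), sum = sum(x), mean = m, std = sd(x),
    kurtosis = kurt, skewness = skew, variance = var(x),
    median = median(x), rms = sqrt(mean(x^2)), iqr = q[2] - q[1]
  )
}

#' Average pairwise absolute difference
#'
#' Mean of `|x_i - x_j|` over all `n(n-1)/2` unordered pairs of samples in
#' the window — a dispersion measure that, unlike the standard deviation,
#' is linear in the signal scale.  Computed with the sorted prefix-sum
#' identity in O(n log n) rather than the O(n^2) double loop.
#'
#' @param x Numeric channel series, length >= 2.
#' @return Single numeric value.
#' @export
#' @examples
#' avg_pairwise_difference(c(0, 1, 2))  # 4/3
avg_pairwise_difference <- function(x) {
  check_window_length(x, 2)
  n <- length(x)
  s <- sort(x)
  # sum over pairs |xi - xj| = sum_i (2i - n - 1) * x_(i)
  total <- sum((2 * seq_len(n) - n - 1) * s)
  total / (n * (n - 1) / 2)
}

#' Zero- and mean-crossing rates
#'
#' `zero_crossing_rate` is the fraction of adjacent sample pairs with
#' strictly opposite signs (exact zeros never count as crossings);
#' `mean_crossing_rate` is the same rate after subtracting the window mean.
#'
#' @param x Numeric channel series, length >= 2.
#' @return Named numeric vector `zero_crossing_rate`, `mean_crossing_rate`.
#' @export
crossing_rates <- function(x) {
  check_window_length(x, 2)
  rate <- function(v) {
    s <- sign(v)
    sum(s[-length(s)] * s[-1] < 0) / (length(v) - 1)
  }
  c(zero_crossing_rate = rate(x), mean_crossing_rate = rate(x - mean(x)))
}

#' Frequency-domain features of a channel
#'
#' Works on the one-sided discrete-Fourier amplitude spectrum `|X_k|` for
#' `k = 1..floor(n/2)`.  The DC bin is excluded from every aggregate: the
#' gravity offset dominates wrist signals and would otherwise swamp the
#' spectral energy of the movement itself.
#'
#' Features: `energy` (sum of amplitudes), `root_sum_squares`
#' (`sqrt(sum |X_k|^2)`), `dominant_frequency` (frequency of the largest
#' bin, ties to the lowest), spectral peaks (local maxima strictly greater
#' than both neighbours, ranked by amplitude) giving `first_peak` and
#' `second_peak` amplitudes, `peak_difference` (absolute frequency gap in
#' Hz between the two largest peaks) and `peak_rms` (RMS of all peak
#' amplitudes).  Missing peaks resolve to 0.
#'
#' @param x Numeric channel series, length >= 4.
#' @param rate_hz Sampling rate in Hz.
#' @return Named numeric vector: `energy`, `dominant_frequency`,
#'   `peak_difference`, `peak_rms`, `root_sum_squares`, `first_peak`,
#'   `second_peak`.
#' @export
spectral_features <- function(x, rate_hz) {
  check_window_length(x, 4)
  n <- length(x)
  k_max <- n %/% 2
  amp <- Mod(fft(x))[2:(k_max + 1)]          # bins k = 1..floor(n/2)
  # floor numerically-zero bins (FFT residue of constant/DC-only signals)
  amp[amp < 64 * .Machine$double.eps * n * max(abs(x), 1)] <- 0
  freqs <- rate_hz * seq_len(k_max) / n

  energy <- sum(amp)
  rss <- sqrt(sum(amp^2))
  dom <- if (max(amp) > 0) freqs[which.max(amp)] else 0

  # interior local maxima, strict on both sides
  is_peak <- if (k_max >= 3) {
    c(FALSE, amp[2:(k_max - 1)] > amp[1:(k_max - 2)] &
        amp[2:(k_max - 1)] > amp[3:k_max], FALSE)
  } else {
    rep(FALSE, k_max)
  }
  p_amp <- amp[is_peak]
  p_freq <- freqs[is_peak]
  ord <- order(p_amp, decreasing = TRUE)
  first_peak <- if (length(p_amp) >= 1) p_amp[ord[1]] else 0
  second_peak <- if (length(p_amp) >= 2) p_amp[ord[2]] else 0
  peak_difference <- if (length(p_amp) >= 2) {
    abs(p_freq[ord[1]] - p_freq[ord[2]])
  } else {
    0
  }
  peak_rms <- if (length(p_amp) >= 1) sqrt(mean(p_amp^2)) else 0

  c(
    energy = energy, dominant_frequency = dom,
    peak_difference = peak_difference, peak_rms = peak_rms,
    root_sum_squares = rss, first_peak = first_peak,
    second_peak = second_peak
  )
}

# Dominant direction / orientation features computed on a triad jointly.
# Returns a list with eigenvalues (descending, length 3), the cagh scalar,
# and the mean rotation angle (radians) about the mean sensor vector.
triad_geometry <- function(m) {
  n <- nrow(m)
  cv <- stats::cov(m)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0                      # numerical guard

  gbar <- colMeans(m)
  gnorm <- sqrt(sum(gbar^2))

  cagh <- 0
  rot <- 0
  if (gnorm > 0) {
    ghat <- gbar / gnorm
    # projection onto the plane orthogonal to the gravity estimate
    proj <- m - (m %*% ghat) %*% t(ghat)
    pv <- stats::cov(proj)
    e <- eigen(pv, symmetric = TRUE)
    hhat <- e$vectors[, 1]
    sg <- as.vector(m %*% ghat)
    sh <- as.vector(m %*% hhat)
    if (sd(sg) > 0 && sd(sh) > 0) cagh <- cor(sg, sh)

    norms <- sqrt(rowSums(m^2))
    ok <- norms > 0
    if (any(ok)) {
      cosang <- (m[ok, , drop = FALSE] %*% ghat) / norms[ok]
      rot <- mean(acos(pmin(pmax(cosang, -1), 1)))
    }
  }
  list(eigenvalues = ev, cagh = cagh, rotation = rot, degenerate = gnorm == 0)
}

#' Orientation features of the accelerometer and gyroscope triads
#'
#' Some of the bank's features are inherently triad-level — they need all
#' three axes of a sensor at once — but must still fill per-channel slots to
#' keep the 25 x 7 bookkeeping.  The assignment is:
#'
#' * `eigenvalues`: the descending eigenvalues of the 3x3 sample covariance
#'   of the accelerometer triad fill the `ax`/`ay`/`az` slots (dominant
#'   direction of movement), likewise for the gyroscope into `gx`/`gy`/`gz`;
#'   the magnitude slot receives the accelerometer total variance
#'   (eigenvalue sum).
#' * `cagh`: gravity is estimated as the normalised window-mean acceleration
#'   vector, heading as the dominant eigenvector of the acceleration
#'   projected onto the plane orthogonal to gravity; `cagh` is the Pearson
#'   correlation between the acceleration components along gravity and along
#'   heading.  The scalar fills the accelerometer and magnitude slots; the
#'   gyroscope slots receive the same construction on the gyroscope triad.
#' * `avg_rotation_angles`: mean angle (radians) between each sample vector
#'   and the window-mean vector, same slot assignment as `cagh`.
#'
#' Zero-variance or zero-gravity windows fall back to 0.
#'
#' @param accel n x 3 matrix of accelerometer samples (ax, ay, az).
#' @param gyro n x 3 matrix of gyroscope samples (gx, gy, gz).
#' @return Named numeric vector with entries
#'   `eigenvalues__*`, `cagh__*`, `avg_rotation_angles__*` for all 7 slots.
#' @export
triad_orientation_features <- function(accel, gyro) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (nrow(accel) != nrow(gyro) || ncol(accel) != 3 || ncol(gyro) != 3) {
    abort("accel and gyro must be n x 3 matrices of equal length",
          class = "wristpose_shape_error")
  }
  check_window_length(accel[, 1], 3)

  ga <- triad_geometry(accel)
  gg <- triad_geometry(gyro)

  out <- c(
    eigenvalues__ax = ga$eigenvalues[1], eigenvalues__ay = ga$eigenvalues[2],
    eigenvalues__az = ga$eigenvalues[3],
    eigenvalues__gx = gg$eigenvalues[1], eigenvalues__gy = gg$eigenvalues[2],
    eigenvalues__gz = gg$eigenvalues[3],
    eigenvalues__amag = sum(ga$eigenvalues),
    cagh__ax = ga$cagh, cagh__ay = ga$cagh, cagh__az = ga$cagh,
    cagh__gx = gg$cagh, cagh__gy = gg$cagh, cagh__gz = gg$cagh,
    cagh__amag = ga$cagh,
    avg_rotation_angles__ax = ga$rotation, avg_rotation_angles__ay = ga$rotation,
    avg_rotation_angles__az = ga$rotation,
    avg_rotation_angles__gx = gg$rotation, avg_rotation_angles__gy = gg$rotation,
    avg_rotation_angles__gz = gg$rotation,
    avg_rotation_angles__amag = ga$rotation
  )
  out
}

#' Extract the 175-entry feature vector from one movement window
#'
#' Computes the 25 per-window features on each of the 7 channels: the six
#' sensor axes and the acceleration magnitude.  The vector is deterministic
#' given the window and its sampling rate, contains no NaN or infinite
#' values (degenerate windows resolve to the documented fallbacks), and is
#' named `<feature>__<channel>` in the canonical order of [feature_names()].
#'
#' @param window Data frame or matrix with columns `ax, ay, az, gx, gy, gz`.
#' @param rate_hz Sampling rate of the window in Hz.
#' @return Named numeric vector of length 175.
#' @export
extract_features <- function(window, rate_hz) {
  w <- as.data.frame(window)
  missing <- setdiff(IMU_CHANNELS, names(w))
  if (length(missing) > 0) {
    abort(paste0("window missing channel(s): ", paste(missing, collapse = ", ")),
          class = "wristpose_schema_error")
  }
  check_window_length(w$ax, 4)

  channels <- list(
    ax = w$ax, ay = w$ay, az = w$az,
    gx = w$gx, gy = w$gy, gz = w$gz,
    amag = triad_magnitude(w$ax, w$ay, w$az)
  )

  per_channel <- purrr::imap(channels, function(x, ch) {
    v <- c(
      time_stats(x),
      avg_difference = avg_pairwise_difference(x),
      crossing_rates(x),
      avg_mean_intensity = mean(abs(x)),
      spectral_features(x, rate_hz)
    )
    setNames(v, paste0(names(v), "__", ch))
  })
  vals <- unlist(unname(per_channel))

  triad <- triad_orientation_features(
    cbind(ax = w$ax, ay = w$ay, az = w$az),
    cbind(gx = w$gx, gy = w$gy, gz = w$gz)
  )
  vals <- c(vals, triad)

  out <- vals[feature_names()]
  stopifnot(!anyNA(out), all(is.finite(out)))
  out
}

#' Build a feature matrix from a window collection
#'
#' Applies the causal moving-average filter to each window (unless the
#' windows were cut from an already-filtered stream) and extracts the
#' 175-entry feature vector from each, producing the windows-by-features
#' table the selector and classifier consume.
#'
#' @param windows A window collection as returned by [cut_windows()] or
#'   [simulate_study()]: a tibble with columns `subject_id`, `label`,
#'   `sampling_rate_hz` and a `data` list column of sample tibbles.
#' @param filter_window_s Moving-average window in seconds applied to each
#'   window before extraction, or `NULL` if the stream was pre-filtered.
#' @return Tibble with columns `subject_id`, `label` and the 175 feature
#'   columns.
#' @export
build_feature_matrix <- function(windows, filter_window_s = 1) {
  feats <- purrr::map2(
    windows$data, windows$sampling_rate_hz,
    function(dat, rate) {
      if (!is.null(filter_window_s)) {
        dat <- purrr::map_dfc(
          dat[IMU_CHANNELS],
          moving_average_filter, window_s = filter_window_s, rate_hz = rate
        )
      }
      extract_features(dat, rate)
    }
  )
  dplyr::bind_cols(
    tibble::tibble(subject_id = windows$subject_id, label = windows$label),
    tibble::as_tibble(do.call(rbind, feats))
  )
}
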