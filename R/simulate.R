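# Seeded synthetic wrist-IMU study.
#
# The simulator emulates the laboratory collection protocol: 20 subjects,
# 10 repetitions of each movement, 5-s annotated windows at 100 Hz from a
# +/-2 g accelerometer and +/-300 deg/s gyroscope.  A posture transition is
# modelled as a rotation of the gravity vector between posture-specific
# canonical wrist orientations with a raised-cosine angular-velocity
# profile; the gyroscope reads the exact kinematic angular velocity and the
# accelerometer the rotated gravity, both plus Gaussian noise and clipped
# at the sensor range.
#
# The three postures are laid out as a one-parameter pitch chain
# (stand -> sit -> lie, ~90 deg of forearm pitch per step about the watch
# z axis).  Adjacent transitions (e.g. stand_sit and sit_lie) therefore
# share their angular-velocity signature and are told apart by the gravity
# context in the accelerometer, which reproduces the essential difficulty
# of wrist-worn posture recognition: the gyroscope alone cannot do it.

POSTURE_GRAVITY <- list(
  stand = c(0, 1, 0),    # arm hanging, y toward hand reads +1 g
  sit   = c(1, 0, 0),    # forearm level on the lap, x up
  lie   = c(0, -1, 0)    # lying, forearm further pitched through vertical
)

# Activity-of-daily-living confounders.  Each combines up to three motion
# components in the sensor frame:
#   * a fast oscillation (frequency in Hz, accelerometer amplitude in g,
#     gyroscope amplitude in deg/s along kind-specific directions);
#   * a slow forearm wobble — a rotation of the gravity vector of
#     `wobble_deg` peak amplitude at `wobble_freq` Hz about `wobble_axis`,
#     with the matching kinematic angular velocity on the gyroscope;
#   * a slow translational sway (`slow_amp` g at `slow_freq` Hz along
#     `slow_dir`) — hand translation with no rotation, hence no gyroscope
#     footprint.
# The slow components are what a 1-s moving-average filter leaves visible
# (fast tones are strongly attenuated).  Rotation-dominant ADLs (brushing,
# cup lifting, arm swings) announce themselves on the gyroscope;
# translation-dominant ones (typing, texting) are visible only in the
# accelerometer, as for the real activities.
CONFOUNDER_PARAMS <- list(
  brushing_teeth = list(freq = 3.3, acc_amp = 0.25, gyro_amp = 80,
                        acc_dir = c(0, 0, 1), gyro_dir = c(1, 0, 0),
                        wobble_deg = 15, wobble_freq = 0.40,
                        wobble_axis = c(1, 0, 0)),
  lifting_cup    = list(freq = 1.1, acc_amp = 0.15, gyro_amp = 40,
                        acc_dir = c(1, 0, 0), gyro_dir = c(0, 0, 1),
                        wobble_deg = 35, wobble_freq = 0.45,
                        wobble_axis = c(0, 0, 1)),
  typing         = list(freq = 2.5, acc_amp = 0.08, gyro_amp = 3,
                        acc_dir = c(0, 1, 0), gyro_dir = c(1, 0, 0),
                        slow_amp = 0.10, slow_freq = 0.50,
                        slow_dir = c(0, 1, 0)),
  phone_texting  = list(freq = 2.0, acc_amp = 0.05, gyro_amp = 2,
                        acc_dir = c(1, 0, 0), gyro_dir = c(0, 1, 0),
                        slow_amp = 0.12, slow_freq = 0.40,
                        slow_dir = c(1, 0, 0)),
  arm_swing      = list(freq = 1.3, acc_amp = 0.25, gyro_amp = 70,
                        acc_dir = c(0, 1, 1) / sqrt(2), gyro_dir = c(0, 0, 1),
                        wobble_deg = 40, wobble_freq = 0.35,
                        wobble_axis = c(0, 0, 1))
)

#' Synthetic-study configuration
#'
#' Collects the parameters of the synthetic wrist-IMU study.  Defaults are
#' the laboratory protocol: 20 subjects, 10 repetitions per movement class,
#' 100 Hz sampling, 5-s windows, a +/-2 g / +/-300 deg/s sensor.  Noise
#' levels (0.03 g, 2 deg/s) are typical consumer MEMS figures; per-subject
#' speed and amplitude factors are drawn once per subject from the given
#' ranges, and each subject carries a random wrist-pose offset of up to
#' `orientation_jitter_deg`.
#'
#' @param n_subjects Number of simulated subjects.
#' @param reps_per_class Repetitions of each movement class per subject.
#' @param rate_hz Sampling rate: 100, 50 or 10 Hz.
#' @param duration_s Annotated window length in seconds.
#' @param noise_sd_accel Accelerometer noise SD in g.
#' @param noise_sd_gyro Gyroscope noise SD in deg/s.
#' @param subject_speed_range,subject_amplitude_range Ranges of the
#'   per-subject movement speed and amplitude factors.
#' @param orientation_jitter_deg Maximum per-subject wrist-pose offset.
#' @param confounders Confounder kinds pooled into `other_movement`; any of
#'   `r paste(names(CONFOUNDER_PARAMS), collapse = ", ")`.
#' @param accel_range_g,gyro_range_dps Sensor ranges for clipping.
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20, reps_per_class = 10,
                       rate_hz = 100, duration_s = 5,
                       noise_sd_accel = 0.03, noise_sd_gyro = 2,
                       subject_speed_range = c(0.8, 1.2),
                       subject_amplitude_range = c(0.8, 1.2),
                       orientation_jitter_deg = 15,
                       confounders = names(CONFOUNDER_PARAMS),
                       accel_range_g = 2, gyro_range_dps = 300,
                       seed = 42) {
  stopifnot(
    n_subjects >= 1, reps_per_class >= 1, rate_hz %in% c(100, 50, 10),
    duration_s > 0, noise_sd_accel >= 0, noise_sd_gyro >= 0
  )
  bad <- setdiff(confounders, names(CONFOUNDER_PARAMS))
  if (length(bad) > 0) {
    abort(paste0("unknown confounder kind(s): ", paste(bad, collapse = ", ")),
          class = "wristpose_parameter_error")
  }
  structure(
    list(
      n_subjects = n_subjects, reps_per_class = reps_per_class,
      rate_hz = rate_hz, duration_s = duration_s,
      noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
      subject_speed_range = subject_speed_range,
      subject_amplitude_range = subject_amplitude_range,
      orientation_jitter_deg = orientation_jitter_deg,
      confounders = confounders,
      accel_range_g = accel_range_g, gyro_range_dps = gyro_range_dps,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rodrigues <- function(v, axis, theta) {
  # rotate vector v about unit axis by theta (Rodrigues' formula)
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function(max_deg) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, 0, max_deg * pi / 180)
  function(v) rodrigues(v, axis, theta)
}

# Per-subject simulation parameters.
draw_subject_params <- function(cfg) {
  list(
    speed = runif(1, cfg$subject_speed_range[1], cfg$subject_speed_range[2]),
    amplitude = runif(1, cfg$subject_amplitude_range[1],
                      cfg$subject_amplitude_range[2]),
    pose = random_rotation(cfg$orientation_jitter_deg)
  )
}

# Accelerometer noise is white noise plus a slowly-varying per-window bias
# jitter at twice the white SD: at window scale the disturbance of a worn
# accelerometer is dominated by slow components (arm-pose micro-shifts,
# bias drift), which a 5-s average cannot remove, while the electronic
# white noise largely averages away.  The gyroscope gets white noise only:
# no bias/drift model.
finish_window <- function(acc, gyr, label, cfg) {
  n <- nrow(acc)
  bias <- matrix(rnorm(3, 0, 2 * cfg$noise_sd_accel), nrow = n, ncol = 3,
                 byrow = TRUE)
  acc <- acc + bias + matrix(rnorm(length(acc), 0, cfg$noise_sd_accel),
                             ncol = 3)
  gyr <- gyr + matrix(rnorm(length(gyr), 0, cfg$noise_sd_gyro), ncol = 3)
  acc <- pmin(pmax(acc, -cfg$accel_range_g), cfg$accel_range_g)
  gyr <- pmin(pmax(gyr, -cfg$gyro_range_dps), cfg$gyro_range_dps)
  tibble::tibble(
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]
  )
}

#' Simulate one posture-transition window
#'
#' Generates a 5-s window in which the wrist rotates between the source and
#' destination posture orientations over a nominal 2 s (scaled by the
#' subject's speed factor, amplitude-scaled rotation angle) centred in the
#' window, with static gravity before and after.  The angular-velocity
#' profile is a raised cosine, so the gyroscope integrates exactly to the
#' rotation angle; the accelerometer reads the rotated gravity vector.
#'
#' @param kind One of the six transition labels.
#' @param subject Subject parameter list from the study generator (speed,
#'   amplitude, pose); `NULL` uses the nominal subject.
#' @param cfg A [sim_config()].
#' @return One-row window tibble (same shape as [cut_windows()] rows) with
#'   the sample data in `data[[1]]`.
#' @export
simulate_transition <- function(kind, subject = NULL, cfg = sim_config()) {
  if (!kind %in% TRANSITION_LABELS) {
    abort(paste0("unknown transition kind: ", kind),
          class = "wristpose_parameter_error")
  }
  subject <- subject %||% list(speed = 1, amplitude = 1, pose = identity)
  n <- round(cfg$duration_s * cfg$rate_hz)
  tt <- (seq_len(n) - 1) / cfg$rate_hz

  g_src <- subject$pose(POSTURE_GRAVITY[[TRANSITION_SRC[[kind]]]])
  g_dst <- subject$pose(POSTURE_GRAVITY[[TRANSITION_DEST[[kind]]]])
  cosang <- sum(g_src * g_dst) / sqrt(sum(g_src^2) * sum(g_dst^2))
  base_angle <- acos(pmin(pmax(cosang, -1), 1))
  axis <- pracma_cross(g_src, g_dst)
  if (sqrt(sum(axis^2)) < 1e-9) {
    # antipodal postures (180 deg): pitch on through the posture chain's
    # plane of motion (about the watch z axis).  Both travel directions
    # share this axis; they differ in the half-plane the gravity vector
    # sweeps through, so the accelerometer, not the gyroscope, tells them
    # apart -- as for the other transition pairs of the chain.
    axis <- subject$pose(c(0, 0, -1))
  }
  axis <- axis / sqrt(sum(axis^2))

  theta_tot <- min(base_angle * subject$amplitude, pi - 0.05)
  t_move <- min(2 / subject$speed, cfg$duration_s)
  t_start <- (cfg$duration_s - t_move) / 2

  u <- pmin(pmax((tt - t_start) / t_move, 0), 1)     # movement phase in [0,1]
  theta <- theta_tot * (u - sin(2 * pi * u) / (2 * pi))
  omega <- ifelse(u > 0 & u < 1,
                  theta_tot / t_move * (1 - cos(2 * pi * u)), 0)

  acc <- t(vapply(theta, function(th) rodrigues(g_src, axis, th),
                  numeric(3)))
  gyr <- outer(omega * 180 / pi, axis)               # deg/s in sensor frame

  tibble::tibble(
    subject_id = "sim", label = kind, sampling_rate_hz = cfg$rate_hz,
    padded = FALSE, data = list(finish_window(acc, gyr, kind, cfg))
  )
}

#' Simulate a no-movement or confounder window
#'
#' `no_movement` windows are pure static gravity plus sensor noise.
#' Confounder windows add a kind-specific oscillation (1-4 Hz, fixed
#' accelerometer and gyroscope amplitudes along kind-specific directions,
#' random phase) on top of the static posture, emulating activities of
#' daily living whose wrist motion can resemble a transition; they are
#' labelled `other_movement`.
#'
#' @param kind A confounder kind (see [sim_config()]) or `"no_movement"`.
#' @param posture Static posture during the activity.
#' @inheritParams simulate_transition
#' @return One-row window tibble.
#' @export
simulate_confounder <- function(kind, posture = c("stand", "sit", "lie"),
                                subject = NULL, cfg = sim_config()) {
  posture <- match.arg(posture)
  subject <- subject %||% list(speed = 1, amplitude = 1, pose = identity)
  n <- round(cfg$duration_s * cfg$rate_hz)
  tt <- (seq_len(n) - 1) / cfg$rate_hz
  gvec <- subject$pose(POSTURE_GRAVITY[[posture]])
  acc <- matrix(gvec, nrow = n, ncol = 3, byrow = TRUE)
  gyr <- matrix(0, nrow = n, ncol = 3)

  if (kind == "no_movement") {
    label <- "no_movement"
  } else {
    p <- CONFOUNDER_PARAMS[[kind]]
    if (is.null(p)) {
      abort(paste0("unknown confounder kind: ", kind),
            class = "wristpose_parameter_error")
    }
    phase <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * p$freq * tt + phase)
    acc <- acc + outer(wave, subject$amplitude * p$acc_amp * subject$pose(p$acc_dir))
    gyr <- gyr + outer(wave, subject$amplitude * p$gyro_amp * subject$pose(p$gyro_dir))

    if (!is.null(p$wobble_deg)) {
      # slow forearm wobble: gravity swings about the wobble axis
      wphase <- runif(1, 0, 2 * pi)
      wamp <- subject$amplitude * p$wobble_deg * pi / 180
      theta_w <- wamp * sin(2 * pi * p$wobble_freq * tt + wphase)
      waxis <- subject$pose(p$wobble_axis)
      acc_wob <- t(vapply(theta_w, function(th) rodrigues(gvec, waxis, th),
                          numeric(3)))
      acc <- acc + acc_wob - matrix(gvec, nrow = n, ncol = 3, byrow = TRUE)
      omega_w <- wamp * 2 * pi * p$wobble_freq *
        cos(2 * pi * p$wobble_freq * tt + wphase)
      gyr <- gyr + outer(omega_w * 180 / pi, waxis)
    }
    if (!is.null(p$slow_amp)) {
      # slow translational sway: accelerometer only, no rotation
      sphase <- runif(1, 0, 2 * pi)
      sway <- subject$amplitude * p$slow_amp *
        sin(2 * pi * p$slow_freq * tt + sphase)
      acc <- acc + outer(sway, subject$pose(p$slow_dir))
    }
    label <- "other_movement"
  }

  tibble::tibble(
    subject_id = "sim", label = label, sampling_rate_hz = cfg$rate_hz,
    padded = FALSE, data = list(finish_window(acc, gyr, label, cfg))
  )
}

#' Simulate the full synthetic study
#'
#' Generates, for every subject, `reps_per_class` windows of each of the six
#' transitions, of `no_movement` (cycling the static posture) and of
#' `other_movement` (cycling the configured confounder kinds and postures),
#' giving a balanced eight-class collection.  Subject speed, amplitude and
#' wrist-pose parameters are drawn once per subject from the seeded
#' generator; the output is bit-identical for the same configuration and
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return Window collection tibble (`subject_id`, `label`,
#'   `sampling_rate_hz`, `padded`, `data`) ready for
#'   [build_feature_matrix()].
#' @export
#' @examples
#' w <- simulate_study(sim_config(n_subjects = 2, reps_per_class = 1,
#'                                rate_hz = 10))
#' nrow(w)  # 2 subjects x 8 classes
simulate_study <- function(cfg = sim_config()) {
  with_preserved_seed(cfg$seed, {
    out <- purrr::map_dfr(seq_len(cfg$n_subjects), function(si) {
      sid <- sprintf("S%02d", si)
      subject <- draw_subject_params(cfg)
      postures <- c("stand", "sit", "lie")
      windows <- list()
      for (rep in seq_len(cfg$reps_per_class)) {
        for (kind in TRANSITION_LABELS) {
          windows[[length(windows) + 1]] <-
            simulate_transition(kind, subject, cfg)
        }
        windows[[length(windows) + 1]] <- simulate_confounder(
          "no_movement", postures[(rep - 1) %% 3 + 1], subject, cfg
        )
        if (length(cfg$confounders) > 0) {
          ck <- cfg$confounders[(rep - 1) %% length(cfg$confounders) + 1]
          windows[[length(windows) + 1]] <- simulate_confounder(
            ck, postures[rep %% 3 + 1], subject, cfg
          )
        }
      }
      dplyr::mutate(dplyr::bind_rows(windows), subject_id = sid)
    })
    out
  })
}

#' Write a simulated study as CSV recordings plus annotation sidecars
#'
#' Emits the same CSV dialect the ingest functions read: one recording
#' `<subject>.csv` per subject (windows concatenated back to back into a
#' continuous stream) and one `<subject>_annotations.csv` with the
#' `start_s,end_s,label` rows marking each movement, so simulator output
#' feeds the real pipeline unchanged.
#'
#' @param windows Window collection from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param accel_range_g,gyro_range_dps Sensor ranges recorded on re-ingest.
#' @return Tibble of written file paths, invisibly.
#' @export
write_study_csv <- function(windows, dir, accel_range_g = 2,
                            gyro_range_dps = 300) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_dfr(unique(windows$subject_id), function(sid) {
    w <- windows[windows$subject_id == sid, ]
    rate <- w$sampling_rate_hz[1]
    len <- nrow(w$data[[1]])
    stream <- dplyr::bind_rows(w$data)
    stream <- dplyr::mutate(stream, t = (dplyr::row_number() - 1) / rate,
                            .before = 1)
    dur <- len / rate
    ann <- tibble::tibble(
      start_s = (seq_len(nrow(w)) - 1) * dur + dur * 0.3,
      end_s = (seq_len(nrow(w)) - 1) * dur + dur * 0.7,
      label = w$label
    )
    rec_path <- file.path(dir, paste0(sid, ".csv"))
    ann_path <- file.path(dir, paste0(sid, "_annotations.csv"))
    rec <- imu_recording(stream, rate, subject_id = sid,
                         accel_range_g = accel_range_g,
                         gyro_range_dps = gyro_range_dps)
    write_imu_csv(rec, rec_path)
    readr::write_csv(ann, ann_path, progress = FALSE)
    tibble::tibble(subject_id = sid, recording = rec_path,
                   annotations = ann_path)
  })
  invisible(paths)
}
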