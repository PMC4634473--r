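test_that("the generator is bit-deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 2, reps_per_class = 1, rate_hz = 10, seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)

  # different seeds: different noise, identical label bookkeeping
  c2 <- simulate_study(sim_config(n_subjects = 2, reps_per_class = 1,
                                  rate_hz = 10, seed = 6))
  expect_false(identical(a$data[[1]], c2$data[[1]]))
  expect_identical(table(a$label), table(c2$label))
})

test_that("study composition follows the collection protocol counts", {
  # protocol counts: subjects x 6 transitions x repetitions
  w <- simulate_study(sim_config(n_subjects = 20, reps_per_class = 10,
                                 rate_hz = 10, seed = 3))
  trans <- w$label %in% movement_labels(transitions_only = TRUE)
  expect_equal(sum(trans), 20 * 6 * 10)
  # balanced eight-class design
  expect_true(all(table(w$label) == 200))
  expect_equal(length(unique(w$subject_id)), 20)

  # no confounders: seven classes per subject
  w2 <- simulate_study(sim_config(n_subjects = 2, reps_per_class = 1,
                                  rate_hz = 10, confounders = character(0),
                                  seed = 1))
  expect_equal(nrow(w2), 2 * 7)
  expect_false("other_movement" %in% w2$label)

  expect_error(sim_config(confounders = "juggling"),
               class = "wristpose_parameter_error")
  expect_error(simulate_transition("sideways_shuffle"),
               class = "wristpose_parameter_error")
})

test_that("noise-free transitions are kinematically consistent", {
  cfg <- sim_config(rate_hz = 100, noise_sd_accel = 0, noise_sd_gyro = 0,
                    seed = 1)
  for (kind in movement_labels(transitions_only = TRUE)) {
    w <- simulate_transition(kind, subject = NULL, cfg = cfg)$data[[1]]
    n <- nrow(w)
    mag <- triad_magnitude(w$ax, w$ay, w$az)
    # static gravity at the window edges
    expect_equal(mag[1], 1, tolerance = 1e-6)
    expect_equal(mag[n], 1, tolerance = 1e-6)

    # the gyroscope integrates to the inter-posture rotation angle
    gyro_norm <- triad_magnitude(w$gx, w$gy, w$gz) * pi / 180
    integrated <- sum(gyro_norm) / cfg$rate_hz
    expected <- if (kind %in% c("stand_lie", "lie_stand")) pi - 0.05 else pi / 2
    expect_equal(integrated, expected, tolerance = 0.01)
  }

  # the two directions of a transition pair spin in opposite senses
  up <- simulate_transition("sit_stand", cfg = cfg)$data[[1]]
  down <- simulate_transition("stand_sit", cfg = cfg)$data[[1]]
  expect_lt(mean(up$gz) * mean(down$gz), 0)
})

test_that("no-movement and confounder windows have the stated structure", {
  cfg0 <- sim_config(rate_hz = 100, noise_sd_accel = 0, noise_sd_gyro = 0,
                     seed = 2)
  still <- simulate_confounder("no_movement", "sit", cfg = cfg0)
  expect_equal(still$label, "no_movement")
  d <- still$data[[1]]
  expect_equal(var(d$ax) + var(d$ay) + var(d$az) + var(d$gx), 0)

  # the driven gyro axis peaks at the configured oscillation frequency
  cfg <- sim_config(rate_hz = 100, seed = 9)
  brush <- simulate_confounder("brushing_teeth", "stand", cfg = cfg)
  expect_equal(brush$label, "other_movement")
  dom <- spectral_features(brush$data[[1]]$gx, 100)[["dominant_frequency"]]
  expect_lt(abs(dom - 3.5), 0.3)

  # confounders share the gravity baseline of their posture but not the label
  sit_conf <- simulate_confounder("typing", "sit", cfg = cfg0)
  sit_still <- simulate_confounder("no_movement", "sit", cfg = cfg0)
  expect_false(sit_conf$label == sit_still$label)
  expect_equal(mean(sit_conf$data[[1]]$ax), mean(sit_still$data[[1]]$ax),
               tolerance = 0.05)
})

test_that("static windows keep accel magnitude near 1 g at study noise", {
  cfg <- sim_config(n_subjects = 3, reps_per_class = 3, rate_hz = 10,
                    seed = 13)
  w <- simulate_study(cfg)
  still <- w[w$label == "no_movement", ]
  dev <- vapply(still$data, function(d) {
    abs(mean(triad_magnitude(d$ax, d$ay, d$az)) - 1)
  }, numeric(1))
  expect_lt(mean(dev), 3 * cfg$noise_sd_accel)
})

test_that("simulator CSV output feeds the ingest pipeline unchanged", {
  dir <- withr::local_tempdir()
  w <- simulate_study(sim_config(n_subjects = 2, reps_per_class = 1,
                                 rate_hz = 10, seed = 8))
  write_study_csv(w, dir)
  files <- list.files(dir)
  expect_length(files, 4)  # recording + annotations per subject

  rec <- read_imu_csv(file.path(dir, "S01.csv"), subject_id = "S01")
  expect_equal(sampling_rate(rec), 10)
  ann <- read_annotations(file.path(dir, "S01_annotations.csv"))
  expect_equal(nrow(ann), 8)

  cut <- cut_windows(rec, ann, duration_s = 5, filter_window_s = NULL)
  expect_equal(cut$label, w$label[w$subject_id == "S01"])
  # windows cut back out of the stream equal the simulated windows
  expect_equal(as.data.frame(cut$data[[1]]),
               as.data.frame(w$data[[1]]), tolerance = 1e-6)
})
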