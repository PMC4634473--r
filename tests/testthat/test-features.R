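test_that("time-domain statistics follow the documented conventions", {
  s <- time_stats(c(1, 2, 3, 4, 5))
  expect_equal(s[["mean"]], 3)
  expect_equal(s[["sum"]], 15)
  expect_equal(s[["median"]], 3)
  expect_equal(s[["min"]], 1)
  expect_equal(s[["max"]], 5)
  expect_equal(s[["rms"]], sqrt(11))  # sqrt((1+4+9+16+25)/5)
  expect_equal(s[["variance"]], var(1:5))  # n-1 denominator
  expect_equal(s[["iqr"]], 2)

  # moment conventions against direct evaluation
  set.seed(9)
  x <- rnorm(200)^2
  s2 <- time_stats(x)
  m <- mean(x); d <- x - m
  expect_equal(s2[["skewness"]], mean(d^3) / mean(d^2)^1.5)
  expect_equal(s2[["kurtosis"]], mean(d^4) / mean(d^2)^2 - 3)

  # constant series: degenerate fallbacks
  sc <- time_stats(rep(2, 10))
  expect_equal(sc[["std"]], 0)
  expect_equal(sc[["skewness"]], 0)
  expect_equal(sc[["kurtosis"]], 0)
  expect_equal(sc[["iqr"]], 0)

  expect_error(time_stats(1), class = "wristpose_window_error")
})

test_that("average pairwise difference equals the O(n^2) brute force", {
  expect_equal(avg_pairwise_difference(c(0, 1, 2)), 4 / 3)
  expect_equal(avg_pairwise_difference(rep(5, 8)), 0)

  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(sample(2:120, 1), sd = runif(1, 0.1, 10))
    expect_equal(avg_pairwise_difference(x), brute_pairwise(x))
  }
})

test_that("crossing rates count strict sign changes", {
  expect_equal(crossing_rates(c(1, -1, 1, -1))[["zero_crossing_rate"]], 1)
  expect_equal(crossing_rates(rep(2, 6)),
               c(zero_crossing_rate = 0, mean_crossing_rate = 0))
  cr <- crossing_rates(c(2, 4, 2, 4))
  expect_equal(cr[["zero_crossing_rate"]], 0)
  expect_equal(cr[["mean_crossing_rate"]], 1)
  # exact zeros do not count as crossings
  expect_equal(crossing_rates(c(1, 0, 1))[["zero_crossing_rate"]], 0)
})

test_that("spectral features agree with a direct DFT oracle", {
  # constant series has an empty (all-zero) non-DC spectrum
  sc <- spectral_features(rep(1, 50), 10)
  expect_true(all(sc == 0))

  # pure 2 Hz tone, 5 s at 10 Hz
  t <- (0:49) / 10
  s1 <- spectral_features(sin(2 * pi * 2 * t), 10)
  expect_equal(s1[["dominant_frequency"]], 2.0)

  # two tones at 1 and 3 Hz -> peak frequency gap of 2 Hz
  s2 <- spectral_features(sin(2 * pi * t) + 0.8 * sin(2 * pi * 3 * t), 10)
  expect_equal(s2[["peak_difference"]], 2.0)

  # aggregates match the O(n^2) DFT on random windows
  set.seed(33)
  for (i in 1:50) {
    n <- sample(10:120, 1)
    x <- rnorm(n)
    amp <- brute_dft_amplitude(x)
    got <- spectral_features(x, 10)
    expect_equal(got[["energy"]], sum(amp), tolerance = 1e-8)
    expect_equal(got[["root_sum_squares"]], sqrt(sum(amp^2)),
                 tolerance = 1e-8)
    expect_equal(got[["dominant_frequency"]],
                 10 * which.max(amp) / n, tolerance = 1e-8)
  }
})

test_that("triad orientation features handle motion, rest and degeneracy", {
  # static window: no rotation, zero eigenvalues, degenerate cagh
  acc <- matrix(rep(c(0, -1, 0), each = 20), ncol = 3)
  gyr <- matrix(0, 20, 3)
  f <- triad_orientation_features(acc, gyr)
  expect_equal(f[["avg_rotation_angles__ax"]], 0)
  expect_equal(f[["eigenvalues__ax"]], 0)
  expect_equal(f[["cagh__ax"]], 0)

  # variance only along one axis: lambda1 > 0 = lambda2 = lambda3,
  # checked against a direct covariance eigen-solve
  set.seed(5)
  v <- rnorm(40)
  acc2 <- cbind(v, 0, 0)
  f2 <- triad_orientation_features(acc2, gyr[rep(1, 40), ] + cbind(v, v, v))
  expect_equal(f2[["eigenvalues__ax"]], max(eigen(stats::cov(acc2))$values))
  expect_gt(f2[["eigenvalues__ax"]], 0)
  expect_equal(f2[["eigenvalues__ay"]], 0)
  expect_equal(f2[["eigenvalues__az"]], 0)
  # magnitude slot carries the total variance of the accel triad
  expect_equal(f2[["eigenvalues__amag"]], sum(eigen(stats::cov(acc2))$values))

  expect_error(triad_orientation_features(acc, gyr[1:5, ]),
               class = "wristpose_shape_error")
})

test_that("the assembled vector has 175 finite named entries at every rate", {
  for (rate in c(100, 50, 10)) {
    n <- round(5 * rate)
    w <- make_window(n)
    fv <- extract_features(w, rate)
    expect_length(fv, 175)
    expect_named(fv, feature_names())
    expect_true(all(is.finite(fv)))
  }

  # all-zero window resolves every degenerate case to 0
  zw <- as.data.frame(matrix(0, 50, 6,
                             dimnames = list(NULL, c("ax", "ay", "az",
                                                     "gx", "gy", "gz"))))
  expect_true(all(extract_features(zw, 10) == 0))

  # determinism: identical windows give bitwise-identical vectors
  w <- make_window(50, seed = 2)
  expect_identical(extract_features(w, 10), extract_features(w, 10))

  # mean intensity worked example
  expect_equal(mean(abs(c(-1, 1, -1, 1))), 1)
})

test_that("amplitude scaling and time shifts act on features as expected", {
  w <- make_window(50, seed = 3)
  s <- 3.7
  ws <- w
  ws$ax <- s * w$ax
  f0 <- extract_features(w, 10)
  f1 <- extract_features(ws, 10)

  linear <- c("min", "max", "sum", "mean", "std", "rms", "energy")
  for (nm in linear) {
    expect_equal(f1[[paste0(nm, "__ax")]], s * f0[[paste0(nm, "__ax")]],
                 tolerance = 1e-10)
  }
  expect_equal(f1[["variance__ax"]], s^2 * f0[["variance__ax"]])
  expect_equal(f1[["zero_crossing_rate__ax"]], f0[["zero_crossing_rate__ax"]])
  expect_equal(f1[["dominant_frequency__ax"]], f0[["dominant_frequency__ax"]])

  # circular time shift of a periodic signal preserves amplitude spectra
  t <- (0:49) / 10
  x <- sin(2 * pi * 2 * t) + 0.5 * cos(2 * pi * t)
  shifted <- c(x[11:50], x[1:10])
  a <- spectral_features(x, 10)
  b <- spectral_features(shifted, 10)
  for (nm in c("energy", "root_sum_squares", "dominant_frequency",
               "first_peak", "second_peak")) {
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-8)
  }
})
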