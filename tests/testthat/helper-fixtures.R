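# Shared fixtures and independent oracles, built in code at test time.

# A deterministic recording: smooth sinusoidal motion on all channels.
make_recording <- function(n = 500, rate = 100, subject = "s1") {
  t <- (seq_len(n) - 1) / rate
  imu_recording(
    data.frame(
      t = t,
      ax = 0.3 * sin(2 * pi * 0.5 * t), ay = 1 + 0.1 * cos(2 * pi * t),
      az = 0.2 * sin(2 * pi * 2 * t),
      gx = 20 * sin(2 * pi * 0.8 * t), gy = 5 * cos(2 * pi * 0.3 * t),
      gz = 10 * sin(2 * pi * 1.5 * t)
    ),
    sampling_rate_hz = rate, subject_id = subject
  )
}

# A single movement window data frame with all six channels.
make_window <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(
    ax = rnorm(n), ay = rnorm(n, 1), az = rnorm(n, 0, 0.5),
    gx = rnorm(n, 0, 10), gy = rnorm(n, 0, 5), gz = rnorm(n, 2, 8)
  )
}

# O(n^2) brute-force mean absolute pairwise difference.
brute_pairwise <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + abs(x[i] - x[j])
  }
  s / (n * (n - 1) / 2)
}

# Direct O(n^2) DFT, one-sided amplitude spectrum for k = 1..floor(n/2).
brute_dft_amplitude <- function(x) {
  n <- length(x)
  ks <- seq_len(n %/% 2)
  vapply(ks, function(k) {
    idx <- 0:(n - 1)
    re <- sum(x * cos(-2 * pi * k * idx / n))
    im <- sum(x * sin(-2 * pi * k * idx / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# Small cached synthetic study shared across tests (built once per run).
tiny_study_env <- new.env(parent = emptyenv())
tiny_study <- function() {
  if (is.null(tiny_study_env$fm)) {
    w <- simulate_study(
      sim_config(n_subjects = 3, reps_per_class = 2, rate_hz = 10, seed = 11)
    )
    tiny_study_env$windows <- w
    tiny_study_env$fm <- build_feature_matrix(w)
  }
  tiny_study_env
}
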