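# Kernel maximum-margin multiclass classifier.  The Pearson VII universal
# kernel (PUK) is authored here; each binary soft-margin dual is delegated
# to kernlab's interior-point QP solver (ipop) on a precomputed Gram
# matrix — deterministic, with runtime independent of how separable the
# labels are — while the one-vs-one decomposition, voting and scaling live
# in this file.

#' Kernel specification
#'
#' Describes the kernel and regularisation of the maximum-margin classifier.
#' The PUK shape defaults `omega = 1`, `sigma = 1` are the conventional
#' defaults of the kernel's reference implementation; with `omega = 1` the
#' Pearson VII profile is a Lorentzian, and larger `omega` approaches a
#' Gaussian.  The complexity `C` defaults to 100 to penalise training
#' mistakes heavily.
#'
#' @param kind `"puk"` (Pearson VII universal kernel) or `"rbf"` (Gaussian
#'   radial basis function, the common alternative in activity recognition).
#' @param omega,sigma PUK shape and width, strictly positive.
#' @param gamma RBF width; default `1/n_features`, resolved at training time
#'   when `NULL`.
#' @param C Soft-margin complexity (cost) parameter.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("puk", "rbf"), omega = 1, sigma = 1,
                        gamma = NULL, C = 100) {
  kind <- match.arg(kind)
  stopifnot(omega > 0, sigma > 0, C > 0, is.null(gamma) || gamma > 0)
  structure(
    list(kind = kind, omega = omega, sigma = sigma, gamma = gamma, C = C),
    class = "kernel_spec"
  )
}

#' Pearson VII universal kernel
#'
#' `K(u, v) = 1 / (1 + (2 ||u - v|| sqrt(2^(1/omega) - 1) / sigma)^2)^omega`.
#' A distance kernel whose shape parameter `omega` lets it interpolate
#' between Lorentzian and Gaussian profiles, which is what makes it
#' "universal": with suitable hyperparameters it can mimic the common
#' kernels.  `K(u, u) = 1`, the kernel is symmetric and strictly decreasing
#' in the distance.
#'
#' @param u,v Numeric vectors of equal length.
#' @param omega,sigma Shape and width parameters, strictly positive.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' puk_kernel(c(0, 0), c(0.3, 0.4))  # distance 0.5 -> 0.5 at defaults
puk_kernel <- function(u, v, omega = 1, sigma = 1) {
  if (length(u) != length(v)) {
    abort("u and v must have equal dimension", class = "wristpose_shape_error")
  }
  d <- sqrt(sum((u - v)^2))
  (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^(-omega)
}

# Squared Euclidean distances between rows of two matrices.
cross_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Gram matrix under a kernel specification
#'
#' @param a,b Numeric matrices with matching column count (rows are points);
#'   `b` defaults to `a`.
#' @param spec A [kernel_spec()]; a `NULL` RBF `gamma` resolves to
#'   `1/ncol(a)`.
#' @return `nrow(a)` x `nrow(b)` kernel matrix.
#' @export
kernel_gram <- function(a, b = a, spec = kernel_spec()) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- cross_sqdist(a, b)
  if (spec$kind == "puk") {
    s <- 4 * (2^(1 / spec$omega) - 1) / spec$sigma^2
    (1 + s * d2)^(-spec$omega)
  } else {
    gamma <- spec$gamma %||% (1 / ncol(a))
    exp(-gamma * d2)
  }
}

scale_minmax <- function(m, lo, hi) {
  rng <- hi - lo
  rng[rng == 0] <- 1          # constant training feature -> scaled to 0
  sweep(sweep(m, 2, lo), 2, rng, "/")
}

# Soft-margin binary SVM dual on a precomputed Gram matrix:
#   min_a  1/2 a' (yy' * K) a - 1'a   s.t.  y'a = 0,  0 <= a <= C
# solved with kernlab's interior-point QP (ipop).  `yn` is +/-1 with +1
# for the pair's first class.  The bias is recovered from the free
# support vectors (KKT), falling back to the midpoint of the bound
# constraints when every multiplier sits at a bound.
fit_binary_svm <- function(K, yn, C) {
  n <- length(yn)
  H <- (yn %o% yn) * K + diag(1e-8, n)
  sol <- kernlab::ipop(
    c = rep(-1, n), H = H, A = matrix(yn, 1), b = 0,
    l = rep(0, n), u = rep(C, n), r = 0, sigf = 5, maxiter = 60
  )
  alpha <- kernlab::primal(sol)
  coef <- alpha * yn
  f <- as.vector(K %*% coef)
  free <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  b0 <- if (length(free) > 0) {
    mean(yn[free] - f[free])
  } else {
    # KKT interval: alpha = 0 demands yn*(f+b) >= 1, alpha = C demands <= 1
    at0 <- alpha <= 1e-6 * C
    atC <- !at0
    lo_b <- suppressWarnings(max(c(1 - f[yn == 1 & at0],
                                   -1 - f[yn == -1 & atC])))
    hi_b <- suppressWarnings(min(c(1 - f[yn == 1 & atC],
                                   -1 - f[yn == -1 & at0])))
    if (is.finite(lo_b) && is.finite(hi_b)) (lo_b + hi_b) / 2 else 0
  }
  sv <- which(alpha > 1e-8 * C)
  list(coef = coef[sv], sv = sv, b0 = b0)
}

#' Train the kernel maximum-margin classifier
#'
#' Fits a soft-margin kernel classifier on the selected feature columns.
#' Features are min-max scaled to \[0, 1\] using statistics from the training
#' rows only (recorded in the model so prediction is self-contained; test
#' rows are clamped to the training box).  Multiclass handling is
#' one-vs-one: one binary machine per class pair, majority vote at
#' prediction, ties broken by the summed absolute decision values and then
#' by label order.  Each binary soft-margin dual is solved by the
#' interior-point QP solver [kernlab::ipop()] on the precomputed Gram
#' matrix, so training is deterministic and its cost does not depend on
#' how separable the labels happen to be.
#'
#' @param features Feature matrix tibble with a `label` column (and
#'   optionally `subject_id`, ignored) plus numeric feature columns.
#' @param spec A [kernel_spec()].
#' @param selected Character vector of feature columns to use; default all.
#' @return A `posture_model` object.
#' @export
train_classifier <- function(features, spec = kernel_spec(),
                             selected = NULL) {
  cols <- setdiff(names(features), c("label", "subject_id"))
  selected <- selected %||% cols
  missing <- setdiff(selected, cols)
  if (length(missing) > 0) {
    abort(paste0("selected feature(s) not in matrix: ",
                 paste(missing, collapse = ", ")),
          class = "wristpose_schema_error")
  }
  x <- as.matrix(features[selected])
  if (!all(is.finite(x))) {
    abort("feature matrix contains non-finite values",
          class = "wristpose_validation_error")
  }
  y <- as.character(features$label)
  classes <- c(intersect(ALL_LABELS, unique(y)),
               sort(setdiff(unique(y), ALL_LABELS)))
  if (length(classes) < 2) {
    abort("training data must contain at least 2 classes",
          class = "wristpose_training_error")
  }
  if (is.null(spec$gamma)) spec$gamma <- 1 / length(selected)

  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  xs <- scale_minmax(x, lo, hi)

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- purrr::map(pairs, function(pr) {
    idx <- which(y %in% pr)
    yn <- ifelse(y[idx] == pr[1], 1, -1)
    k_sub <- kernel_gram(xs[idx, , drop = FALSE], spec = spec)
    fit <- fit_binary_svm(k_sub, yn, spec$C)
    # keep only the support rows for prediction
    list(pair = pr, idx = idx[fit$sv], coef = fit$coef, b0 = fit$b0)
  })

  structure(
    list(
      spec = spec, selected = selected, classes = classes,
      scale_lo = lo, scale_hi = hi, x_scaled = xs, machines = machines,
      n_train = nrow(xs)
    ),
    class = "posture_model"
  )
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf(
    "<posture_model> %s kernel (C = %g), %d features, %d classes, %d training windows\n",
    toupper(x$spec$kind), x$spec$C, length(x$selected), length(x$classes),
    x$n_train
  ))
  invisible(x)
}

#' Predict movement labels
#'
#' One-vs-one voting over the model's binary machines.  Test features are
#' scaled with the training min-max statistics, clamped to \[0, 1\] so points
#' outside the training box still yield a valid label.  Vote ties are
#' broken by the summed absolute binary decision values credited to each
#' winning class, then by label order; the procedure is deterministic.
#'
#' @param object A `posture_model`.
#' @param newdata Feature matrix tibble carrying the model's selected
#'   feature columns.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.posture_model <- function(object, newdata, ...) {
  missing <- setdiff(object$selected, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("newdata missing feature(s): ",
                 paste(missing, collapse = ", ")),
          class = "wristpose_schema_error")
  }
  x <- as.matrix(newdata[object$selected])
  xs <- scale_minmax(x, object$scale_lo, object$scale_hi)
  xs <- pmin(pmax(xs, 0), 1)
  n <- nrow(xs)
  classes <- object$classes

  k_full <- kernel_gram(xs, object$x_scaled, spec = object$spec)

  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  scores <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (m in object$machines) {
    dec <- as.vector(k_full[, m$idx, drop = FALSE] %*% m$coef) + m$b0
    pred <- ifelse(dec >= 0, m$pair[1], m$pair[2])
    for (cl in m$pair) {
      hit <- pred == cl
      votes[hit, cl] <- votes[hit, cl] + 1L
      scores[hit, cl] <- scores[hit, cl] + abs(dec[hit])
    }
  }

  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      top <- top[scores[i, top] == max(scores[i, top])]
    }
    classes[top[1]]
  }, character(1))
}

#' @export
tidy.posture_model <- function(x, ...) {
  tibble::tibble(
    pair = purrr::map_chr(x$machines, ~ paste(.x$pair, collapse = " vs ")),
    n_support_vectors = purrr::map_int(x$machines, ~ length(.x$idx)),
    bias = purrr::map_dbl(x$machines, "b0")
  )
}

#' @export
glance.posture_model <- function(x, ...) {
  tibble::tibble(
    kernel = x$spec$kind, C = x$spec$C,
    n_features = length(x$selected), n_classes = length(x$classes),
    n_train = x$n_train
  )
}

#' Baseline activity-of-daily-living feature set
#'
#' The compact feature set long used for recognising activities of daily
#' living from a hip-worn accelerometer: per axis the mean, standard
#' deviation and spectral energy over the window, plus the pairwise Pearson
#' correlations between axes — 12 features for the accelerometer, 24 when
#' the gyroscope is included.  Zero-variance axes make the correlation
#' undefined; it falls back to 0.
#'
#' @inheritParams extract_features
#' @param use_gyro Also compute the same 12 features on the gyroscope axes.
#' @return Named numeric vector of length 12 (or 24 with `use_gyro`).
#' @export
adl_features <- function(window, rate_hz, use_gyro = FALSE) {
  w <- as.data.frame(window)
  one_sensor <- function(axes) {
    stats <- purrr::imap(axes, function(x, nm) {
      setNames(
        c(mean(x), sd(x), spectral_features(x, rate_hz)[["energy"]]),
        paste0(c("adl_mean__", "adl_std__", "adl_energy__"), nm)
      )
    })
    prs <- utils::combn(names(axes), 2, simplify = FALSE)
    cors <- purrr::map(prs, function(pr) {
      a <- axes[[pr[1]]]
      b <- axes[[pr[2]]]
      r <- if (sd(a) > 0 && sd(b) > 0) cor(a, b) else 0
      setNames(r, paste0("adl_corr__", pr[1], pr[2]))
    })
    unlist(c(stats, cors))
  }
  out <- one_sensor(list(ax = w$ax, ay = w$ay, az = w$az))
  if (use_gyro) {
    out <- c(out, one_sensor(list(gx = w$gx, gy = w$gy, gz = w$gz)))
  }
  out
}

#' Build the baseline ADL feature matrix from a window collection
#'
#' @inheritParams build_feature_matrix
#' @param use_gyro Include the gyroscope block (24 features instead of 12).
#' @return Tibble with `subject_id`, `label` and the baseline feature
#'   columns.
#' @export
build_adl_matrix <- function(windows, use_gyro = FALSE, filter_window_s = 1) {
  feats <- purrr::map2(
    windows$data, windows$sampling_rate_hz,
    function(dat, rate) {
      if (!is.null(filter_window_s)) {
        dat <- purrr::map_dfc(
          dat[IMU_CHANNELS],
          moving_average_filter, window_s = filter_window_s, rate_hz = rate
        )
      }
      adl_features(dat, rate, use_gyro = use_gyro)
    }
  )
  dplyr::bind_cols(
    tibble::tibble(subject_id = windows$subject_id, label = windows$label),
    tibble::as_tibble(do.call(rbind, feats))
  )
}
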