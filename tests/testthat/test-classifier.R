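test_that("the PUK kernel matches its closed form and is a valid kernel", {
  u <- c(0, 0)
  expect_equal(puk_kernel(u, u), 1.0)
  # omega = sigma = 1, distance 0.5: 1 / (1 + (2 * 0.5 * sqrt(2 - 1))^2) = 0.5
  expect_equal(puk_kernel(c(0, 0), c(0.3, 0.4)), 0.5)

  # strictly decreasing in distance, vanishing in the limit
  d <- seq(0.1, 50, length.out = 200)
  k <- vapply(d, function(dd) puk_kernel(0, dd), numeric(1))
  expect_true(all(diff(k) < 0))
  expect_lt(tail(k, 1), 1e-3)

  expect_error(puk_kernel(1:3, 1:2), class = "wristpose_shape_error")

  # Gram matrices: unit diagonal, symmetric, PSD within 1e-8
  set.seed(42)
  x <- matrix(rnorm(100 * 5), 100, 5)
  for (kind in c("puk", "rbf")) {
    g <- kernel_gram(x, spec = kernel_spec(kind))
    expect_equal(diag(g), rep(1, 100))
    expect_equal(g, t(g))
    expect_gt(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }

  # gram agrees with the scalar kernel entry-wise
  g <- kernel_gram(x[1:5, ], x[6:10, ], kernel_spec("puk", omega = 2, sigma = 0.7))
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(g[i, j],
                   puk_kernel(x[i, ], x[5 + j, ], omega = 2, sigma = 0.7))
    }
  }
})

test_that("training separates a separable toy problem exactly", {
  toy <- tibble::tibble(
    label = c("sit_stand", "sit_stand", "stand_sit", "stand_sit"),
    f1 = c(0, 0.1, 1, 0.9),
    f2 = c(0, 0.1, 1, 1.1)
  )
  m <- train_classifier(toy, kernel_spec("puk"))
  expect_equal(predict(m, toy), toy$label)

  # duplicated row duplicates its prediction
  expect_equal(predict(m, toy[c(1, 1), ]), rep("sit_stand", 2))

  # a point far outside the training box still yields a valid label
  far <- tibble::tibble(f1 = 50, f2 = -10)
  expect_true(predict(m, far) %in% m$classes)

  # constant feature scales to 0 without division failure
  toy$f3 <- 5
  m2 <- train_classifier(toy, kernel_spec("puk"))
  expect_equal(predict(m2, toy), toy$label)

  expect_error(train_classifier(toy[1:2, ]),
               class = "wristpose_training_error")
  expect_error(predict(m, toy["f1"]), class = "wristpose_schema_error")
  toy_bad <- toy
  toy_bad$f1[1] <- NaN
  expect_error(train_classifier(toy_bad),
               class = "wristpose_validation_error")
})

test_that("predictions are invariant under feature-wise affine rescaling", {
  fm <- tiny_study()$fm
  sel <- rank_features(fm, 12)$feature
  m <- train_classifier(fm, kernel_spec("puk"), selected = sel)
  p0 <- predict(m, fm)

  fm2 <- fm
  for (i in seq_along(sel)) {
    fm2[[sel[i]]] <- fm[[sel[i]]] * (i + 0.5) - 3 * i
  }
  m2 <- train_classifier(fm2, kernel_spec("puk"), selected = sel)
  expect_equal(predict(m2, fm2), p0)
})

test_that("the eight-class model trains on the synthetic study", {
  fm <- tiny_study()$fm
  sel <- rank_features(fm, 20)$feature
  m <- train_classifier(fm, kernel_spec("puk"), selected = sel)
  expect_length(m$classes, 8)
  expect_setequal(m$classes, movement_labels())

  # training-set fit on an easy configuration is essentially perfect
  acc <- mean(predict(m, fm) == fm$label)
  expect_gte(acc, 0.95)

  # tidy/glance expose the one-vs-one structure
  td <- tidy(m)
  expect_equal(nrow(td), choose(8, 2))
  expect_equal(glance(m)$n_features, 20)
})

test_that("the ADL baseline feature set has the documented cardinality", {
  w <- make_window(50)
  f12 <- adl_features(w, 10)
  expect_length(f12, 12)  # 3 axes x 3 stats + 3 correlations
  f24 <- adl_features(w, 10, use_gyro = TRUE)
  expect_length(f24, 24)

  # static window: zero-variance correlations fall back to 0
  zw <- as.data.frame(matrix(1, 50, 6,
                             dimnames = list(NULL, c("ax", "ay", "az",
                                                     "gx", "gy", "gz"))))
  fz <- adl_features(zw, 10)
  expect_equal(fz[["adl_corr__axay"]], 0)

  # matrix builder carries ids and labels through
  win <- tiny_study()$windows
  am <- build_adl_matrix(win[1:4, ], use_gyro = TRUE)
  expect_equal(ncol(am), 26)
  expect_equal(am$label, win$label[1:4])
})
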