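test_that("MDL discretization finds a separating cut and stops on noise", {
  # perfect two-class separation at x = 0 -> exactly one cut near 0,
  # matching a brute-force entropy scan over all boundaries
  x <- c(-3, -2.5, -2, -1.5, -1, 1, 1.5, 2, 2.5, 3)
  y <- rep(c("a", "b"), each = 5)
  cuts <- mdl_discretize(x, y)
  expect_length(cuts, 1)
  expect_equal(cuts, 0)  # midpoint of -1 and 1

  # brute-force scan oracle: the accepted cut is the entropy-minimising one
  xs <- sort(x)
  cand <- (xs[-1] + xs[-length(xs)]) / 2
  h <- vapply(cand, function(cc) {
    l <- y[order(x)][xs <= cc]
    r <- y[order(x)][xs > cc]
    ent <- function(v) {
      p <- table(v) / length(v)
      -sum(p * log2(p))
    }
    (length(l) * ent(l) + length(r) * ent(r)) / length(xs)
  }, numeric(1))
  expect_equal(cuts, cand[which.min(h)])

  # constant feature and single-class labels yield no cuts
  expect_length(mdl_discretize(rep(1, 10), y), 0)
  expect_length(mdl_discretize(x, rep("a", 10)), 0)

  # independent uniform noise is uninformative with high probability
  set.seed(101)
  empties <- sum(vapply(1:100, function(i) {
    length(mdl_discretize(runif(40), sample(c("a", "b"), 40, TRUE))) == 0
  }, logical(1)))
  expect_gte(empties, 90)
})

test_that("information gain attains its documented extremes", {
  # a 1-1 recoding of 2 balanced classes carries exactly H(y) = 1 bit
  y2 <- rep(c("a", "b"), each = 20)
  x2 <- rep(c(10, -5), each = 20) + rep(seq(0, 0.1, length.out = 20), 2)
  expect_equal(info_gain(x2, y2), 1.0)

  # constant feature: 0 bits
  expect_equal(info_gain(rep(3, 40), y2), 0)

  # 4 balanced classes, exact recoding: log2(4) = 2 bits
  y4 <- rep(c("a", "b", "c", "d"), each = 10)
  x4 <- rep(c(1, 2, 3, 4), each = 10)
  expect_equal(info_gain(x4, y4), 2.0)

  # bounds hold on random data
  set.seed(7)
  for (i in 1:20) {
    y <- sample(letters[1:3], 60, TRUE)
    ig <- info_gain(rnorm(60), y)
    expect_gte(ig, 0)
    expect_lte(ig, log2(3))
  }
})

test_that("information gain is invariant under monotone transforms", {
  set.seed(15)
  x <- rnorm(80)
  y <- ifelse(x + rnorm(80, 0, 0.3) > 0, "pos", "neg")
  ig0 <- info_gain(x, y)
  expect_gt(ig0, 0)
  expect_equal(info_gain(exp(x), y), ig0)
  expect_equal(info_gain(atan(x) * 100 + 3, y), ig0)
})

test_that("feature ranking is deterministic, complete and leak-free by design", {
  fm <- tiny_study()$fm

  rk30 <- rank_features(fm, k = 30)
  expect_equal(nrow(rk30), 30)
  expect_equal(rk30$rank, 1:30)

  rk_all <- rank_features(fm)
  expect_setequal(rk_all$feature, feature_names())
  expect_true(all(diff(rk_all$info_gain_bits) <= 1e-12))

  # a feature equal to the class code dominates the ranking
  fm2 <- fm
  fm2$oracle_feature <- as.numeric(factor(fm$label))
  names(fm2)[names(fm2) == "oracle_feature"] <- "aaa_class_code"
  expect_equal(rank_features(fm2, k = 1)$feature, "aaa_class_code")

  expect_error(rank_features(fm, k = 200), class = "wristpose_parameter_error")
  expect_identical(rank_features(fm, 10), rank_features(fm, 10))
})

test_that("the 10:1 feature budget reproduces the protocol arithmetic", {
  expect_equal(feature_budget(20, 7, 10), 14L)
  expect_equal(feature_budget(10, 7, 10), 7L)
  expect_equal(feature_budget(20, 7, 5), 28L)  # doubled non-linear budget
})
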