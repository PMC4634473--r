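# Information-gain feature ranking.
#
# Numeric features are discretized by recursive entropy-minimising binary
# splitting with the minimum-description-length (MDL) stopping rule
# (Fayyad & Irani), then scored by the reduction in class entropy the
# resulting bins achieve.  A feature whose MDL recursion accepts no split
# is uninformative at this sample size and scores 0.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Row-wise class entropy of a counts matrix (rows = candidate splits).
row_entropy_bits <- function(m, n = rowSums(m)) {
  xlx <- m * log2(m)
  xlx[m == 0] <- 0
  h <- log2(n) - rowSums(xlx) / n
  h[n == 0] <- 0
  h
}

# Recursive MDL partitioning of y (integer class codes) sorted by x.
# x_sorted: sorted numeric values; ymat: 0/1 indicator matrix n x k
# aligned with x_sorted.  Returns numeric vector of accepted cut values.
mdl_split <- function(x_sorted, ymat) {
  n <- nrow(ymat)
  if (n < 2) return(numeric(0))

  total <- colSums(ymat)
  h_all <- entropy_bits(total)
  if (h_all == 0) return(numeric(0))

  # candidate boundaries: between adjacent distinct x values
  cum <- apply(ymat, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  distinct <- which(diff(x_sorted) > 0)      # split after these indices
  if (length(distinct) == 0) return(numeric(0))

  left <- cum[distinct, , drop = FALSE]
  right <- matrix(total, nrow = length(distinct), ncol = length(total),
                  byrow = TRUE) - left
  n_left <- distinct
  n_right <- n - distinct

  h_left <- row_entropy_bits(left, n_left)
  h_right <- row_entropy_bits(right, n_right)
  h_split <- (n_left * h_left + n_right * h_right) / n
  best <- which.min(h_split)
  gain <- h_all - h_split[best]

  # MDL acceptance test
  k <- sum(total > 0)
  k1 <- sum(left[best, ] > 0)
  k2 <- sum(right[best, ] > 0)
  delta <- log2(3^k - 2) -
    (k * h_all - k1 * h_left[best] - k2 * h_right[best])
  threshold <- (log2(n - 1) + delta) / n
  if (gain <= threshold) return(numeric(0))

  i <- distinct[best]
  cut <- (x_sorted[i] + x_sorted[i + 1]) / 2
  lo <- seq_len(i)
  hi <- (i + 1):n
  c(
    mdl_split(x_sorted[lo], ymat[lo, , drop = FALSE]),
    cut,
    mdl_split(x_sorted[hi], ymat[hi, , drop = FALSE])
  )
}

#' MDL discretization of a numeric feature
#'
#' Recursive binary splitting of `x` that, at each step, picks the cut
#' minimising the class-information entropy of the two sides and accepts it
#' only if the gain exceeds the minimum-description-length coding cost.
#' Cut points are placed midway between the adjacent distinct values they
#' separate, so the partition depends only on the ordering of `x` — any
#' strictly monotone transform of the feature yields the same bins.
#'
#' @param x Numeric feature column.
#' @param y Class labels (coercible to factor), same length as `x`.
#' @return Sorted numeric vector of cut points; empty when no split passes
#'   the MDL test (the feature is uninformative at this sample size), in
#'   particular when `y` has a single class or `x` is constant.
#' @export
#' @examples
#' x <- c(-2, -1.5, -1, 1, 1.5, 2)
#' y <- c("a", "a", "a", "b", "b", "b")
#' mdl_discretize(x, y)  # one cut near 0
mdl_discretize <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2",
          class = "wristpose_parameter_error")
  }
  y <- factor(y)
  if (nlevels(y) < 2) return(numeric(0))
  ord <- order(x)
  ymat <- outer(y[ord], levels(y), "==") * 1L
  sort(mdl_split(x[ord], ymat))
}

#' Information gain of a feature with respect to the class label
#'
#' The reduction in class entropy achieved by conditioning on the
#' MDL-discretized feature: `IG = H(y) - sum_bins p(bin) H(y | bin)`, in
#' bits.  Bounded by `0 <= IG <= log2(#classes)`; a feature with an empty
#' cut list scores exactly 0, and a feature that recodes the class exactly
#' attains `H(y)`.
#'
#' @inheritParams mdl_discretize
#' @param cuts Optional pre-computed cut points (skips the discretization).
#' @return Information gain in bits.
#' @export
info_gain <- function(x, y, cuts = NULL) {
  y <- factor(y)
  if (is.null(cuts)) cuts <- mdl_discretize(x, y)
  h_all <- entropy_bits(table(y))
  if (length(cuts) == 0 || h_all == 0) return(0)
  bin <- findInterval(x, cuts)
  tab <- table(bin, y)
  n <- length(x)
  h_cond <- sum(apply(tab, 1, function(cnt) sum(cnt) / n * entropy_bits(cnt)))
  max(h_all - h_cond, 0)
}

#' Rank features by information gain
#'
#' Scores every feature column of a feature matrix by [info_gain()] against
#' the `label` column and returns the ranking, ties broken by canonical
#' feature-name order so the ranking is a deterministic function of the
#' matrix.  Inside cross-validation this must be run on the training folds
#' only — ranking on the full matrix would leak the held-out subject.
#'
#' @param features Feature matrix tibble: a `label` column plus numeric
#'   feature columns (and optionally `subject_id`, ignored).
#' @param k Number of top features to return (default all).
#' @return Tibble with columns `feature`, `info_gain_bits`, `rank`, sorted
#'   by rank, truncated to the top `k` rows.
#' @export
rank_features <- function(features, k = NULL) {
  cols <- setdiff(names(features), c("label", "subject_id"))
  if (!"label" %in% names(features) || length(unique(features$label)) < 2) {
    abort("feature matrix must carry a label column with >= 2 classes",
          class = "wristpose_parameter_error")
  }
  if (!is.null(k) && (k < 1 || k > length(cols))) {
    abort(sprintf("k must be between 1 and %d", length(cols)),
          class = "wristpose_parameter_error")
  }
  y <- factor(features$label)
  ig <- purrr::map_dbl(cols, function(cn) info_gain(features[[cn]], y))
  ord <- order(-ig, cols)
  out <- tibble::tibble(
    feature = cols[ord],
    info_gain_bits = ig[ord],
    rank = seq_along(cols)
  )
  if (!is.null(k)) out <- out[seq_len(k), ]
  out
}

#' Feature budget for a maximum-margin classifier
#'
#' The rule of thumb that a linear maximum-margin classifier should see at
#' most one feature per ten independent data samples.  Repetitions of the
#' same movement by the same subject are not independent, so the sample
#' count is subjects times unique movement classes.  With 20 subjects and 7
#' unique actions (six transitions plus no-movement) the linear budget is
#' 14 features; a non-linear kernel is conventionally granted double.
#'
#' @param n_subjects Number of subjects.
#' @param n_unique_classes Number of unique movement classes counted as
#'   independent samples (default 7).
#' @param ratio Samples required per feature (default 10).
#' @return Integer feature budget, `floor(n_subjects * n_unique_classes / ratio)`.
#' @export
#' @examples
#' feature_budget(20, 7)            # 14
#' feature_budget(20, 7, ratio = 5) # 28, the doubled non-linear budget
feature_budget <- function(n_subjects, n_unique_classes = 7, ratio = 10) {
  stopifnot(n_subjects >= 1, n_unique_classes >= 1, ratio >= 1)
  as.integer(floor(n_subjects * n_unique_classes / ratio))
}
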