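#' Per-class confusion counts
#'
#' For each class c: TP = windows of class c predicted as c; FN = windows of
#' class c predicted as anything else; FP = windows of other classes
#' predicted as c; TN = the remainder.  A misclassification is therefore
#' simultaneously a false negative for the true class and a false positive
#' for the predicted one.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Classes to account for; defaults to the union of labels
#'   seen in `truth` and `pred`, ordered canonically.
#' @return Tibble with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts("stand_sit", "stand_lie")
confusion_counts <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length",
          class = "wristpose_shape_error")
  }
  seen <- unique(c(truth, pred))
  classes <- classes %||% c(intersect(ALL_LABELS, seen),
                            sort(setdiff(seen, ALL_LABELS)))
  n <- length(truth)
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   tn = n - tp - fn - fp)
  })
}

#' F-score from precision and recall
#'
#' The harmonic mean `F = 2PR / (P + R)`, with the degenerate convention
#' `F = 0` when `P + R = 0`.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F-score in \[0, 1\].
#' @export
#' @examples
#' f_score(1, 0.5)  # 2/3
f_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' System precision and recall from confusion counts
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)` (0 when the
#' denominator is 0) are averaged with equal class weight; this does not
#' bias toward any movement when, as in the collection protocol, every
#' label has the same number of windows.  The pooled (micro) variant —
#' precision and recall of the summed counts — is reported alongside; under
#' balanced classes with every prediction inside the class set the two
#' coincide exactly.
#'
#' @param counts Confusion tibble from [confusion_counts()].
#' @return One-row tibble: `precision`, `recall` (class-averaged),
#'   `precision_pooled`, `recall_pooled`.
#' @export
averaged_pr <- function(counts) {
  if (sum(counts$tp + counts$fn) == 0) {
    abort("no positive instances in any class",
          class = "wristpose_evaluation_error")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  tibble::tibble(
    precision = mean(safe_div(counts$tp, counts$tp + counts$fp)),
    recall = mean(safe_div(counts$tp, counts$tp + counts$fn)),
    precision_pooled = safe_div(sum(counts$tp), sum(counts$tp) + sum(counts$fp)),
    recall_pooled = safe_div(sum(counts$tp), sum(counts$tp) + sum(counts$fn))
  )
}

#' Leave-one-subject-out cross-validation
#'
#' The generalisation test for a subject-worn sensor: each fold holds out
#' every window of one subject, ranks features by information gain on the
#' remaining subjects only, fits the scaling and the kernel classifier on
#' those training rows, and predicts the held-out subject's windows.  No
#' held-out row ever influences selection, scaling or training; the fold
#' audit in the returned report records the train/test subject overlap
#' (always empty).  Per-subject precision, recall and F-score are computed
#' from the subject's confusion counts and the mean F across subjects is
#' the headline metric.
#'
#' @param features Feature matrix tibble with `subject_id`, `label` and
#'   numeric feature columns (see [build_feature_matrix()]).
#' @param spec A [kernel_spec()].
#' @param k Number of top-ranked features per fold (default 30); `NULL`
#'   uses all feature columns without ranking (e.g. for the ADL baseline).
#' @return A `posture_eval` object: list with `per_subject` (tibble of
#'   subject, precision, recall, f_score), `confusion` (pooled per-class
#'   counts over all folds), `mean_f`, `selected` (per-fold feature lists),
#'   `fold_audit` and a config echo.
#' @export
losocv <- function(features, spec = kernel_spec(), k = 30) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) {
    abort("LOSOCV needs at least 2 subjects",
          class = "wristpose_parameter_error")
  }
  classes <- c(intersect(ALL_LABELS, unique(features$label)),
               sort(setdiff(unique(features$label), ALL_LABELS)))

  folds <- purrr::map(subjects, function(s) {
    test <- dplyr::filter(features, .data$subject_id == s)
    train <- dplyr::filter(features, .data$subject_id != s)

    selected <- if (is.null(k)) {
      setdiff(names(features), c("label", "subject_id"))
    } else {
      rank_features(train, k = k)$feature
    }
    model <- train_classifier(train, spec = spec, selected = selected)

    unseen <- setdiff(unique(test$label), model$classes)
    if (length(unseen) > 0) {
      warn(paste0("classes absent from training fold (count as FN): ",
                  paste(unseen, collapse = ", ")))
    }
    pred <- predict(model, test)
    counts <- confusion_counts(test$label, pred, classes = classes)
    pr <- averaged_pr(counts)
    list(
      subject = s, counts = counts, pr = pr, selected = selected,
      truth = test$label, pred = pred,
      leak = length(intersect(unique(train$subject_id), s))
    )
  })

  per_subject <- purrr::map_dfr(folds, function(f) {
    tibble::tibble(
      subject = f$subject,
      precision = f$pr$precision, recall = f$pr$recall,
      f_score = f_score(f$pr$precision, f$pr$recall),
      precision_pooled = f$pr$precision_pooled,
      recall_pooled = f$pr$recall_pooled
    )
  })

  pooled <- purrr::map_dfr(folds, "counts") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(c("tp", "fp", "fn", "tn"), sum),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$class, classes))

  structure(
    list(
      per_subject = per_subject,
      confusion = pooled,
      mean_f = mean(per_subject$f_score),
      selected = setNames(purrr::map(folds, "selected"),
                          purrr::map_chr(folds, "subject")),
      fold_audit = tibble::tibble(
        subject = purrr::map_chr(folds, "subject"),
        leaked_subjects = purrr::map_int(folds, "leak")
      ),
      config = list(kernel = spec$kind, C = spec$C, k = k,
                    n_subjects = length(subjects), classes = classes)
    ),
    class = "posture_eval"
  )
}

#' @export
print.posture_eval <- function(x, ...) {
  cat(sprintf(
    "<posture_eval> %d-subject LOSOCV, %s kernel, k = %s\n  mean F-score = %.3f\n",
    x$config$n_subjects, toupper(x$config$kernel),
    x$config$k %||% "all", x$mean_f
  ))
  invisible(x)
}

#' @describeIn losocv Per-subject precision, recall and F-score as a tibble.
#' @param x A `posture_eval` object.
#' @param ... Unused.
#' @export
tidy.posture_eval <- function(x, ...) x$per_subject

#' @describeIn losocv One-row summary: mean/min/max F-score and config.
#' @export
glance.posture_eval <- function(x, ...) {
  tibble::tibble(
    mean_f = x$mean_f,
    min_f = min(x$per_subject$f_score),
    max_f = max(x$per_subject$f_score),
    n_subjects = x$config$n_subjects,
    kernel = x$config$kernel,
    k = x$config$k %||% NA_integer_
  )
}

#' @describeIn losocv Bar chart of per-subject F-scores with the mean line.
#' @param object A `posture_eval` object.
#' @export
autoplot.posture_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_subject,
                  ggplot2::aes(x = .data$subject, y = .data$f_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_f, linetype = "dashed") +
    ggplot2::labs(
      x = "held-out subject", y = "F-score",
      title = sprintf("LOSOCV F-scores (mean %.3f)", object$mean_f)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
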