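#' Build a confusion matrix from truth and prediction
#'
#' @param truth Logical vector (TRUE = observed beta-turn).
#' @param predicted Logical vector of equal length.
#' @return A list of class `"confusion_matrix"` with integer counts
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  structure(
    list(TP = sum(truth & predicted), FP = sum(!truth & predicted),
         TN = sum(!truth & !predicted), FN = sum(truth & !predicted)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

cm_total <- function(cm) cm$TP + cm$FP + cm$TN + cm$FN

#' Prediction quality measures
#'
#' The four standard beta-turn measures over a confusion matrix:
#' * `q_total`: overall accuracy, `100 (TP + TN) / total` (percent);
#' * `q_predicted`: precision, `100 TP / (TP + FP)` — the fraction of
#'   predicted turns that are real (0 with a warning when nothing is
#'   predicted positive);
#' * `q_observed`: sensitivity, `100 TP / (TP + FN)` — the fraction of
#'   observed turns recovered (an evaluation set without positives is an
#'   error);
#' * `mcc`: Matthews correlation coefficient,
#'   `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#'   `[-1, 1]`, 0 by convention when any denominator factor is zero.
#'
#' @param cm A [confusion_matrix()].
#' @return A scalar (percent for the Q measures).
#' @name quality_measures
NULL

#' @rdname quality_measures
#' @export
q_total <- function(cm) {
  if (cm_total(cm) < 1L) stop_bt("empty confusion matrix")
  100 * (cm$TP + cm$TN) / cm_total(cm)
}

#' @rdname quality_measures
#' @export
q_predicted <- function(cm) {
  if (cm$TP + cm$FP < 1L) {
    warn_bt("no positive predictions; Q_predicted reported as 0")
    return(0)
  }
  100 * cm$TP / (cm$TP + cm$FP)
}

#' @rdname quality_measures
#' @export
q_observed <- function(cm) {
  if (cm$TP + cm$FN < 1L) stop_bt("evaluation set has no observed positives")
  100 * cm$TP / (cm$TP + cm$FN)
}

#' @rdname quality_measures
#' @export
mcc <- function(cm) {
  f <- c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP, cm$TN + cm$FN)
  if (any(f == 0)) return(0)
  (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(prod(as.numeric(f)))
}

#' ROC curve and area under it
#'
#' `roc_curve()` sweeps every distinct score as a threshold and returns the
#' (FPR, TPR) points; `roc_auc()` computes the area by the rank
#' (Mann-Whitney) method, which handles tied scores by midranks and equals
#' the trapezoid area under the curve.
#'
#' @param scores Numeric scores, larger meaning more turn-like.
#' @param labels Logical truth of equal length; both classes must occur.
#' @return `roc_curve()`: a tibble with `threshold`, `fpr`, `tpr`;
#'   `roc_auc()`: a scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop_bt("ROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname roc_auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop_bt("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(labels & scores >= t) / n_pos, double(1)),
    fpr = vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, double(1))
  )
}

# Random equal-size fold assignment; the remainder is spread one sample
# per fold over the first folds.
assign_folds <- function(n, k, seed) {
  if (k < 2L) stop_bt("need at least 2 folds")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  with_seed(seed, sample(rep.int(seq_len(k), sizes)))
}

#' Seven-fold cross-validation of the turn classifier
#'
#' Implements the published protocol: folds are formed by randomly
#' assigning equal numbers of window samples (remainder spread one per
#' fold); for each fold the ENTIRE model — K-means split, both clustered
#' models and the second layer — is refit on the other `k - 1` folds, and
#' the held-out fold is scored, so every sample is predicted exactly once
#' by a model that never saw it in either layer. Predictions are pooled
#' into one confusion matrix, the four quality measures and the ROC/AUC.
#'
#' Sample-level folding follows the published protocol; note that windows
#' of one chain can then span folds. `chain_level = TRUE` instead assigns
#' whole chains to folds (requires a `chain_id` column), avoiding that
#' leakage at the cost of unequal fold sizes.
#'
#' @param samples Window-sample tibble (`label` + matrix-column
#'   `features`; `chain_id` needed for `chain_level`).
#' @param k Number of folds (default 7).
#' @param config A [training_config()]; per-fold seeds derive from
#'   `config$seed`.
#' @param model `"two_layer"` (default) or `"single"` for the flat SVM
#'   baseline at the first-layer `(C, gamma)`.
#' @param threshold Positive-label threshold.
#' @param chain_level Assign whole chains to folds instead of samples.
#' @return A list of class `"cv_result"`: `predictions` (tibble with
#'   `fold`, `truth`, `score`, `label`), `cm`, `metrics` (one-row tibble
#'   with `q_total`, `q_predicted`, `q_observed`, `mcc`, `auc`), `folds`,
#'   `k`, `model`.
#' @export
cross_validate <- function(samples, k = 7L, config = training_config(),
                           model = c("two_layer", "single"),
                           threshold = 0.5, chain_level = FALSE) {
  model <- match.arg(model)
  n <- nrow(samples)
  if (chain_level) {
    if (!"chain_id" %in% names(samples)) stop_bt("chain_level folding needs a chain_id column")
    warn_bt("chain-level folding departs from the sample-level protocol; fold sizes will be unequal")
    ids <- unique(samples$chain_id)
    id_fold <- assign_folds(length(ids), k, config$seed)
    folds <- id_fold[match(samples$chain_id, ids)]
  } else {
    folds <- assign_folds(n, k, config$seed)
  }
  score <- numeric(n); lab <- logical(n)
  for (f in seq_len(k)) {
    test <- folds == f
    train <- samples[!test, , drop = FALSE]
    if (!any(train$label) || all(train$label)) {
      stop_bt("training split for fold %d has a single class", f)
    }
    fold_cfg <- config
    fold_cfg$seed <- config$seed + 1000L * f
    fitted <- if (model == "two_layer") {
      train_two_layer(train, fold_cfg)
    } else {
      train_single_svm(train, C = config$first_layer_C,
                       gamma = config$first_layer_gamma, seed = fold_cfg$seed)
    }
    pred <- stats::predict(fitted, samples[test, , drop = FALSE],
                           threshold = threshold)
    score[test] <- pred$score
    lab[test] <- pred$label
  }
  cm <- confusion_matrix(samples$label, lab)
  metrics <- tibble::tibble(
    q_total = q_total(cm), q_predicted = q_predicted(cm),
    q_observed = q_observed(cm), mcc = mcc(cm),
    auc = roc_auc(score, samples$label)
  )
  structure(
    list(predictions = tibble::tibble(fold = folds, truth = samples$label,
                                      score = score, label = lab),
         cm = cm, metrics = metrics, folds = folds, k = k, model = model),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<cv_result> %d-fold (%s): Q_total %.1f%%, Q_pred %.1f%%, Q_obs %.1f%%, MCC %.3f, AUC %.3f\n",
              x$k, x$model, m$q_total, m$q_predicted, m$q_observed, m$mcc, m$auc))
  invisible(x)
}

#' Tidy methods for cross-validation results
#'
#' `tidy()` returns per-fold quality measures; `glance()` the pooled
#' one-row summary; `autoplot()` the pooled ROC curve.
#'
#' @param x A `"cv_result"`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  x$predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      q_total = q_total(confusion_matrix(.data$truth, .data$label)),
      q_predicted = q_predicted(confusion_matrix(.data$truth, .data$label)),
      q_observed = q_observed(confusion_matrix(.data$truth, .data$label)),
      mcc = mcc(confusion_matrix(.data$truth, .data$label)),
      .groups = "drop"
    )
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(TP = x$cm$TP, FP = x$cm$FP, TN = x$cm$TN, FN = x$cm$FN,
                   n = cm_total(x$cm), k = x$k, model = x$model)
  )
}

#' @rdname tidy.cv_result
#' @param object A `"cv_result"`.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  curve <- roc_curve(object$predictions$score, object$predictions$truth)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, %d-fold CV (%s model), AUC = %.3f",
                      object$k, object$model, object$metrics$auc)
    ) +
    ggplot2::theme_minimal()
}
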