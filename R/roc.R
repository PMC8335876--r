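## ROC construction by explicit threshold sweep.
##
## Thresholds are the midpoints between consecutive distinct sorted scores
## plus -Inf/+Inf sentinels, so the curve is deterministic and every
## achievable confusion matrix appears exactly once. The AUC is the
## trapezoidal area over (FPR, TPR), which equals the tie-aware
## Mann-Whitney pair statistic (concordant + ties/2) / (n_pos * n_neg).

.trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
}

#' ROC analysis of classification scores
#'
#' Sweeps a threshold over the scores (midpoints between consecutive
#' distinct values, plus sentinels), computing sensitivity and specificity
#' at each point, the trapezoidal AUC, and the operating point maximizing
#' Youden's J = sensitivity + specificity - 1 (ties broken toward higher
#' sensitivity). The score orientation is chosen so that the reported AUC
#' is >= 0.5: if positives tend to score *lower* than negatives the scores
#' are negated internally and `orientation` is `"decreasing"`; thresholds
#' are reported on the original scale either way.
#'
#' @param scores Numeric scores, or a scored tibble from [map_and_score()]
#'   (then `labels` defaults to its `label` column).
#' @param labels Class labels; the first factor level (or `"positive"`) is
#'   the positive class.
#' @return An object of class `abcpe_roc`: a list with `auc` (the
#'   max-oriented area), `auc_raw` (the area for the as-given increasing
#'   orientation, which is `1 - auc` when `orientation` is
#'   `"decreasing"`), `orientation`, `curve` (tibble `threshold`, `sensitivity`,
#'   `specificity`, `fpr`, `tpr`), `optimal` (one-row tibble with the
#'   Youden point), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(labels)) labels <- scores$label
    scores <- scores$score
  }
  if (is.null(labels) || length(labels) != length(scores)) {
    abort("`labels` must match `scores` in length.",
          class = "abcpe_error_validation")
  }
  if (!is.factor(labels)) {
    labels <- factor(labels, levels = c("positive", "negative"))
  }
  is_pos <- labels == levels(labels)[[1]]
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be non-empty.", class = "abcpe_error_config")
  }
  if (anyNA(scores)) {
    abort("Scores must not contain missing values.",
          class = "abcpe_error_validation")
  }

  sweep_curve <- function(s) {
    distinct <- sort(unique(s))
    thresholds <- c(-Inf,
                    if (length(distinct) > 1)
                      (head(distinct, -1) + tail(distinct, -1)) / 2,
                    Inf)
    tpr <- vapply(thresholds, function(t) mean(s[is_pos] >= t), 0)
    fpr <- vapply(thresholds, function(t) mean(s[!is_pos] >= t), 0)
    tibble(threshold = thresholds, tpr = tpr, fpr = fpr)
  }

  curve <- sweep_curve(scores)
  auc_raw <- .trapezoid_auc(curve$fpr, curve$tpr)
  orientation <- "increasing"
  if (auc_raw < 0.5) {
    ## positives score lower than negatives: classify on -score, report
    ## thresholds on the original scale
    orientation <- "decreasing"
    curve <- sweep_curve(-scores)
    curve$threshold <- -curve$threshold
  }
  auc <- max(auc_raw, 1 - auc_raw)
  if (length(unique(scores)) == 1) {
    warn("All scores are identical; ROC is degenerate and AUC is 0.5.")
    auc <- 0.5
  }

  curve <- curve |>
    dplyr::mutate(sensitivity = .data$tpr, specificity = 1 - .data$fpr) |>
    dplyr::select("threshold", "sensitivity", "specificity", "fpr", "tpr")

  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(curve$sensitivity[best])]
  optimal <- dplyr::mutate(curve[best, ], youden_j = j[best])

  structure(
    list(auc = auc, auc_raw = auc_raw, orientation = orientation,
         curve = curve, optimal = optimal, n_pos = n_pos, n_neg = n_neg),
    class = "abcpe_roc"
  )
}

#' @export
print.abcpe_roc <- function(x, ...) {
  cat("ROC analysis (", x$n_pos, " positive / ", x$n_neg,
      " negative observations)\n", sep = "")
  cat(sprintf("  AUC: %.4f (orientation: %s)\n", x$auc, x$orientation))
  cat(sprintf(
    "  Youden point: threshold %.4g, sensitivity %.3f, specificity %.3f\n",
    x$optimal$threshold, x$optimal$sensitivity, x$optimal$specificity))
  invisible(x)
}

#' Tidy the threshold sweep of a ROC analysis
#'
#' @param x An `abcpe_roc` object.
#' @param ... Unused.
#' @return A tibble with one row per threshold: `threshold`,
#'   `sensitivity`, `specificity`, `fpr`, `tpr`.
#' @method tidy abcpe_roc
#' @export
tidy.abcpe_roc <- function(x, ...) {
  x$curve
}

#' One-row summary of a ROC analysis
#'
#' @param x An `abcpe_roc` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `auc_raw`, `sensitivity`, `specificity`,
#'   `threshold`, `youden_j`, `orientation`, `n_pos`, `n_neg`.
#' @method glance abcpe_roc
#' @export
glance.abcpe_roc <- function(x, ...) {
  tibble(
    auc = x$auc,
    auc_raw = x$auc_raw,
    sensitivity = x$optimal$sensitivity,
    specificity = x$optimal$specificity,
    threshold = x$optimal$threshold,
    youden_j = x$optimal$youden_j,
    orientation = x$orientation,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#'
#' @param object An `abcpe_roc` object.
#' @param ... Unused.
#' @return A ggplot: the ROC curve with the chance diagonal and the Youden
#'   operating point marked.
#' @method autoplot abcpe_roc
#' @export
autoplot.abcpe_roc <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = object$optimal, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
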