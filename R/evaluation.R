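# Classification metrics: sensitivity, specificity, accuracy, Matthews
# correlation and ROC AUC. Undefined-denominator cases are reported as NA
# and named in an `undefined` field rather than silently zeroed.

#' Confusion counts at a score threshold
#'
#' Predictions are `score >= threshold` (a score exactly at the threshold
#' counts as positive).
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) abort("Empty input.")
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have the same length.")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1.")
  pred <- as.integer(scores >= threshold)
  tibble(
    tp = sum(pred == 1L & labels == 1L),
    tn = sum(pred == 0L & labels == 0L),
    fp = sum(pred == 1L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L)
  )
}

#' Threshold metrics from confusion counts
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is returned as `NA` and listed in the
#' `undefined` column.
#'
#' @param counts One-row tibble (or list) with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with `se`, `sp`, `acc`, `mcc`, `undefined`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total < 1) abort("Confusion counts are empty.")
  undef <- character(0)
  se <- if (tp + fn > 0) tp / (tp + fn) else {undef <- c(undef, "se"); NA_real_}
  sp <- if (tn + fp > 0) tn / (tn + fp) else {undef <- c(undef, "sp"); NA_real_}
  acc <- (tp + tn) / total
  mcc_den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  mcc <- if (mcc_den > 0) {
    (as.double(tp) * tn - as.double(fp) * fn) / mcc_den
  } else {
    undef <- c(undef, "mcc"); NA_real_
  }
  tibble(se = se, sp = sp, acc = acc, mcc = mcc,
         undefined = paste(undef, collapse = ","))
}

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney estimator: the probability that a random
#' positive outscores a random negative, with ties counted one half. This
#' equals trapezoidal integration of the ROC curve with tie-grouped
#' thresholds.
#'
#' @param labels Binary vector (0/1) containing both classes.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have the same length.")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC requires both classes to be present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metrics report for one labelled score set
#'
#' @inheritParams confusion
#' @param dataset Optional dataset name for the report row.
#' @return One-row tibble of class `crbp_metrics` with `dataset`, `n`,
#'   `se`, `sp`, `acc`, `mcc`, `auc`, `undefined`.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5,
                            dataset = "dataset") {
  cm <- classification_metrics(confusion(labels, scores, threshold))
  out <- tibble(dataset = dataset, n = length(labels)) %>%
    dplyr::bind_cols(cm[, c("se", "sp", "acc", "mcc")]) %>%
    mutate(auc = auc_score(labels, scores), undefined = cm$undefined)
  class(out) <- c("crbp_metrics", class(out))
  out
}

#' Aggregate per-dataset metric reports
#'
#' Binds per-dataset rows and appends an unweighted arithmetic mean row
#' (dataset = "AVG"); metrics flagged undefined are excluded from the mean.
#'
#' @param reports A list of [evaluate_scores()] tibbles, or one tibble with
#'   several rows.
#' @return Tibble with one row per dataset plus the mean row.
#' @export
aggregate_metrics <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0) abort("`reports` must contain at least one report.")
  rows <- dplyr::bind_rows(reports)
  num <- c("se", "sp", "acc", "mcc", "auc")
  avg <- tibble(dataset = "AVG", n = sum(rows$n))
  for (m in num) avg[[m]] <- mean(rows[[m]], na.rm = TRUE)
  avg$undefined <- ""
  dplyr::bind_rows(rows, avg)
}

#' ROC curve points
#'
#' @inheritParams confusion
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   (0,0) to the (1,1) corner.
#' @export
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / max(1, sum(y == 0))),
    tpr = c(0, tp[last] / max(1, sum(y == 1)))
  )
}

#' Plot a ROC curve from labels and scores
#'
#' @inheritParams confusion
#' @return A ggplot object.
#' @export
plot_roc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  a <- auc_score(labels, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", a)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.crbp_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("dataset", "se", "sp", "acc", "mcc", "auc")],
    -"dataset", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$dataset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
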