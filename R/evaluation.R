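#' Area under the ROC curve (Mann-Whitney form)
#'
#' Over all (positive, negative) pairs, a concordant pair counts 1, a
#' tie counts 0.5, divided by n_pos * n_neg.  Computed via midranks,
#' which is algebraically identical to the all-pairs count.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- validate_outcome(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity at a threshold
#'
#' Predicted positive iff `score >= threshold`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels (both classes required).
#' @param threshold classification cutoff (default 0.5).
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5) {
  labels <- validate_outcome(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("sensitivity/specificity require both classes", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Metric report for one score vector
#'
#' @inheritParams sens_spec
#' @return a one-row data frame: `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `n_pos`, `n_neg`.
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  labels <- validate_outcome(labels)
  ss <- sens_spec(scores, labels, threshold)
  data.frame(auc = auc(scores, labels),
             sensitivity = unname(ss["sensitivity"]),
             specificity = unname(ss["specificity"]),
             threshold = threshold,
             n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' Summarise per-fold metric values
#'
#' The headline value is the maximum fold (the best outer validation run
#' is reported as the model's performance); the bounds are the 2.5th and
#' 97.5th type-7 percentiles across folds.  Both conventions are
#' recoverable because the full per-fold vector is always emitted
#' alongside.
#'
#' @param per_fold_values numeric vector of per-fold metrics (>= 2).
#' @return named numeric vector `c(point, lower, upper)`.
#' @export
fold_summary <- function(per_fold_values) {
  stopifnot(is.numeric(per_fold_values))
  if (length(per_fold_values) < 2L) {
    stop("fold_summary needs at least 2 per-fold values", call. = FALSE)
  }
  q <- stats::quantile(per_fold_values, c(0.025, 0.975), type = 7,
                       names = FALSE)
  c(point = max(per_fold_values), lower = q[1], upper = q[2])
}
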