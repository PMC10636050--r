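#' Confusion counts at a decision threshold
#'
#' Scores at or above the threshold are predicted cases (>= rule, so exact
#' ties go to the positive class).
#'
#' @param labels Binary labels (1 = case).
#' @param scores Numeric scores, higher = more case-like.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  stop_if_not(length(labels) == length(scores) && length(labels) > 0,
              "labels and scores must be equal-length and non-empty")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 TN = sum(!pred & labels == 0),
                 FP = sum(pred & labels == 0),
                 FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Matthews correlation coefficient
#'
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any factor of the denominator is zero.
#'
#' @param counts A [confusion()] result.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  with(counts, {
    den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  })
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random case outscores a
#' random control, ties counting one half (midranks). Equivalent to
#' trapezoidal integration of the ROC curve.
#'
#' @param labels Binary labels; both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, scores) {
  stop_if_not(length(labels) == length(scores), "length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stop_if_not(n1 > 0 && n0 > 0, "AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: sweep the unique scores in descending
#' order (tied scores enter as one group) and accumulate precision times
#' the recall increment.
#'
#' @param labels Binary labels; both classes must be present.
#' @param scores Numeric scores.
#' @return AUPRC in [0, 1]; the chance level equals the case prevalence.
#' @export
auprc <- function(labels, scores) {
  stop_if_not(length(labels) == length(scores), "length mismatch")
  n1 <- sum(labels == 1)
  stop_if_not(n1 > 0 && sum(labels == 0) > 0,
              "AUPRC requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(lab)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Full metrics report for scored predictions
#'
#' Sensitivity, specificity, precision, MCC at the given threshold plus AUC
#' and AUPRC. Values are on the [0, 1] scale; use
#' [as.data.frame.metrics_report()] with `percent = TRUE` for the
#' conventional x100 table scale.
#'
#' @param labels Binary labels (1 = case).
#' @param scores Numeric scores.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return A list of class `metrics_report` with `sen`, `spe`, `pre`,
#'   `mcc`, `auc`, `auprc`, `n_pos`, `n_neg`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cts <- confusion(labels, scores, threshold)
  both <- sum(labels == 1) > 0 && sum(labels == 0) > 0
  structure(list(
    sen = with(cts, safe_ratio(TP, TP + FN)),
    spe = with(cts, safe_ratio(TN, TN + FP)),
    pre = with(cts, safe_ratio(TP, TP + FP)),
    mcc = mcc(cts),
    auc = if (both) auc(labels, scores) else NA_real_,
    auprc = if (both) auprc(labels, scores) else NA_real_,
    n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
    class = "metrics_report")
}

metric_names <- c("sen", "spe", "pre", "mcc", "auc", "auprc")

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param percent If `TRUE`, scale sen/spe/pre/auc/auprc (and MCC) by 100 as
#'   in conventional results tables.
#' @param ... Unused.
#' @export
as.data.frame.metrics_report <- function(x, ..., percent = FALSE) {
  vals <- unlist(x[metric_names])
  if (percent) vals <- vals * 100
  df <- as.data.frame(as.list(vals))
  names(df) <- c("Sen", "Spe", "Pre", "MCC", "AUC", "AUPRC")
  df
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sen %.3f  spe %.3f  pre %.3f  mcc %.3f  auc %.3f  auprc %.3f  (%d+/%d-)\n",
              x$sen, x$spe, x$pre, x$mcc, x$auc, x$auprc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)) / (n1 n0))` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc_value The AUC estimate A.
#' @param n_pos,n_neg Numbers of cases and controls.
#' @return The standard error.
#' @export
hanley_mcneil_se <- function(auc_value, n_pos, n_neg) {
  a <- auc_value
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

#' Hanley-McNeil test comparing two AUCs on the same labels
#'
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)` with a two-sided
#' normal p-value. The correlation `r` between the two AUC estimates
#' defaults to 0 (conservative independent form); supply the correlated
#' value when available. Degenerate AUCs (0 or 1) give SE 0; a floor of
#' `1 / (n_pos * n_neg)` is applied with a warning.
#'
#' @param labels Shared binary labels.
#' @param scores_a,scores_b The two score vectors to compare.
#' @param r Correlation between the two AUC estimates (default 0).
#' @return List with `auc_a`, `auc_b`, `se_a`, `se_b`, `z`, `p`.
#' @export
hanley_mcneil_test <- function(labels, scores_a, scores_b, r = 0) {
  a1 <- auc(labels, scores_a)
  a2 <- auc(labels, scores_b)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  se1 <- hanley_mcneil_se(a1, n1, n0)
  se2 <- hanley_mcneil_se(a2, n1, n0)
  floor_se <- 1 / (n1 * n0)
  if (se1 < floor_se || se2 < floor_se) {
    warning("degenerate AUC: standard-error floor applied")
    se1 <- max(se1, floor_se)
    se2 <- max(se2, floor_se)
  }
  denom <- sqrt(se1^2 + se2^2 - 2 * r * se1 * se2)
  z <- if (a1 == a2) 0 else (a1 - a2) / denom
  list(auc_a = a1, auc_b = a2, se_a = se1, se_b = se2,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Average metrics over cross-validation folds
#'
#' Unweighted per-metric mean and standard deviation across folds (single
#' fold: sd 0). Folds with undefined values (e.g. one-class evaluation
#' folds) contribute `NA`, which is dropped with a warning.
#'
#' @param reports List of [metrics_report()] objects, one per fold.
#' @return List with `mean` and `sd`, each a named numeric vector over
#'   sen/spe/pre/mcc/auc/auprc, plus `n_folds`.
#' @export
cv_average <- function(reports) {
  stop_if_not(length(reports) >= 1, "need at least one fold")
  mat <- vapply(reports, function(rp) unlist(rp[metric_names]),
                numeric(length(metric_names)))
  mat <- matrix(mat, nrow = length(metric_names),
                dimnames = list(metric_names, NULL))
  if (anyNA(mat)) warning("undefined fold metrics dropped from the average")
  mean_v <- apply(mat, 1, mean, na.rm = TRUE)
  sd_v <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1) 0 else sd(v)
  })
  list(mean = mean_v, sd = sd_v, n_folds = length(reports))
}
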