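# Validation statistics: confusion metrics with F-score, ROC/AUC, Spearman
# correlation with permutation p-value, group comparisons.

#' Confusion-matrix metrics for a binary classifier
#'
#' Sensitivity, specificity, precision and F-score from predicted and true
#' flags. With class imbalance the F-score is the headline accuracy measure.
#' Ratios with zero denominators are reported as NA (undefined), not zero.
#'
#' @param predicted logical predictions.
#' @param truth logical ground truth (same length).
#' @return object of class `classification_report` with counts tp/fp/fn/tn
#'   and sensitivity, specificity, precision, f_score.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_ilam("predicted and truth must have equal length")
  }
  if (length(truth) < 1L) stop_ilam("need at least one observation")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f <- if (is.finite(sens) && is.finite(prec) && (sens + prec) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = length(truth),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f_score = f, auc = NA_real_, rho = NA_real_),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification report (n = %d)\n", x$n))
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  precision %.3f  F %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$f_score))
  if (is.finite(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  if (is.finite(x$rho)) cat(sprintf("  Spearman rho %.3f\n", x$rho))
  invisible(x)
}

#' ROC curve and AUC of a score against binary truth
#'
#' Sweeps every distinct score as a threshold, accumulates (FPR, TPR) points
#' and integrates by the trapezoidal rule; the result equals the Mann-Whitney
#' concordance statistic, with ties contributing one half.
#'
#' @param score numeric scores (higher = more positive).
#' @param truth logical flags; both classes must be present.
#' @return list with `auc` and `curve` (data.frame fpr, tpr).
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  if (length(score) != length(truth)) stop_ilam("length mismatch")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop_ilam("both classes must be present")
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(score >= th & truth) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(score >= th & !truth) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Spearman rank correlation with a seeded permutation p-value
#'
#' rho is the Pearson correlation of mid-ranks; the two-sided p-value comes
#' from random permutations of one vector under a fixed seed.
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) != length(y)) stop_ilam("length mismatch")
  if (length(x) < 3L) stop_ilam("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_ilam("undefined ranks: constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  obs <- abs(rho)
  exceed <- 0L
  with_substream(seed, "spearman_perm", {
    for (i in seq_len(n_perm)) {
      if (abs(stats::cor(rx, sample(ry))) >= obs - 1e-12) exceed <- exceed + 1L
    }
  })
  list(rho = rho, p_value = (exceed + 1) / (n_perm + 1))
}

#' Two-group comparison
#'
#' Wilcoxon rank-sum for continuous data (exact null for small samples
#' without ties, normal approximation otherwise) or Fisher's exact test for a
#' 2x2 table (`a` and `b` are the two rows of counts). Two-sided throughout.
#'
#' @param a,b numeric vectors (rank-sum) or length-2 count vectors (fisher).
#' @param kind "ranksum" or "fisher".
#' @return list with `statistic` and `p_value`.
#' @export
group_compare <- function(a, b, kind = c("ranksum", "fisher")) {
  kind <- match.arg(kind)
  if (length(a) == 0L || length(b) == 0L) stop_ilam("empty group")
  if (kind == "ranksum") {
    res <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                               correct = TRUE))
    list(statistic = unname(res$statistic), p_value = min(1, res$p.value))
  } else {
    if (length(a) != 2L || length(b) != 2L) {
      stop_ilam("fisher needs a 2x2 table")
    }
    tab <- rbind(a, b)
    res <- stats::fisher.test(tab)
    list(statistic = unname(res$estimate), p_value = res$p.value)
  }
}

#' Full validation report for DZ-vs-SC classification
#'
#' Confusion metrics of DZ presence against slow-conduction truth, plus the
#' ROC/AUC of isochrones/cm and the Spearman correlation between
#' isochrones/cm and CV.
#'
#' @param table data.frame with columns `dz`, `sc`, `isochrones_per_cm`,
#'   `cv_m_s` (one row per isthmus, e.g. from [isthmus_table()]).
#' @param seed seed for the permutation p-value.
#' @return a `classification_report` with `auc` and `rho` filled.
#' @export
validation_report <- function(table, seed = 1) {
  rep <- confusion_metrics(table$dz, table$sc)
  if (length(unique(table$sc)) == 2L) {
    rep$auc <- roc_auc(table$isochrones_per_cm, table$sc)$auc
  }
  sp <- spearman_rho(table$isochrones_per_cm, table$cv_m_s, seed = seed)
  rep$rho <- sp$rho
  rep$rho_p_value <- sp$p_value
  rep
}
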