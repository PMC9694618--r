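#' Empirical ROC curve
#'
#' Decision rule: with `positive_high = TRUE` (the default), a score greater
#' than or equal to the threshold predicts infection. Candidate thresholds
#' are the distinct observed scores plus a sentinel above the maximum (the
#' "predict nobody" operating point), so the curve starts at (0, 0) and ends
#' at (1, 1). The AUC is computed by trapezoidal integration, which for this
#' construction equals the tie-corrected rank statistic
#' U / (n_pos * n_neg) -- the probability that a random positive outscores a
#' random negative, ties counting one half.
#'
#' @param scores numeric vector of marker values.
#' @param labels binary vector (1 = documented infection, the positive
#'   class), same length as `scores`.
#' @param positive_high if `FALSE`, low scores predict infection (rule
#'   `score <= threshold`); the AUC maps to `1 - AUC` of the default rule.
#' @param marker name carried on the curve for reporting.
#' @return object of class `roc_curve`: `thresholds` (most extreme first),
#'   `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`, `positive_high`, `marker`.
#' @export
compute_roc <- function(scores, labels, positive_high = TRUE,
                        marker = "score") {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  stopifnot(all(is.finite(scores)), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present (AUC undefined)", call. = FALSE)
  }
  s <- if (positive_high) scores else -scores
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]
  pos <- labels[ord] == 1
  last <- cumsum(rle(ss)$lengths)       # last index of each distinct value
  tp <- cumsum(pos)[last]               # counts for rule s >= thr, thr desc
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thresholds <- c(Inf, ss[last])
  if (!positive_high) thresholds <- -thresholds
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(marker = marker, thresholds = thresholds, fpr = fpr,
                 tpr = tpr, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 positive_high = positive_high),
            class = "roc_curve")
}

#' Pairwise-counting AUC
#'
#' Brute-force rank interpretation of the AUC:
#' `(#\{pos > neg\} + 0.5 * #\{pos = neg\}) / (n_pos * n_neg)` over all
#' positive-negative score pairs. An independent route to the same quantity
#' as the trapezoidal integral of [compute_roc()]; quadratic in n, intended
#' for verification at small to moderate sizes.
#'
#' @inheritParams compute_roc
#' @return the AUC as a single number.
#' @export
auc_pairwise <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

#' Select the Youden-optimal cut-off
#'
#' Scans the curve's observed thresholds and reports the one maximizing
#' Youden's J = sensitivity + specificity - 1. Ties are broken in favour of
#' higher sensitivity (a missed infection being the costly error in this
#' setting), then lower threshold. The cut-off is reported as an observed
#' score value, not an interpolated midpoint.
#'
#' @param curve a `roc_curve`.
#' @return object of class `cutoff_performance`: `marker`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
select_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  j <- sens + spec - 1
  ord <- order(-j, -sens,
               if (curve$positive_high) curve$thresholds else -curve$thresholds)
  k <- ord[1]
  structure(list(marker = curve$marker, auc = curve$auc,
                 cutoff = curve$thresholds[k],
                 sensitivity = sens[k], specificity = spec[k],
                 youden_j = j[k]),
            class = "cutoff_performance")
}

#' @export
print.cutoff_performance <- function(x, ...) {
  cat(sprintf("%s: AUC = %.3f, cut-off = %g, sensitivity = %.2f, specificity = %.2f (J = %.2f)\n",
              x$marker, x$auc, x$cutoff, x$sensitivity, x$specificity,
              x$youden_j))
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve for %s: AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$marker, x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' ROC performance of the three biomarkers and the composite index
#'
#' Runs [compute_roc()] and [select_cutoff()] for PCT, CRP, IL-6 and the
#' CIndex, with documented infection as the positive class, always in that
#' fixed order.
#'
#' @param cohort a [cohort] containing both classes.
#' @param cindex per-episode index values aligned with the cohort; computed
#'   from the cohort's own means when omitted.
#' @return list with `performance` (data frame of four rows:
#'   `marker, auc, cutoff, sensitivity, specificity, youden_j`) and
#'   `curves` (named list of `roc_curve` objects).
#' @export
analyze_markers <- function(cohort, cindex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cindex)) cindex <- compute_cindex(cohort)$cindex
  stopifnot(length(cindex) == nrow(cohort))
  scores <- list(pct = cohort$pct, crp = cohort$crp, il6 = cohort$il6,
                 cindex = cindex)
  curves <- lapply(names(scores), function(m) {
    compute_roc(scores[[m]], cohort$infection, marker = m)
  })
  names(curves) <- names(scores)
  perf <- lapply(curves, select_cutoff)
  performance <- do.call(rbind, lapply(perf, function(p) {
    data.frame(marker = p$marker, auc = p$auc, cutoff = p$cutoff,
               sensitivity = p$sensitivity, specificity = p$specificity,
               youden_j = p$youden_j, stringsAsFactors = FALSE)
  }))
  rownames(performance) <- NULL
  list(performance = performance, curves = curves)
}
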