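# Independent oracles used across test files.  Each is a deliberately
# different route to the quantity it checks, kept simple at small n.

# Two-sided rank-sum p by explicit enumeration of every way to assign the
# group-a labels over the pooled values, using the rank-sum W (not U) as the
# statistic.  Valid with ties (conditional on the observed values).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  center <- n1 * (length(pooled) + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  extreme <- 0L
  for (k in seq_len(ncol(sets))) {
    w <- sum(r[sets[, k]])
    if (abs(w - center) >= abs(w_obs - center) - 1e-9) extreme <- extreme + 1L
  }
  extreme / ncol(sets)
}

# AUC as an explicit double loop over positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force Youden scan over every curve operating point, replaying the
# tie-break (max J, then max sensitivity, then min threshold) by filtering.
oracle_best_cutoff <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- j <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- scores >= thr[k]
    sens[k] <- sum(pred & labels == 1) / sum(labels == 1)
    spec[k] <- sum(!pred & labels == 0) / sum(labels == 0)
    j[k] <- sens[k] + spec[k] - 1
  }
  keep <- which(j == max(j))
  keep <- keep[sens[keep] == max(sens[keep])]
  keep <- keep[which.min(thr[keep])]
  list(cutoff = thr[keep], sensitivity = sens[keep], specificity = spec[keep],
       youden_j = j[keep])
}

# Closed-form AUC for two lognormal groups (positive group 1).
lognormal_auc <- function(p0, p1) {
  stats::pnorm((p1$mu - p0$mu) / sqrt(p0$sigma^2 + p1$sigma^2))
}

# Small valid cohort data frame for fixture use.
make_cohort_df <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    episode_id = sprintf("ep-%03d", seq_len(n)),
    patient_id = sprintf("pt-%02d", sample(ceiling(n / 2), n, replace = TRUE)),
    infection = rep_len(c(0, 1), n),
    pct = round(stats::rlnorm(n, 0, 1), 4),
    crp = round(stats::rlnorm(n, 2, 0.7), 4),
    il6 = round(stats::rlnorm(n, 4, 1), 4),
    stringsAsFactors = FALSE
  )
}

# Random 0/1 labels guaranteed to contain both classes.
rbinom_both <- function(n) {
  stopifnot(n >= 2)
  l <- stats::rbinom(n, 1, 0.4)
  l[sample(n, 2)] <- c(0, 1)
  l
}
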