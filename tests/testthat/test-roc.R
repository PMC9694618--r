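test_that("compute_roc handles the canonical small cases", {
  perfect <- compute_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1.0)
  inverted <- compute_roc(c(4, 3, 2, 1), c(0, 0, 1, 1))
  expect_equal(inverted$auc, 0.0)
  # 4 positive-negative pairs: 3 wins + 1 tie counted half -> 3.5/4
  tied <- compute_roc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(tied$auc, 0.875)
  expect_equal(auc_pairwise(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(auc_pairwise(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
})

test_that("curves are monotone from (0,0) to (1,1) with a +Inf sentinel", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    scores <- sample(stats::rlnorm(n %/% 2 + 1), n, replace = TRUE)
    labels <- rbinom_both(n)
    cv <- compute_roc(scores, labels)
    expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[length(cv$fpr)], 1)
    expect_equal(cv$tpr[length(cv$tpr)], 1)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_identical(cv$thresholds[1], Inf)
    expect_equal(length(cv$thresholds), length(unique(scores)) + 1)
  }
})

test_that("trapezoidal AUC equals the pairwise rank statistic on 200 random instances", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(5:100, 1)
    with_ties <- rep %% 2 == 0
    scores <- if (with_ties) {
      sample(round(stats::rlnorm(n), 1), n, replace = TRUE)
    } else {
      stats::rnorm(n)
    }
    labels <- rbinom_both(n)
    cv <- compute_roc(scores, labels)
    expect_equal(cv$auc, auc_pairwise(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with loop and pROC oracles on random instances", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (rep in 1:10) {
    n <- 40
    scores <- round(stats::rlnorm(n), 1)
    labels <- rbinom_both(n)
    cv <- compute_roc(scores, labels)
    expect_equal(cv$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                               direction = "<", quiet = TRUE)))
    expect_equal(cv$auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under increasing transforms and flips under reversal", {
  set.seed(23)
  scores <- stats::rlnorm(30)
  labels <- rbinom_both(30)
  base <- compute_roc(scores, labels)$auc
  expect_equal(compute_roc(log(scores), labels)$auc, base, tolerance = 1e-12)
  expect_equal(compute_roc(scores^2, labels)$auc, base, tolerance = 1e-12)
  expect_equal(compute_roc(scores, labels, positive_high = FALSE)$auc,
               1 - base, tolerance = 1e-12)
})

test_that("select_cutoff maximizes Youden's J with the documented tie-break", {
  perfect <- select_cutoff(compute_roc(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(perfect$cutoff, 3)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$youden_j, 1)

  set.seed(31)
  for (rep in 1:30) {
    n <- 30
    scores <- sample(round(stats::rlnorm(n), 1), n, replace = TRUE)
    labels <- rbinom_both(n)
    got <- select_cutoff(compute_roc(scores, labels))
    want <- oracle_best_cutoff(scores, labels)
    expect_equal(got$youden_j, want$youden_j, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("reported sensitivity/specificity recompute from the confusion matrix", {
  set.seed(37)
  for (rep in 1:20) {
    scores <- round(stats::rlnorm(40), 1)
    labels <- rbinom_both(40)
    perf <- select_cutoff(compute_roc(scores, labels))
    pred <- as.numeric(scores >= perf$cutoff)
    expect_equal(perf$sensitivity,
                 sum(pred == 1 & labels == 1) / sum(labels == 1))
    expect_equal(perf$specificity,
                 sum(pred == 0 & labels == 0) / sum(labels == 0))
    expect_equal(perf$youden_j, perf$sensitivity + perf$specificity - 1)
  }
})

test_that("ties in every score leave no discrimination", {
  cv <- compute_roc(rep(3.2, 10), rep_len(c(0, 1), 10))
  expect_equal(cv$auc, 0.5)
  perf <- select_cutoff(cv)
  expect_equal(perf$youden_j, 0)
})

test_that("single-class labels are rejected", {
  expect_error(compute_roc(1:4, rep(1, 4)), "both classes")
  expect_error(compute_roc(1:4, rep(0, 4)), "both classes")
  expect_error(auc_pairwise(1:4, rep(1, 4)), "both classes")
  expect_error(compute_roc(1:4, c(0, 1, 1)), "equal length")
})

test_that("analyze_markers reports the four markers in fixed order", {
  co <- as_cohort(make_cohort_df(n = 24, seed = 13))
  out <- analyze_markers(co)
  expect_identical(out$performance$marker, c("pct", "crp", "il6", "cindex"))
  expect_equal(nrow(out$performance), 4)

  # with pct = crp = 0 the index is a positive multiple of il6, so the two
  # ROC rows coincide (monotone-transform invariance)
  df <- make_cohort_df(n = 16, seed = 19)
  df$pct <- 0
  df$crp <- 0
  df$il6 <- df$il6 + 0.1               # keep il6 mean positive
  expect_error(analyze_markers(as_cohort(df)), "mean")  # pct mean is 0
  # supply external-mean-normalized index directly instead
  co0 <- as_cohort(df)
  ci <- compute_cindex(co0, external_reference_means(1, 1, mean(df$il6)))
  out0 <- analyze_markers(co0, ci$cindex)
  expect_equal(out0$performance$auc[out0$performance$marker == "cindex"],
               out0$performance$auc[out0$performance$marker == "il6"],
               tolerance = 1e-12)
})
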