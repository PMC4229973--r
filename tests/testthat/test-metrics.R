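test_that("AUC hits the definitional anchors", {
  # perfect separation
  roc1 <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                    c("positive", "positive", "negative", "negative"))
  expect_equal(roc1$auc, 1.0)
  # perfectly wrong
  roc0 <- roc_curve(c(0.1, 0.9), c("positive", "negative"))
  expect_equal(roc0$auc, 0.0)
  expect_error(roc_curve(1:3, rep("positive", 3)), "both classes")
})

test_that("trapezoidal AUC equals the concordant-pair statistic with ties", {
  set.seed(3)
  for (trial in 1:30) {
    n <- sample(10:200, 1)
    labels <- sample(c("positive", "negative"), n, TRUE)
    labels[1:2] <- c("positive", "negative")
    scores <- round(runif(n), sample(1:2, 1))  # coarse rounding forces ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12, info = paste("trial", trial))
    # curve is monotone in both coordinates
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- runif(300)
  labels <- ifelse(runif(300) < plogis(6 * (scores - 0.5)),
                   "positive", "negative")
  labels[1:2] <- c("positive", "negative")
  r <- roc_curve(scores, labels)
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             levels = c("negative", "positive"),
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("partial AUC is normalized by its FPR cutoff", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c("positive", "positive", "positive",
              "negative", "negative", "negative")
  r <- roc_curve(scores, labels)
  expect_equal(pauc(r, 1), r$auc)
  for (x in c(0.005, 0.1, 0.5)) expect_equal(pauc(r, x), 1.0)  # perfect

  # hand case: one positive scored below one negative
  r2 <- roc_curve(c(0.9, 0.5, 0.7), c("positive", "positive", "negative"))
  # curve: (0,0.5) at fpr 0, then (1, 0.5), (1, 1): area over [0, 0.5] is
  # 0.5 * 0.25... full auc = 0.5; pauc(0.5) = (0.5*0.5)/0.5
  expect_equal(pauc(r2, 0.5), 0.5)
  expect_equal(pauc(r2, 1), r2$auc)
})

test_that("MCC follows the formula with the zero-denominator convention", {
  expect_equal(mcc(c(TP = 10, FP = 0, TN = 10, FN = 0)), 1)
  expect_equal(mcc(c(TP = 0, FP = 10, TN = 0, FN = 10)), -1)
  expect_equal(mcc(c(TP = 25, FP = 25, TN = 25, FN = 25)), 0)
  expect_equal(mcc(c(TP = 0, FP = 0, TN = 50, FN = 10)), 0)  # degenerate
  # large counts must not overflow integer arithmetic
  big <- c(TP = 1e5, FP = 2e6, TN = 5e7, FN = 1e5)
  expect_true(is.finite(mcc(big)))
})

test_that("F-measure matches precision/recall identities and printed case", {
  # precision == recall == p -> F == p
  expect_equal(f_measure(c(TP = 30, FP = 70, TN = 0, FN = 70)), 0.3)
  expect_equal(f_measure(c(TP = 0, FP = 5, TN = 5, FN = 5)), 0)
  # a published benchmark row: TP 143, FP 5026, FN 4152 -> F ~ 0.030
  expect_equal(f_measure(c(TP = 143, FP = 5026, TN = 1766423, FN = 4152)),
               0.030, tolerance = 1e-2)
  cc <- c(TP = 143, FP = 5026, TN = 1766423, FN = 4152)
  expect_equal(143 / (143 + 5026), 0.0277, tolerance = 1e-2)
  expect_equal(143 / (143 + 4152), 0.0333, tolerance = 1e-2)
})

test_that("confusion counts use the >= threshold and partition all pairs", {
  scores <- c(0.9, 0.5, 0.5, 0.1)
  labels <- c("positive", "negative", "positive", "negative")
  cc <- confusion_counts(scores, labels, 0.5)
  expect_equal(unname(cc), c(2, 1, 1, 0))
  expect_equal(sum(cc), length(scores))
})

test_that("threshold selection maximizes F over distinct scores", {
  set.seed(6)
  for (trial in 1:20) {
    n <- sample(8:60, 1)
    scores <- round(runif(n), 1)
    labels <- sample(c("positive", "negative"), n, TRUE)
    labels[1:2] <- c("positive", "negative")
    theta <- select_threshold(scores, labels)
    # exhaustive scan oracle
    cand <- sort(unique(scores))
    f <- vapply(cand, function(t)
      f_measure(confusion_counts(scores, labels, t)), numeric(1))
    expect_equal(theta, min(cand[f == max(f)]), info = paste("trial", trial))
  }
  expect_equal(select_threshold(rep(0.4, 5),
                                c("positive", "negative", "positive",
                                  "negative", "positive")), 0.4)
})

test_that("equal-variance t-test handles degenerate and toy inputs", {
  expect_equal(compare_auc_ttest(c(0.7, 0.7, 0.7), c(0.7, 0.7, 0.7)), 1)
  expect_equal(compare_auc_ttest(c(0.7, 0.7), c(0.8, 0.8)), 0)
  a <- c(0.70, 0.72, 0.74)
  b <- c(0.80, 0.82, 0.84)
  # textbook pooled-variance t on a 3+3 toy
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(compare_auc_ttest(a, b),
               2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  expect_equal(compare_auc_ttest(a, b), compare_auc_ttest(b, a))
  expect_lt(compare_auc_ttest(a, b), 0.01)
})
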