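test_that("confusion counts match brute-force enumeration", {
  # all 2^4 prediction patterns over 4 items vs direct counting
  truth <- c("pregnancy", "pregnancy", "non_pregnancy", "non_pregnancy")
  lev <- c("pregnancy", "non_pregnancy")
  for (mask in 0:15) {
    pred <- lev[1 + as.integer(intToBits(mask))[1:4]]
    cm <- confusion(pred, truth)
    for (t in lev) for (p in lev) {
      expect_equal(cm[t, p], sum(truth == t & pred == p))
    }
    expect_equal(sum(cm), 4)
  }
  # perfect agreement is diagonal
  cm <- confusion(truth, truth)
  expect_equal(cm["pregnancy", "non_pregnancy"] +
               cm["non_pregnancy", "pregnancy"], 0)
  expect_error(confusion(c("maybe", "pregnancy"), truth[1:2]), "label")
})

test_that("a 95-prediction fixture reproduces the printed confusion matrix", {
  # 31 true positives, 14 misses, 13 false alarms, 37 true negatives
  truth <- c(rep("pregnancy", 45), rep("non_pregnancy", 50))
  pred <- c(rep("pregnancy", 31), rep("non_pregnancy", 14),
            rep("pregnancy", 13), rep("non_pregnancy", 37))
  cm <- confusion(pred, truth)
  expect_equal(unclass(cm), matrix(c(31L, 13L, 14L, 37L), 2,
               dimnames = list(true = c("pregnancy", "non_pregnancy"),
                               predicted = c("pregnancy", "non_pregnancy"))),
               ignore_attr = TRUE)
  r <- eval_metrics(cm)
  expect_equal(round(r$per_class$precision, 2), c(0.70, 0.73))
  expect_equal(round(r$per_class$recall, 2), c(0.69, 0.74))
  expect_equal(round(r$per_class$f1, 2), c(0.70, 0.73))
  expect_equal(round(r$per_class$accuracy_pct, 2), c(68.89, 74.00))
  expect_equal(r$correct, 68)
  expect_equal(r$total, 95)
  expect_equal(r$overall_accuracy, 68 / 95)
})

test_that("metric arithmetic holds on degenerate and tiny matrices", {
  perfect <- matrix(c(10, 0, 0, 10), 2)
  r <- eval_metrics(perfect)
  expect_equal(r$per_class$precision, c(1, 1))
  expect_equal(r$per_class$f1, c(1, 1))
  expect_equal(r$overall_accuracy, 1)
  r2 <- eval_metrics(matrix(c(2, 1, 1, 2), 2))
  expect_equal(r2$per_class$precision, c(2 / 3, 2 / 3))
  expect_equal(r2$per_class$recall, c(2 / 3, 2 / 3))
  expect_equal(r2$overall_accuracy, 4 / 6)
  # overall accuracy = frequency-weighted mean of recalls
  cm <- matrix(c(31, 13, 14, 37), 2)
  r3 <- eval_metrics(cm)
  w <- rowSums(cm) / sum(cm)
  expect_equal(r3$overall_accuracy, sum(w * r3$per_class$recall))
  # one class never predicted: precision undefined there
  r4 <- eval_metrics(matrix(c(3, 2, 0, 0), 2))
  expect_true(is.na(r4$per_class$precision[2]))
  expect_error(eval_metrics(matrix(0, 2, 2)), "empty")
})

test_that("trapezoid AUC equals the Mann-Whitney pair-count statistic", {
  set.seed(91)
  for (rep in 1:25) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    truth <- c(rep("pregnancy", n1), rep("non_pregnancy", n0))
    scores <- round(rnorm(n1 + n0), 1)  # coarse rounding forces ties
    ra <- roc_auc(scores, truth)
    pos <- scores[truth == "pregnancy"]; neg <- scores[truth != "pregnancy"]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(ra$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC is 1 for separated scores and invariant under monotone maps", {
  truth <- c(rep("pregnancy", 10), rep("non_pregnancy", 10))
  scores <- c(rnorm(10, 5), rnorm(10, -5))
  expect_equal(roc_auc(scores, truth)$auc, 1)
  set.seed(92)
  s <- rnorm(40); t2 <- sample(truth, 40, replace = TRUE)
  t2[1:2] <- c("pregnancy", "non_pregnancy")  # ensure both classes
  a1 <- roc_auc(s, t2)$auc
  expect_equal(roc_auc(exp(s), t2)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(100 + 3 * s, t2)$auc, a1, tolerance = 1e-12)
  expect_error(roc_auc(rnorm(5), rep("pregnancy", 5)), "undefined AUC")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(93)
  truth <- sample(c("pregnancy", "non_pregnancy"), 2000, replace = TRUE)
  auc <- roc_auc(rnorm(2000), truth)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("ROC and AUC agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(94)
  truth <- c(rep("pregnancy", 30), rep("non_pregnancy", 30))
  scores <- rnorm(60) + rep(c(0.8, 0), c(30, 30))
  ours <- roc_auc(scores, truth)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("non_pregnancy", "pregnancy")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})
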