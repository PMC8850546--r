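test_that("confusion metrics hit the textbook values on a known table", {
  # TP=8, FN=2, TN=15, FP=5 at threshold 0.5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.1, 15), rep(0.9, 5))
  labels <- rep(c("positive", "negative"), c(10, 20))
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(8, 2, 15, 5))
  expect_equal(m$TPR, 0.8)
  expect_equal(m$TNR, 0.75)
  expect_equal(m$ACC, 23 / 30)
  expect_equal(m$MCC, (8 * 15 - 5 * 2) / sqrt(10 * 20 * 13 * 17))
})

test_that("perfect and inverted classifiers reach the metric endpoints", {
  labels <- rep(c("positive", "negative"), each = 10)
  perfect <- c(rep(1, 10), rep(0, 10))
  m <- confusion_metrics(perfect, labels, 0.5)
  expect_equal(c(m$TPR, m$TNR, m$ACC, m$MCC), c(1, 1, 1, 1))
  expect_equal(c(m$FNR, m$MCR, m$FPR), c(0, 0, 0))
  inv <- confusion_metrics(1 - perfect, labels, 0.5)
  expect_equal(inv$MCC, -1)
  expect_error(confusion_metrics(perfect, rep("positive", 20), 0.5),
               "both classes")
})

test_that("metric identities hold on random score/label sets", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    scores <- runif(n)
    labels <- factor(c("positive", "negative",
                       sample(c("positive", "negative"), n - 2, TRUE)),
                     levels = c("negative", "positive"))
    m <- confusion_metrics(scores, labels, runif(1))
    expect_equal(m$TPR + m$FNR, 1)
    expect_equal(m$TNR + m$FPR, 1)
    expect_equal(m$ACC + m$MCR, 1)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("fixed-FPR threshold maximizes TPR without exceeding the cap", {
  set.seed(67)
  # 10 negatives with distinct scores, cap 0.20 -> at most 2 above threshold
  neg <- sample(seq(0.05, 0.95, by = 0.1))
  pos <- runif(10)
  scores <- c(pos, neg)
  labels <- rep(c("positive", "negative"), each = 10)
  thr <- threshold_at_fpr(scores, labels, 0.20)
  expect_lte(sum(neg > thr), 2)
  expect_equal(sum(neg > thr), 2)   # smallest threshold under the cap
  # perfect separation: returned operating point has FPR 0
  thr2 <- threshold_at_fpr(c(rep(1, 5), rep(0, 5)),
                           rep(c("positive", "negative"), each = 5), 0.20)
  expect_equal(mean(rep(0, 5) > thr2), 0)
  # cap 1.0 admits everything: threshold below the minimum score, TPR = 1
  thr3 <- threshold_at_fpr(scores, labels, 1.0)
  expect_lt(thr3, min(scores))
  expect_equal(confusion_metrics(scores, labels, thr3)$TPR, 1)
  expect_error(threshold_at_fpr(scores, labels, 0), "fpr_cap")
  expect_error(threshold_at_fpr(scores, labels, 1.5), "fpr_cap")
})

test_that("tied scores are grouped so the cap is never exceeded", {
  # 5 negatives tied at 0.8: admitting the tie group would give FPR 0.5
  scores <- c(rep(0.9, 3), rep(0.8, 2), rep(0.8, 5), rep(0.1, 5))
  labels <- c(rep("positive", 5), rep("negative", 10))
  thr <- threshold_at_fpr(scores, labels, 0.20)
  m <- confusion_metrics(scores, labels, thr)
  expect_lte(m$FPR, 0.20)
})

test_that("ROC endpoints, chance level and the pairwise AUC oracle agree", {
  labels <- rep(c("positive", "negative"), each = 50)
  perfect <- c(rep(1, 50), rep(0, 50))
  r <- roc_auc_pauc(perfect, labels, 0.20)
  expect_equal(r$auc, 1)
  expect_equal(r$pauc, 0.20)
  set.seed(71)
  chance <- roc_auc_pauc(runif(4000), rep(c("positive", "negative"), 2000),
                         0.20)
  expect_lt(abs(chance$auc - 0.5), 0.03)
  expect_lt(abs(chance$pauc - 0.02), 0.01)
  # trapezoid AUC equals the Mann-Whitney pairwise statistic
  for (i in 1:40) {
    n <- sample(10:40, 1)
    scores <- round(runif(n), 1)   # ties included
    labels <- factor(c("positive", "negative",
                       sample(c("positive", "negative"), n - 2, TRUE)),
                     levels = c("negative", "positive"))
    expect_equal(roc_auc_pauc(scores, labels, 1)$auc,
                 auc_pairwise(scores, labels), tolerance = 1e-12)
  }
})

test_that("partial AUC reduces to AUC at cap 1 and is bounded by the cap", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- runif(n)
    labels <- factor(c("positive", "negative",
                       sample(c("positive", "negative"), n - 2, TRUE)),
                     levels = c("negative", "positive"))
    r1 <- roc_auc_pauc(scores, labels, 1)
    expect_equal(r1$pauc, r1$auc, tolerance = 1e-12)
    r02 <- roc_auc_pauc(scores, labels, 0.20)
    expect_lte(r02$pauc, 0.20 + 1e-12)
    expect_lte(r02$pauc, r1$auc)
  }
})

test_that("evaluation report at the capped threshold keeps TNR >= 1 - cap", {
  set.seed(79)
  for (i in 1:10) {
    scores <- runif(60)
    labels <- rep(c("positive", "negative"), each = 30)
    rep <- evaluate_scores(scores, labels, 0.20)
    expect_gte(rep$TNR, 0.80 - 1e-12)
    expect_lte(rep$FPR, 0.20 + 1e-12)
  }
})

test_that("CV folds partition the window set with stratified ratios", {
  ws <- random_window_set(20, 40, seed = 83)
  folds <- phosfuse:::stratified_folds(ws$label, 5, seed = 1)
  expect_length(folds, 60)
  expect_setequal(folds, 1:5)
  for (i in 1:5) {
    expect_equal(sum(folds == i & ws$label == "positive"), 4)
    expect_equal(sum(folds == i & ws$label == "negative"), 8)
  }
  # deterministic per seed
  expect_identical(folds, phosfuse:::stratified_folds(ws$label, 5, seed = 1))
})

test_that("k-fold CV refits the pipeline per fold and returns k reports", {
  ws <- random_window_set(10, 20, seed = 89)
  cv <- kfold_cv(ws, k = 5, seed = 3, family = "RF", ntree = 50,
                 top_n = c(CKSAAP = 60L, BINARY = 40L))
  expect_length(cv$folds, 5)
  expect_equal(nrow(cv$summary), 9)
  expect_true(all(is.finite(cv$summary$mean)))
  au <- cv_metric(cv, "auc")
  expect_true(au[["mean"]] >= 0 && au[["mean"]] <= 1)
  expect_error(kfold_cv(random_window_set(3, 20, seed = 1), k = 5),
               "needs >= 5")
})
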