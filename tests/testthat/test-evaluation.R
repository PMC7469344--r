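test_that("confusion metrics match hand computation and the formula oracle", {
  r <- confusionMetrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unlist(r[c("Acc", "Sen", "Spe", "Pre", "MCC")]),
               c(Acc = 1, Sen = 1, Spe = 1, Pre = 1, MCC = 1))

  r <- confusionMetrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
  expect_equal(r$Acc, 0.7)
  expect_equal(r$Sen, 0.8)
  expect_equal(r$Spe, 0.6)
  expect_equal(r$Pre, 2 / 3)
  expect_equal(r$MCC, (8 * 6 - 4 * 2) / sqrt(10 * 12 * 8 * 10))

  r <- confusionMetrics(list(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(r$Pre, 0)
  expect_true("Pre" %in% r$degenerate)
  expect_equal(r$MCC, 0)
  expect_error(confusionMetrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")

  set.seed(600)
  for (i in 1:1000) {
    cts <- as.list(stats::setNames(sample(0:30, 4, TRUE), c("TP", "FP", "TN", "FN")))
    if (Reduce(`+`, cts) == 0) next
    got <- confusionMetrics(cts)
    want <- oracleMetrics(cts$TP, cts$FP, cts$TN, cts$FN)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the concordant-pair probability", {
  expect_equal(rocCurve(c(0.9, 0.8, 0.3), c(1, 1, 0))$auc, 1)
  expect_equal(rocCurve(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 0, 1))$auc, 0.75)
  expect_equal(rocCurve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(rocCurve(1:3, c(1, 1, 1)), "both classes")

  set.seed(71)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    roc <- rocCurve(scores, labels)
    expect_equal(roc$auc, oracleAUC(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
  }
})

test_that("ROC agrees with an independent library implementation", {
  set.seed(81)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  expect_equal(rocCurve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("hold-out evaluation is stratified, reproducible and sane", {
  b <- tinyBundle()
  ds <- buildDataset(b, seed = 2)
  cfg <- tinyConfig()
  r1 <- holdoutEval(ds, cfg, seed = 3)
  r2 <- holdoutEval(ds, cfg, seed = 3)
  expect_identical(r1$scores, r2$scores)
  expect_equal(sum(r1$labels == 1), round(0.2 * sum(ds$pairs$label == 1)))
  expect_equal(length(r1$labels), length(r1$scores))
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  r3 <- holdoutEval(ds, cfg, seed = 4)
  expect_false(identical(r1$scores, r3$scores))
})

test_that("k-fold folds are disjoint, exhaustive and averaged", {
  b <- tinyBundle()
  ds <- buildDataset(b, seed = 2)
  cv <- kfoldEval(ds, tinyConfig(), k = 5, seed = 1)
  expect_length(cv$folds, 5)
  n <- nrow(ds$pairs)
  expect_equal(sort(unique(cv$pooled$foldId)), 1:5)
  expect_length(cv$pooled$scores, n)
  sizes <- table(cv$pooled$foldId)
  expect_lte(max(sizes) - min(sizes), 2)
  # stratification: class ratio within one sample per fold
  for (f in 1:5) {
    lab <- ds$pairs$label[cv$pooled$foldId == f]
    expect_lte(abs(sum(lab == 1) - sum(lab == 0)), 2)
  }
  expect_equal(unname(cv$mean["auc"]),
               mean(vapply(cv$folds, `[[`, numeric(1), "auc")))
})

test_that("LOOCV pools one score per sample", {
  b <- tinyBundle()
  im <- b@interaction
  small <- buildDataset(im, b@hierarchy, nNegatives = 10, seed = 2)
  keepPos <- which(small$pairs$label == 1)[1:10]
  small$pairs <- small$pairs[c(keepPos, which(small$pairs$label == 0)), ]
  cfg <- tinyConfig(mode = "paper_faithful")
  r <- loocvEval(small, cfg)
  expect_length(r$scores, 20)
  r2 <- loocvEval(small, cfg)
  expect_identical(r$scores, r2$scores)
})

test_that("repeated-F1 comparison flags zero variance and detects separation", {
  b <- tinyBundle()
  ds <- buildDataset(b, seed = 2)
  cfg <- tinyConfig(mode = "paper_faithful")
  same <- repeatedF1Test(ds, cfg, cfg, nRep = 5, seed = 10)
  expect_true(same$zeroVariance)
  expect_true(is.na(same$pValue))
  expect_equal(same$meanA, same$meanB)
  expect_warning(repeatedF1Test(ds, cfg, cfg, nRep = 2, seed = 1), "low power")
})

test_that("candidate ranking orders all lncRNAs with deterministic ties", {
  b <- tinyBundle()
  ds <- buildDataset(b, seed = 2)
  cfg <- tinyConfig()
  rk <- rankCandidates("disease001", ds, cfg)
  expect_equal(nrow(rk), length(lncRNANames(b)))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 0))
  ties <- which(duplicated(rk$score) | duplicated(rk$score, fromLast = TRUE))
  if (length(ties)) {
    for (s in unique(rk$score[ties]))
      expect_false(is.unsorted(rk$index[rk$score == s]))
  }
  expect_error(rankCandidates("nonexistent", ds, cfg), "unknown disease")
})
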