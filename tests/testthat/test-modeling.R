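test_that("the metric suite reproduces the binary hand computation", {
  # per-class counts for 'pos': TP = 3, FP = 1, FN = 1, TN = 5
  yTrue <- c(rep("pos", 4), rep("neg", 6))
  yPred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  rep1 <- computeMetrics(yTrue, yPred)
  pc <- rep1@perClass
  expect_equal(pc$precision[pc$class == "pos"], 0.75)
  expect_equal(pc$recall[pc$class == "pos"], 0.75)
  expect_equal(pc$f1[pc$class == "pos"], 0.75)
  expect_equal(rep1@accuracy, 0.8)
})

test_that("perfect and degenerate predictions hit the metric extremes", {
  y <- rep(c("1", "2", "3"), each = 4)
  scores <- matrix(0, 12, 3, dimnames = list(NULL, c("1", "2", "3")))
  scores[cbind(seq_len(12), as.integer(y))] <- 1
  repP <- computeMetrics(y, y, scores)
  expect_equal(repP@accuracy, 1)
  expect_equal(repP@f1, 1)
  expect_equal(repP@mAP, 1)
  yb <- rep(c("a", "b"), each = 3)
  repW <- computeMetrics(yb, rev(yb))
  expect_equal(repW@accuracy, 0)
})

test_that("confusion rows sum to true counts and accuracy is the trace share", {
  withr::with_seed(21, {
    y <- sample(1:4, 60, replace = TRUE)
    p <- sample(1:4, 60, replace = TRUE)
  })
  r <- computeMetrics(y, p)
  expect_equal(unname(rowSums(r@confusion)), unname(c(table(factor(y, 1:4)))))
  expect_equal(r@accuracy, sum(diag(r@confusion)) / 60)
})

test_that("macro F1 is invariant to class relabeling", {
  withr::with_seed(22, {
    y <- sample(c("a", "b", "c"), 50, replace = TRUE)
    p <- sample(c("a", "b", "c"), 50, replace = TRUE)
  })
  perm <- c(a = "c", b = "a", c = "b")
  f1a <- computeMetrics(y, p)@f1
  f1b <- computeMetrics(unname(perm[y]), unname(perm[p]))@f1
  expect_equal(f1a, f1b)
})

test_that("AP by recall increments equals the brute-force PR computation", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(5:8, 1)
      isPos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(isPos)) isPos[1] <- TRUE
      s <- sample(seq_len(100), n)  # distinct scores
    })
    y <- ifelse(isPos, "p", "n")
    scores <- cbind(p = s / 100, n = 1 - s / 100)
    r <- computeMetrics(y, y, scores)
    expect_equal(r@perClass$AP[r@perClass$class == "p"],
                 bruteAP(isPos, s), tolerance = 1e-12,
                 info = sprintf("seed %d", seed))
  }
})

test_that("variability is the n-1 normalized standard deviation", {
  expect_equal(variability(c(0.9, 0.9, 0.9)), 0)
  expect_equal(variability(c(0.8, 1.0)), 0.1414214, tolerance = 1e-6)
  expect_error(variability(0.5), "at least 2")
})

test_that("classifiers fit separable data and are reproducible", {
  ds <- toyDataset(nPerClass = 20, nClasses = 2, sep = 6)
  for (alg in c("rf", "gbdt", "extratrees", "histgb", "xgb")) {
    mdl <- trainModel(modelSpec(alg, seed = 3), ds)
    pred <- predictGrades(mdl, ds)
    expect_gte(mean(pred$labels == as.character(grades(ds))), 0.99)
    mdl2 <- trainModel(modelSpec(alg, seed = 3), ds)
    expect_identical(predictGrades(mdl2, ds)$prob, pred$prob, info = alg)
  }
  one <- LabeledDataset(matrix(rnorm(10), 5, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        rep("x", 5))
  expect_error(trainModel(modelSpec("rf"), one), "single class")
})

test_that("label-shuffled data score at chance", {
  ds <- toyDataset(nPerClass = 20, nClasses = 3, sep = 3)
  accs <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, yShuf <- sample(as.character(grades(ds))))
    dsS <- LabeledDataset(features(ds), yShuf)
    sp <- stratifiedSplit(dsS, 0.75, seed = s)
    mdl <- trainModel(modelSpec("rf", seed = s), sp$train)
    mean(predictGrades(mdl, sp$test)$labels ==
           as.character(grades(sp$test)))
  }, 0)
  # mean accuracy within 3 standard errors of 1/3
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * max(se, 0.02))
})

test_that("a 1x1x1 grid equals the directly composed stages", {
  ds <- toyDataset(nPerClass = 18, nClasses = 3, sep = 3)
  g <- runGrid(list(`3` = ds), featureSets = "COR", algorithms = "rf",
               seed = 5)
  expect_equal(nrow(g$table), 1L)
  sp <- stratifiedSplit(ds, 0.8, seed = stageSeed(5, "split"))
  sel <- selectFeatures(sp$train, "COR", seed = stageSeed(5, "select"))
  bal <- smoteBalance(applySelection(sp$train, sel),
                      seed = stageSeed(5, "balance"))
  mdl <- trainModel(modelSpec("rf", seed = stageSeed(5, "train")), bal)
  pred <- predictGrades(mdl, applySelection(sp$test, sel))
  direct <- computeMetrics(grades(applySelection(sp$test, sel)),
                           pred$labels, pred$prob)
  expect_equal(g$table$accuracy, direct@accuracy)
  expect_equal(g$table$mAP, direct@mAP)
})

test_that("the grid enumerates every cell and records failures", {
  ds <- toyDataset(nPerClass = 15, nClasses = 2, sep = 4)
  g <- runGrid(list(`3` = ds), featureSets = c("ALL", "COR"),
               algorithms = c("rf", "gbdt"), seed = 2)
  expect_equal(nrow(g$table), 4L)
  expect_true(all(g$table$status == "ok"))
})

test_that("cross-validation is stratified, deterministic and leakage-safe", {
  ds <- toyDataset(nPerClass = 20, nClasses = 2, sep = 4)
  cv1 <- kfoldCV(modelSpec("rf", seed = 1), ds, k = 5, seed = 9)
  cv2 <- kfoldCV(modelSpec("rf", seed = 1), ds, k = 5, seed = 9)
  expect_identical(cv1$foldAssignment, cv2$foldAssignment)
  expect_equal(cv1$mean, cv2$mean)
  expect_length(cv1$folds, 5)
  # per-fold class balance within one sample
  tab <- table(cv1$foldAssignment, grades(ds))
  expect_true(max(tab) - min(tab) <= 1)
  # synthetic input rejected in leakage-safe mode
  bal <- smoteBalance(ds[c(1:20, 21:30), ], seed = 1)
  expect_error(kfoldCV(modelSpec("rf"), bal, k = 5), "original rows")
  # compatibility mode balances before partitioning instead
  cvc <- kfoldCV(modelSpec("rf", seed = 1), ds[c(1:20, 21:30), ], k = 5,
                 seed = 9, smoteInsideFolds = FALSE)
  expect_length(cvc$folds, 5)
})

test_that("leave-one-out folds have size one", {
  ds <- toyDataset(nPerClass = 2, nClasses = 2, p = 3, sep = 5)
  cv <- kfoldCV(modelSpec("rf", seed = 1), ds, k = 4, seed = 1,
                smoteTarget = 1)
  expect_length(cv$folds, 4)
  expect_true(all(table(cv$foldAssignment) == 1))
  expect_error(kfoldCV(modelSpec("rf"), ds, k = 5), "exceed")
})

test_that("evaluation reports round-trip through JSON", {
  withr::with_seed(31, {
    y <- sample(1:3, 30, TRUE); p <- sample(1:3, 30, TRUE)
    s <- matrix(runif(90), 30, 3, dimnames = list(NULL, 1:3))
  })
  r <- computeMetrics(y, p, s / rowSums(s))
  path <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(r, path)
  rt <- readEvalReport(path)
  expect_equal(rt@confusion, r@confusion)
  expect_equal(rt@accuracy, r@accuracy, tolerance = 1e-12)
  expect_equal(rt@mAP, r@mAP, tolerance = 1e-12)
})
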