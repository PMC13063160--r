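test_that("stratified split uses largest-remainder allocation", {
  # three classes summing to 143 at 0.8 -> 114 train / 29 test
  withr::with_seed(1, {
    y <- rep(1:3, c(60, 55, 28))
    X <- matrix(rnorm(143 * 4), 143, 4, dimnames = list(NULL, paste0("f", 1:4)))
  })
  sp <- stratifiedSplit(LabeledDataset(X, y), 0.8, seed = 2)
  expect_equal(nrow(features(sp$train)), 114)
  expect_equal(nrow(features(sp$test)), 29)
  # per-class proportions preserved to within one sample
  tr <- table(grades(sp$train))
  expect_true(all(abs(tr - 0.8 * c(60, 55, 28)) <= 1))

  # balanced 2-class n = 10 at 0.8 -> 4 + 4 train, 1 + 1 test
  ds10 <- toyDataset(nPerClass = 5, nClasses = 2, p = 3)
  sp10 <- stratifiedSplit(ds10, 0.8, seed = 3)
  expect_equal(unname(c(table(grades(sp10$train)))), c(4, 4))
  expect_equal(unname(c(table(grades(sp10$test)))), c(1, 1))
})

test_that("splits are deterministic and reject singleton classes", {
  ds <- toyDataset(nPerClass = 10, nClasses = 3)
  a <- stratifiedSplit(ds, 0.8, seed = 7)
  b <- stratifiedSplit(ds, 0.8, seed = 7)
  expect_identical(features(a$train), features(b$train))
  bad <- LabeledDataset(matrix(rnorm(3), 3, 1, dimnames = list(NULL, "f1")),
                        c("A", "A", "B"))
  expect_error(stratifiedSplit(bad, 0.8), "at least 2")
})

test_that("synthetic rows never reach the test partition", {
  ds <- toyDataset(nPerClass = 8, nClasses = 2)
  # unbalance then SMOTE so the input carries synthetic rows
  dsUnb <- ds[c(1:8, 9:12), ]
  bal <- smoteBalance(dsUnb, seed = 1)
  sp <- stratifiedSplit(bal, 0.8, seed = 1)
  expect_true(all(provenance(sp$test) == "original"))
  expect_true(any(provenance(sp$train) == "synthetic"))
})

test_that("SMOTE balances exactly to the target and flags interpolants", {
  ds <- toyDataset(nPerClass = 10, nClasses = 2, p = 3)
  # already balanced: unchanged
  expect_identical(features(smoteBalance(ds, seed = 1)), features(ds))
  dsUnb <- ds[c(1:10, 11:14), ]
  expect_warning(bal <- smoteBalance(dsUnb, seed = 2), "shrinking")
  counts <- table(grades(bal))
  expect_equal(unname(c(counts)), c(10, 10))
  expect_equal(sum(provenance(bal) == "synthetic"), 6)
  # explicit numeric target
  bal2 <- suppressWarnings(smoteBalance(dsUnb, targetCount = 12, seed = 2))
  expect_equal(unname(c(table(grades(bal2)))), c(12, 12))
})

test_that("every synthetic row lies on a segment between same-class parents", {
  ds <- toyDataset(nPerClass = 12, nClasses = 2, p = 3)
  dsUnb <- ds[c(1:12, 13:17), ]
  bal <- smoteBalance(dsUnb, seed = 4)
  X <- features(bal); y <- grades(bal); prov <- provenance(bal)
  for (s in which(prov == "synthetic")) {
    parents <- which(prov == "original" & y == y[s])
    onSegment <- FALSE
    for (i in parents) for (j in parents) {
      if (i == j) next
      dir <- X[j, ] - X[i, ]
      if (all(abs(dir) < 1e-12)) next
      u <- (X[s, ] - X[i, ]) / dir
      u <- u[is.finite(u)]
      if (length(u) && max(u) - min(u) < 1e-8 && min(u) >= -1e-8 &&
          max(u) <= 1 + 1e-8) onSegment <- TRUE
    }
    expect_true(onSegment, info = sprintf("row %d", s))
  }
})

test_that("SMOTE is reproducible under a fixed seed", {
  ds <- toyDataset(nPerClass = 10, nClasses = 2, p = 3)[c(1:10, 11:15), ]
  expect_identical(features(smoteBalance(ds, seed = 9)),
                   features(smoteBalance(ds, seed = 9)))
})

test_that("cumulative-importance selection keeps the minimal prefix", {
  # ten identical copies of the label: equal importances, 0.60 -> 6 kept
  withr::with_seed(2, {
    y <- rep(1:3, each = 10)
    X <- matrix(rep(as.numeric(y), 10), 30, 10)
    colnames(X) <- paste0("f", 1:10)
  })
  sel <- selectFeatures(LabeledDataset(X, y), "COR", threshold = 0.60)
  expect_length(sel@selected, 6)
  expect_equal(sum(sel@importances), 1)

  # one dominant feature
  withr::with_seed(3, {
    X2 <- matrix(rnorm(300, sd = 1e-9), 30, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
    X2[, 4] <- as.numeric(y)
  })
  sel2 <- selectFeatures(LabeledDataset(X2, y), "COR", threshold = 0.60)
  expect_equal(names(sel2@importances)[sel2@selected[1]], "f4")
})

test_that("an affine copy of the label dominates every selector", {
  withr::with_seed(5, {
    y <- rep(1:3, each = 12)
    X <- matrix(rnorm(36 * 5), 36, 5)
    X <- cbind(X, labelCopy = 2 * as.numeric(y) + 1)
    colnames(X) <- c(paste0("f", 1:5), "labelCopy")
  })
  ds <- LabeledDataset(X, y)
  for (m in c("RFI", "COR", "MI", "RFE", "XGB")) {
    sel <- selectFeatures(ds, m, seed = 1)
    expect_equal(names(sel@importances)[sel@selected[1]], "labelCopy",
                 info = m)
  }
  # for COR specifically, |r| = 1 and informative share is total
  selC <- selectFeatures(ds, "COR", seed = 1)
  expect_equal(max(selC@importances), selC@importances[["labelCopy"]])
})

test_that("ALL is the identity selection and thresholds nest", {
  ds <- toyDataset(nPerClass = 15, nClasses = 3, p = 8)
  sel <- selectFeatures(ds, "ALL")
  expect_identical(sel@selected, seq_len(8L))
  for (m in c("RFI", "COR", "MI", "XGB")) {
    s40 <- selectFeatures(ds, m, threshold = 0.40, seed = 2)@selected
    s60 <- selectFeatures(ds, m, threshold = 0.60, seed = 2)@selected
    expect_true(all(s40 %in% s60), info = m)
    expect_lte(length(s40), length(s60))
  }
})

test_that("constant features get zero COR importance with a warning", {
  withr::with_seed(6, {
    y <- rep(1:2, each = 10)
    X <- cbind(flat = rep(1, 20), sig = as.numeric(y) + rnorm(20, sd = .1))
  })
  expect_warning(sel <- selectFeatures(LabeledDataset(X, y), "COR"),
                 "constant")
  expect_equal(unname(sel@importances["flat"]), 0)
})

test_that("selection reports round-trip through JSON", {
  ds <- toyDataset(nPerClass = 10, nClasses = 2, p = 5)
  sel <- selectFeatures(ds, "COR")
  path <- withr::local_tempfile(fileext = ".json")
  writeSelection(sel, path)
  rt <- readSelection(path)
  expect_equal(rt@importances, sel@importances, tolerance = 1e-12)
  expect_equal(rt@selected, sel@selected)
  expect_error(readSelection(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "method")
})
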