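#' @include AllClasses.R
NULL

#' The classifier registry
#'
#' Five tree-ensemble slots share the hyperparameter vocabulary
#' `learning_rate`, `depth`, `iterations`, `l2_leaf_reg`:
#'
#' * `gbdt` — depth-wise, exact-split gradient-boosted trees with
#'   conservative CatBoost-style defaults (xgboost backend);
#' * `xgb` — standard gradient-boosted trees (xgboost backend);
#' * `histgb` — histogram-binned, leaf-wise gradient boosting
#'   (LightGBM-family configuration, xgboost backend);
#' * `extratrees` — extremely randomized trees (ranger backend);
#' * `rf` — random-forest baseline (ranger backend).
#'
#' @return named list; each entry has `backend`, `defaults` and `bounds`.
#' @export
algorithmRegistry <- function() {
  bounds <- paramBounds()
  list(
    gbdt = list(backend = "xgboost", bounds = bounds,
                defaults = list(learning_rate = 0.03, depth = 6,
                                iterations = 500, l2_leaf_reg = 3),
                xgbParams = list(tree_method = "exact")),
    xgb = list(backend = "xgboost", bounds = bounds,
               defaults = list(learning_rate = 0.1, depth = 6,
                               iterations = 200, l2_leaf_reg = 1),
               xgbParams = list(tree_method = "exact")),
    histgb = list(backend = "xgboost", bounds = bounds,
                  defaults = list(learning_rate = 0.1, depth = 8,
                                  iterations = 200, l2_leaf_reg = 1),
                  xgbParams = list(tree_method = "hist",
                                   grow_policy = "lossguide",
                                   max_leaves = 31)),
    extratrees = list(backend = "ranger", bounds = bounds,
                      defaults = list(iterations = 500, depth = 0),
                      rangerParams = list(splitrule = "extratrees",
                                          num.random.splits = 1,
                                          replace = FALSE,
                                          sample.fraction = 1)),
    rf = list(backend = "ranger", bounds = bounds,
              defaults = list(iterations = 500, depth = 0),
              rangerParams = list())
  )
}

# merge registry defaults with a spec's overrides
resolveParams <- function(spec) {
  entry <- algorithmRegistry()[[spec@algorithm]]
  utils::modifyList(entry$defaults, spec@params)
}

#' Fit a classifier
#'
#' @param spec a [ModelSpec-class].
#' @param ds training [LabeledDataset-class] (more than one class).
#' @return a [PNSModel-class] handle supporting [predictGrades()].
#' @export
trainModel <- function(spec, ds) {
  X <- features(ds)
  y <- droplevels(grades(ds))
  if (nlevels(y) < 2) stop("training data contain a single class")
  entry <- algorithmRegistry()[[spec@algorithm]]
  p <- resolveParams(spec)
  fit <- if (entry$backend == "ranger") {
    args <- c(list(x = X, y = y, num.trees = as.integer(round(p$iterations)),
                   probability = TRUE, seed = as.integer(spec@seed),
                   num.threads = 1),
              entry$rangerParams)
    if (!is.null(p$depth) && p$depth > 0)
      args$max.depth <- as.integer(round(p$depth))
    do.call(ranger::ranger, args)
  } else {
    params <- c(list(objective = "multi:softprob", num_class = nlevels(y),
                     eta = p$learning_rate,
                     max_depth = as.integer(round(p$depth)),
                     lambda = p$l2_leaf_reg, nthread = 1, verbosity = 0,
                     seed = as.integer(spec@seed)),
                entry$xgbParams)
    xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                  nthread = 1),
      nrounds = as.integer(round(p$iterations)))
  }
  new("PNSModel", spec = spec, fit = fit, classes = levels(y),
      featureNames = colnames(X))
}

#' Predict grade labels and per-class probabilities
#'
#' @param model a [PNSModel-class].
#' @param X feature matrix (columns matching the training features) or a
#'   [LabeledDataset-class].
#' @return list with `labels` (character) and `prob` (n x C matrix with
#'   class columns).
#' @export
predictGrades <- function(model, X) {
  if (is(X, "LabeledDataset")) X <- features(X)
  X <- X[, model@featureNames, drop = FALSE]
  prob <- if (inherits(model@fit, "ranger")) {
    pr <- stats::predict(model@fit, data = X, num.threads = 1)$predictions
    pr[, model@classes, drop = FALSE]
  } else {
    pr <- stats::predict(model@fit,
                         xgboost::xgb.DMatrix(X, nthread = 1))
    pr <- matrix(pr, nrow = nrow(X), byrow = FALSE,
                 ncol = length(model@classes))
    colnames(pr) <- model@classes
    pr
  }
  labels <- model@classes[max.col(prob, ties.method = "first")]
  list(labels = labels, prob = prob)
}

## ---- metrics --------------------------------------------------------------

#' Evaluation metrics for grade predictions
#'
#' Accuracy is the trace of the confusion matrix over the total. Precision,
#' recall and F1 are computed per class one-vs-rest and macro-averaged.
#' Average precision accumulates precision over recall increments along the
#' descending score ranking (ties broken by sample index); mAP averages AP
#' over the classes present in `yTrue` (absent classes are excluded with a
#' warning).
#'
#' @param yTrue,yPred aligned label vectors.
#' @param scores optional n x C per-class score matrix (columns named by
#'   class) used for AP/mAP; without it mAP is `NA`.
#' @return an [EvalReport-class].
#' @export
computeMetrics <- function(yTrue, yPred, scores = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  stopifnot(length(yTrue) == length(yPred))
  cls <- sort(unique(c(yTrue, yPred)))
  if (!is.null(scores)) cls <- sort(unique(c(cls, colnames(scores))))
  conf <- table(factor(yTrue, levels = cls), factor(yPred, levels = cls))
  conf <- unclass(conf)
  dimnames(conf) <- list(cls, cls)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(conf) > 0
  if (!all(present))
    warning("class(es) absent from y_true excluded from macro metrics: ",
            paste(cls[!present], collapse = ", "))
  ap <- rep(NA_real_, length(cls))
  if (!is.null(scores)) {
    for (ci in which(present)) {
      s <- scores[, cls[ci]]
      pos <- yTrue == cls[ci]
      ord <- order(-s, seq_along(s))
      hits <- pos[ord]
      precAtK <- cumsum(hits) / seq_along(hits)
      ap[ci] <- sum(precAtK[hits]) / sum(pos)
    }
  }
  perClass <- data.frame(class = cls, precision = prec, recall = rec,
                         f1 = f1, AP = ap, row.names = NULL)
  new("EvalReport", confusion = conf,
      accuracy = sum(tp) / sum(conf),
      precision = mean(prec[present]), recall = mean(rec[present]),
      f1 = mean(f1[present]),
      mAP = if (is.null(scores)) NA_real_ else mean(ap[present]),
      perClass = perClass)
}

#' Run-to-run variability (sample standard deviation)
#'
#' @param values numeric vector of per-run metric values (length >= 2).
#' @return the 1/(n-1)-normalized standard deviation.
#' @export
variability <- function(values) {
  if (length(values) < 2) stop("variability needs at least 2 values")
  stats::sd(values)
}

#' Write / read an EvalReport as JSON
#'
#' @param report an [EvalReport-class].
#' @param path JSON file path.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(confusion = unname(report@confusion),
         classes = rownames(report@confusion),
         accuracy = report@accuracy, precision = report@precision,
         recall = report@recall, f1 = report@f1, mAP = report@mAP,
         perClass = report@perClass),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("confusion", "classes", "accuracy", "f1"))
    if (is.null(obj[[f]])) stop("eval JSON is missing field '", f, "'")
  conf <- obj$confusion
  dimnames(conf) <- list(obj$classes, obj$classes)
  new("EvalReport", confusion = conf, accuracy = obj$accuracy,
      precision = obj$precision, recall = obj$recall, f1 = obj$f1,
      mAP = if (is.null(obj$mAP)) NA_real_ else obj$mAP,
      perClass = as.data.frame(obj$perClass))
}

## ---- comparison grid ------------------------------------------------------

#' Algorithms x feature sets x schemes comparison grid
#'
#' For every combination: split the scheme's dataset (one split per scheme,
#' reused across cells), compute the feature selection on the training
#' partition, SMOTE-balance the selected training data, fit, and evaluate
#' on the untouched, original-only test partition. Failed cells are
#' recorded and the grid continues.
#'
#' @param data named list of [LabeledDataset-class] objects keyed by scheme
#'   (e.g. `"3"`, `"5"`, `"6"`), all original-provenance rows.
#' @param schemes character/integer subset of `names(data)`.
#' @param featureSets subset of ALL, RFI, COR, MI, RFE, XGB.
#' @param algorithms subset of the registry keys.
#' @param seed master seed; per-scheme splits and fits derive from it.
#' @param trainFraction,smoteTarget,threshold passed to the stages.
#' @return list with `table` (one row per cell: scheme, featureSet,
#'   algorithm, metrics, status) and `reports` (named list of
#'   [EvalReport-class]).
#' @export
runGrid <- function(data, schemes = names(data),
                    featureSets = c("ALL", "RFI", "COR", "MI", "RFE", "XGB"),
                    algorithms = names(algorithmRegistry()),
                    seed = 1L, trainFraction = 0.8,
                    smoteTarget = "majority", threshold = 0.60) {
  schemes <- as.character(schemes)
  rows <- list(); reports <- list()
  for (sc in schemes) {
    ds <- data[[sc]]
    if (is.null(ds)) stop("no dataset supplied for scheme ", sc)
    sp <- stratifiedSplit(ds, trainFraction, seed = stageSeed(seed, "split"))
    stopifnot(all(provenance(sp$test) == "original"))
    for (fs in featureSets) {
      sel <- try(selectFeatures(sp$train, fs, threshold = threshold,
                                seed = stageSeed(seed, "select")),
                 silent = TRUE)
      for (alg in algorithms) {
        key <- paste(sc, fs, alg, sep = "/")
        res <- try({
          if (inherits(sel, "try-error")) stop(attr(sel, "condition"))
          trainSel <- applySelection(sp$train, sel)
          testSel <- applySelection(sp$test, sel)
          bal <- smoteBalance(trainSel, targetCount = smoteTarget,
                              seed = stageSeed(seed, "balance"))
          mdl <- trainModel(modelSpec(alg, seed = stageSeed(seed, "train")),
                            bal)
          pred <- predictGrades(mdl, testSel)
          computeMetrics(grades(testSel), pred$labels, pred$prob)
        }, silent = TRUE)
        if (inherits(res, "try-error")) {
          rows[[key]] <- data.frame(scheme = sc, featureSet = fs,
                                    algorithm = alg, accuracy = NA,
                                    f1 = NA, mAP = NA, status = "failed")
        } else {
          reports[[key]] <- res
          rows[[key]] <- data.frame(scheme = sc, featureSet = fs,
                                    algorithm = alg,
                                    accuracy = res@accuracy, f1 = res@f1,
                                    mAP = res@mAP, status = "ok")
        }
      }
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}

#' Stratified k-fold cross-validation
#'
#' By default balancing (and, when `selection` is given, feature selection)
#' is refit inside each training fold so no synthetic sample or selection
#' statistic ever touches an evaluation fold. `smoteInsideFolds = FALSE`
#' reproduces the balance-then-partition ordering some workflows use; it is
#' methodologically weaker (interpolants of test points leak into
#' training) and exists for comparability only.
#'
#' @param spec a [ModelSpec-class].
#' @param ds a [LabeledDataset-class]; original rows only in the default
#'   leakage-safe mode.
#' @param k fold count (k <= smallest class count).
#' @param seed integer seed (fold assignment and stage seeds).
#' @param smoteInsideFolds logical, see above.
#' @param selection optional feature-selection method refit per fold.
#' @param smoteTarget passed to [smoteBalance()].
#' @return list with `folds` (per-fold [EvalReport-class]), `mean` and
#'   `sd` (named metric summaries; `sd` is the Eq-style run variability).
#' @export
kfoldCV <- function(spec, ds, k = 10, seed = 1L, smoteInsideFolds = TRUE,
                    selection = NULL, smoteTarget = "majority") {
  n <- nrow(features(ds))
  if (k > n) stop("k must not exceed the sample count")
  y <- grades(ds)
  if (smoteInsideFolds && any(provenance(ds) == "synthetic"))
    stop("leakage-safe CV expects original rows only; balance happens ",
         "inside the folds")
  if (!smoteInsideFolds)
    ds <- smoteBalance(ds, targetCount = smoteTarget,
                       seed = stageSeed(seed, "balance"))
  y <- grades(ds)
  n <- nrow(features(ds))
  # class-blocked round-robin: stratified and every fold non-empty
  fold <- integer(n)
  withr::with_seed(seed, {
    ord <- unlist(lapply(levels(y), function(cls) {
      rows <- which(y == cls)
      rows[sample.int(length(rows))]
    }))
    fold[ord] <- rep_len(seq_len(k), n)
  })
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trainDs <- ds[fold != f, ]
    testDs <- ds[fold == f, ]
    if (smoteInsideFolds) {
      if (!is.null(selection)) {
        sel <- selectFeatures(trainDs, selection,
                              seed = stageSeed(seed, "select"))
        trainDs <- applySelection(trainDs, sel)
        testDs <- applySelection(testDs, sel)
      }
      trainDs <- smoteBalance(trainDs, targetCount = smoteTarget,
                              seed = stageSeed(seed, "balance") + f)
      stopifnot(all(provenance(testDs) == "original"))
    }
    mdl <- trainModel(spec, trainDs)
    pred <- predictGrades(mdl, testDs)
    reports[[f]] <- computeMetrics(grades(testDs), pred$labels, pred$prob)
  }
  metric <- function(slot) vapply(reports, methods::slot, 0, name = slot)
  mets <- c("accuracy", "precision", "recall", "f1", "mAP")
  means <- vapply(mets, function(m) mean(metric(m)), 0)
  sds <- vapply(mets, function(m) variability(metric(m)), 0)
  list(folds = reports, mean = means, sd = sds, foldAssignment = fold)
}
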