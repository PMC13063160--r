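#' @include AllClasses.R
NULL

# z-score columns using reference statistics (constant columns left at 0)
.zscore <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Stratified train/test split
#'
#' Per-class proportional allocation with largest-remainder rounding of the
#' total train size `round(trainFraction * n)`. Synthetic rows (SMOTE
#' interpolants) are always placed in the training partition, so the test
#' set contains only original samples.
#'
#' @param ds a [LabeledDataset-class]; every class needs >= 2 original
#'   members.
#' @param trainFraction fraction of original samples to train on.
#' @param seed integer seed (deterministic partition).
#' @return list with `train` and `test` [LabeledDataset-class] objects.
#' @export
stratifiedSplit <- function(ds, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  orig <- which(provenance(ds) == "original")
  y <- grades(ds)[orig]
  counts <- table(y)
  if (any(counts < 2))
    stop("every class needs at least 2 original members to stratify; ",
         "short classes: ", paste(names(counts)[counts < 2], collapse = ", "))
  nTrainTotal <- round(trainFraction * length(orig))
  raw <- as.numeric(counts) * trainFraction
  base <- floor(raw)
  rem <- nTrainTotal - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(raw))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(raw - base, seq_along(raw))[seq_len(-rem)]
    base[cut] <- base[cut] - 1
  }
  # keep at least one test row per class
  base <- pmin(base, as.numeric(counts) - 1)

  withr::with_seed(seed, {
    trainIdx <- integer(0)
    for (ci in seq_along(counts)) {
      rows <- orig[y == names(counts)[ci]]
      trainIdx <- c(trainIdx, sample(rows, base[ci]))
    }
  })
  trainIdx <- sort(c(trainIdx, which(provenance(ds) == "synthetic")))
  testIdx <- setdiff(seq_len(nrow(features(ds))), trainIdx)
  list(train = ds[trainIdx, ], test = ds[testIdx, ])
}

#' Subset a LabeledDataset by row and/or feature index
#'
#' @param x a [LabeledDataset-class].
#' @param i row indices; @param j feature (column) indices.
#' @param ... ignored. @param drop ignored.
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (missing(j)) j <- seq_len(ncol(x@X))
  # factor levels are kept so train/test partitions stay comparable
  LabeledDataset(x@X[i, j, drop = FALSE], x@y[i], x@provenance[i])
})

#' SMOTE class balancing
#'
#' Brings every minority class up to `targetCount` by interpolating between
#' a class member and one of its k nearest same-class neighbors:
#' `x_new = x_i + u (x_nn - x_i)`, `u ~ U(0, 1)`. Neighbor search runs in
#' z-scored feature space (statistics of the input data); interpolation is
#' affine, so synthetic rows lie on the raw-space segment as well. Synthetic
#' rows are flagged in the provenance; classes at or above the target are
#' untouched.
#'
#' @param ds training [LabeledDataset-class]; minority classes need >= 2
#'   members.
#' @param targetCount per-class target, or `"majority"` (the default) for
#'   the largest class count.
#' @param kNeighbors neighbor pool size (shrunk per class with a warning
#'   when the class is smaller).
#' @param seed integer seed.
#' @return a balanced [LabeledDataset-class].
#' @export
smoteBalance <- function(ds, targetCount = "majority", kNeighbors = 5,
                         seed = 1L) {
  X <- features(ds); y <- grades(ds); prov <- provenance(ds)
  counts <- table(y)
  target <- if (identical(targetCount, "majority")) max(counts)
            else as.integer(targetCount)
  need <- pmax(target - as.integer(counts), 0L)
  if (all(need == 0)) return(ds)
  short <- names(counts)[need > 0 & as.integer(counts) < 2]
  if (length(short))
    stop("classes with a single member cannot be SMOTE-balanced: ",
         paste(short, collapse = ", "))
  Z <- .zscore(X)
  newX <- list(); newY <- character(0)
  withr::with_seed(seed, {
    for (ci in which(need > 0)) {
      cls <- names(counts)[ci]
      rows <- which(y == cls)
      k <- kNeighbors
      if (k >= length(rows)) {
        k <- length(rows) - 1L
        warning(sprintf(
          "class %s has %d members; shrinking k_neighbors to %d",
          cls, length(rows), k))
      }
      D <- as.matrix(stats::dist(Z[rows, , drop = FALSE]))
      diag(D) <- Inf
      nnIdx <- apply(D, 1, function(d) order(d)[seq_len(k)],
                     simplify = FALSE)
      parents <- sample(seq_along(rows), need[ci], replace = TRUE)
      for (p in parents) {
        nb <- nnIdx[[p]][sample.int(k, 1)]
        u <- stats::runif(1)
        newX[[length(newX) + 1L]] <-
          X[rows[p], ] + u * (X[rows[nb], ] - X[rows[p], ])
        newY <- c(newY, cls)
      }
    }
  })
  Xs <- do.call(rbind, newX)
  colnames(Xs) <- colnames(X)
  LabeledDataset(rbind(X, Xs),
                 factor(c(as.character(y), newY), levels = levels(y)),
                 c(prov, rep("synthetic", nrow(Xs))))
}

## ---- feature selection ----------------------------------------------------

# Ross (2014) k-NN mutual information between a continuous feature and a
# discrete label; tiny seeded jitter breaks ties
.miKnn <- function(x, y, k = 3L) {
  n <- length(x)
  x <- x + stats::rnorm(n, sd = 1e-10 * max(stats::sd(x), 1e-12))
  counts <- table(y)
  dAll <- abs(outer(x, x, "-"))
  diag(dAll) <- Inf
  mi <- 0; used <- 0
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    nc <- length(same)
    if (nc < 2) next
    ki <- min(k, nc - 1L)
    r <- sort(dAll[i, same])[ki]        # distance to ki-th same-class nb
    m <- sum(dAll[i, ] < r)             # all-class points strictly inside
    mi <- mi + digamma(n) - digamma(nc) + digamma(ki) - digamma(max(m, 1))
    used <- used + 1
  }
  max(mi / max(used, 1), 0)
}

# recursive feature elimination order via repeated impurity-ranked refits;
# returns a score increasing with elimination step (kept-longest = largest)
.rfeScores <- function(X, y, seed, numTrees = 150) {
  p <- ncol(X)
  remaining <- seq_len(p)
  score <- numeric(p)
  step <- 1
  while (length(remaining) > 1) {
    fit <- ranger::ranger(x = X[, remaining, drop = FALSE], y = y,
                          num.trees = numTrees, importance = "impurity",
                          seed = seed + step, num.threads = 1)
    imp <- fit$variable.importance
    dropLocal <- which.min(imp)
    score[remaining[dropLocal]] <- step
    remaining <- remaining[-dropLocal]
    step <- step + 1
  }
  score[remaining] <- step
  score
}

#' Importance-based feature selection
#'
#' Computes per-feature importances on training data only, normalizes them
#' to sum 1, sorts descending (ties broken by original index) and keeps the
#' minimal prefix whose cumulative importance reaches `threshold`.
#'
#' Methods: `ALL` (identity), `RFI` (impurity importance of a 500-tree
#' randomized ensemble), `COR` (absolute Pearson correlation with the
#' numeric grade label), `MI` (k-NN mutual information estimator, k = 3),
#' `RFE` (reverse elimination order of iterative tree-ensemble refits
#' dropping one feature per step) and `XGB` (total-gain importance of a
#' gradient-boosted-tree fit).
#'
#' @param ds training [LabeledDataset-class].
#' @param method one of ALL, RFI, COR, MI, RFE, XGB.
#' @param threshold cumulative-importance fraction (default 0.60).
#' @param seed integer seed for the stochastic estimators.
#' @return a [FeatureSelection-class].
#' @export
selectFeatures <- function(ds, method = c("ALL", "RFI", "COR", "MI",
                                          "RFE", "XGB"),
                           threshold = 0.60, seed = 1L) {
  method <- match.arg(method)
  X <- features(ds); y <- grades(ds)
  p <- ncol(X)
  if (method == "ALL") {
    imp <- rep(1 / p, p)
    names(imp) <- colnames(X)
    return(new("FeatureSelection", method = method, importances = imp,
               selected = seq_len(p), threshold = threshold))
  }
  imp <- switch(method,
    RFI = {
      fit <- ranger::ranger(x = X, y = y, num.trees = 500,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      pmax(fit$variable.importance, 0)
    },
    COR = {
      Z <- .zscore(X)
      yn <- as.numeric(y)
      r <- suppressWarnings(abs(stats::cor(Z, yn)))[, 1]
      if (anyNA(r)) {
        warning("constant feature(s) under COR given importance 0: ",
                paste(colnames(X)[is.na(r)], collapse = ", "))
        r[is.na(r)] <- 0
      }
      r
    },
    MI = {
      Z <- .zscore(X)
      withr::with_seed(seed,
        apply(Z, 2, .miKnn, y = y, k = 3L))
    },
    RFE = {
      s <- .rfeScores(X, y, seed = seed)
      names(s) <- colnames(X)
      s
    },
    XGB = {
      yy <- as.integer(y) - 1L
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y), eta = 0.1, max_depth = 6,
                      nthread = 1, verbosity = 0, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = yy, nthread = 1),
        nrounds = 100)
      tab <- xgboost::xgb.importance(model = fit)
      g <- stats::setNames(rep(0, p), colnames(X))
      g[tab$Feature] <- tab$Gain
      g
    })
  if (sum(imp) <= 0) stop("all importances are zero under method ", method)
  imp <- imp / sum(imp)
  ord <- order(-imp, seq_len(p))
  cum <- cumsum(imp[ord])
  nKeep <- which(cum >= threshold - 1e-12)[1]
  new("FeatureSelection", method = method, importances = imp,
      selected = as.integer(ord[seq_len(nKeep)]), threshold = threshold)
}

#' Apply a feature selection to a dataset
#'
#' @param ds a [LabeledDataset-class].
#' @param sel a [FeatureSelection-class] computed on compatible features.
#' @return the dataset restricted to the selected features.
#' @export
applySelection <- function(ds, sel) {
  stopifnot(length(sel@importances) == ncol(features(ds)))
  ds[, sel@selected]
}

#' Write / read a selection report as JSON
#'
#' @param sel a [FeatureSelection-class].
#' @param path JSON file path.
#' @export
writeSelection <- function(sel, path) {
  jsonlite::write_json(
    list(method = sel@method, threshold = sel@threshold,
         importances = as.list(sel@importances),
         selected = names(sel@importances)[sel@selected]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSelection
#' @export
readSelection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("method", "threshold", "importances", "selected"))
    if (is.null(obj[[f]])) stop("selection JSON is missing field '", f, "'")
  imp <- unlist(obj$importances)
  new("FeatureSelection", method = obj$method,
      importances = imp,
      selected = match(obj$selected, names(imp)),
      threshold = obj$threshold)
}
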