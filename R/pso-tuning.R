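#' @include AllClasses.R
NULL

#' Hyperparameter search box
#'
#' @param learning_rate,depth,iterations,l2_leaf_reg length-2 numeric
#'   ranges. `depth` and `iterations` are integer dimensions (rounded at
#'   objective evaluation only).
#' @return data.frame with columns `name`, `lower`, `upper`, `kind`.
#' @export
paramBounds <- function(learning_rate = c(0.001, 0.1), depth = c(4, 12),
                        iterations = c(500, 2000), l2_leaf_reg = c(1, 10)) {
  b <- data.frame(
    name = c("learning_rate", "depth", "iterations", "l2_leaf_reg"),
    lower = c(learning_rate[1], depth[1], iterations[1], l2_leaf_reg[1]),
    upper = c(learning_rate[2], depth[2], iterations[2], l2_leaf_reg[2]),
    kind = c("real", "integer", "integer", "real"))
  if (any(b$lower > b$upper)) stop("bounds must satisfy lower <= upper")
  b
}

# round integer dimensions for objective evaluation
.evalParams <- function(position, bounds) {
  p <- as.list(position)
  names(p) <- bounds$name
  for (i in which(bounds$kind == "integer")) p[[i]] <- round(p[[i]])
  p
}

#' Particle swarm optimization (global-best, maximizing)
#'
#' Canonical velocity/position update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with per-dimension
#' `r1, r2 ~ U(0, 1)`; positions are clamped to the box and the velocity on
#' a clamped dimension is zeroed. Integer dimensions are rounded only when
#' passed to the objective. Non-finite fitness values are treated as -Inf
#' with a warning. The gbest trace is monotone non-decreasing.
#'
#' @param objective function(named param list) -> scalar fitness to
#'   maximize.
#' @param bounds a [paramBounds()]-style data.frame.
#' @param swarmSize,iterations swarm dimensions.
#' @param w,c1,c2 inertia, cognitive and social coefficients.
#' @param seed integer seed; a fixed seed reproduces the trajectory.
#' @param init optional matrix of initial positions (rows; recycled
#'   particles beyond `nrow(init)` are sampled uniformly in the box).
#' @return list with `bestParams` (named list, integers rounded),
#'   `bestFitness`, and `trace` (data.frame iteration/gbest).
#' @export
psoOptimize <- function(objective, bounds, swarmSize = 20, iterations = 30,
                        w = 0.72, c1 = 1.49, c2 = 1.49, seed = 1L,
                        init = NULL) {
  d <- nrow(bounds)
  lower <- bounds$lower; upper <- bounds$upper
  span <- upper - lower
  evalAt <- function(pos) {
    f <- objective(.evalParams(pos, bounds))
    if (!is.finite(f)) {
      warning("non-finite fitness; treating as -Inf")
      f <- -Inf
    }
    f
  }
  if (all(span == 0)) {
    # degenerate box: every particle sits on the single feasible point
    f <- evalAt(lower)
    return(list(bestParams = .evalParams(lower, bounds), bestFitness = f,
                trace = data.frame(iteration = 0, gbest = f)))
  }
  withr::with_seed(seed, {
    pos <- matrix(stats::runif(swarmSize * d), swarmSize, d)
    pos <- sweep(sweep(pos, 2, span, "*"), 2, lower, "+")
    if (!is.null(init)) {
      nI <- min(nrow(init), swarmSize)
      pos[seq_len(nI), ] <- init[seq_len(nI), , drop = FALSE]
    }
    vel <- matrix(stats::runif(swarmSize * d, -1, 1), swarmSize, d) *
      matrix(span, swarmSize, d, byrow = TRUE) * 0.1
    pbest <- pos
    pbestVal <- apply(pos, 1, evalAt)
    gIdx <- which.max(pbestVal)
    gbest <- pbest[gIdx, ]; gbestVal <- pbestVal[gIdx]
    trace <- data.frame(iteration = 0, gbest = gbestVal)
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(swarmSize * d), swarmSize, d)
      r2 <- matrix(stats::runif(swarmSize * d), swarmSize, d)
      vel <- w * vel +
        c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, swarmSize, d, byrow = TRUE) - pos)
      pos <- pos + vel
      for (j in seq_len(d)) {
        lowHit <- pos[, j] < lower[j]; highHit <- pos[, j] > upper[j]
        pos[lowHit, j] <- lower[j]; pos[highHit, j] <- upper[j]
        vel[lowHit | highHit, j] <- 0
      }
      vals <- apply(pos, 1, evalAt)
      improved <- vals > pbestVal
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbestVal[improved] <- vals[improved]
      if (max(pbestVal) > gbestVal) {
        gIdx <- which.max(pbestVal)
        gbest <- pbest[gIdx, ]; gbestVal <- pbestVal[gIdx]
      }
      trace <- rbind(trace, data.frame(iteration = it, gbest = gbestVal))
    }
  })
  list(bestParams = .evalParams(gbest, bounds), bestFitness = gbestVal,
       trace = trace)
}

#' PSO hyperparameter tuning of a classifier
#'
#' Fitness is the classification accuracy on a seeded inner validation
#' split of the supplied (training) data: each candidate parameter set
#' refits the model on the SMOTE-balanced inner-training part, scored on the
#' untouched, original-only validation part. One particle starts at the
#' registry defaults, so the tuned fitness can never fall below the default
#' configuration's fitness.
#'
#' @param spec a [ModelSpec-class] (xgboost-backend slots expose all four
#'   tuned dimensions).
#' @param ds the training [LabeledDataset-class] (leakage-safe: must not be
#'   the evaluation partition).
#' @param bounds a [paramBounds()] box.
#' @param validationFraction inner holdout fraction.
#' @param swarmSize,iterations,seed passed to [psoOptimize()].
#' @return list with `spec` (tuned [ModelSpec-class]), `bestFitness`,
#'   `defaultFitness` and `trace`.
#' @export
tuneModel <- function(spec, ds, bounds = paramBounds(),
                      validationFraction = 0.25, swarmSize = 10,
                      iterations = 10, seed = 1L) {
  sp <- stratifiedSplit(ds, trainFraction = 1 - validationFraction,
                        seed = stageSeed(seed, "split"))
  inner <- smoteBalance(sp$train, seed = stageSeed(seed, "balance"))
  objective <- function(params) {
    res <- try({
      mdl <- trainModel(modelSpec(spec@algorithm, params = params,
                                  seed = spec@seed), inner)
      pred <- predictGrades(mdl, sp$test)
      mean(pred$labels == as.character(grades(sp$test)))
    }, silent = TRUE)
    if (inherits(res, "try-error")) -Inf else res
  }
  defaults <- resolveParams(spec)
  init <- matrix(vapply(bounds$name, function(nm) {
    v <- defaults[[nm]]
    if (is.null(v)) mean(c(bounds$lower[bounds$name == nm],
                           bounds$upper[bounds$name == nm])) else v
  }, 0), nrow = 1)
  init[1, ] <- pmin(pmax(init[1, ], bounds$lower), bounds$upper)
  defaultFitness <- objective(.evalParams(init[1, ], bounds))
  res <- psoOptimize(objective, bounds, swarmSize = swarmSize,
                     iterations = iterations, seed = seed, init = init)
  list(spec = modelSpec(spec@algorithm, params = res$bestParams,
                        seed = spec@seed),
       bestFitness = res$bestFitness, defaultFitness = defaultFitness,
       trace = res$trace)
}

#' Write a tuning report as JSON
#'
#' @param tuning result of [tuneModel()].
#' @param bounds the searched box.
#' @param path JSON file path.
#' @export
writeTuningReport <- function(tuning, bounds, path) {
  jsonlite::write_json(
    list(bounds = bounds, trace = tuning$trace,
         bestFitness = tuning$bestFitness,
         defaultFitness = tuning$defaultFitness,
         bestParams = tuning$spec@params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
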