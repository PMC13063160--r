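#' @include AllClasses.R
NULL

#' Derive a stage-specific seed from the master seed
#'
#' A fixed offset table keeps stage streams independent, so toggling one
#' stage does not reshuffle the others. Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param stage one of the pipeline stage names.
#' @return integer seed.
#' @export
stageSeed <- function(master, stage = c("derive", "simulate", "extract",
                                        "split", "balance", "select",
                                        "train", "tune", "cv")) {
  stage <- match.arg(stage)
  offsets <- c(derive = 101L, simulate = 907L, extract = 211L, split = 307L,
               balance = 401L, select = 503L, train = 601L, tune = 701L,
               cv = 809L)
  as.integer((as.numeric(master) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param outputDir run directory (created if missing).
#' @param schemes grading schemes to evaluate.
#' @param n synthetic sample count when simulating (images + assays are
#'   generated when `imagesDir`/`assaysCsv` are NULL).
#' @param imagesDir,assaysCsv optional input paths: a directory of slice
#'   images and a CSV with columns `sample_id`, `pns`.
#' @param deriveGrades derive grade tables from the assays (TRUE) or use
#'   the shipped reference tables (FALSE).
#' @param featureSets,algorithms grid axes.
#' @param featureCfg a [featureConfig()].
#' @param trainFraction,threshold stage settings.
#' @param pso list `(enabled, bounds, swarmSize, iterations, algorithm,
#'   featureSet)` controlling tuning of the best cell.
#' @param cv list `(enabled, k)` controlling cross-validation of the best
#'   cell.
#' @param seed master seed fanned out per stage via [stageSeed()].
#' @param size synthetic image side length.
#' @return validated config list of class `runConfig`.
#' @export
runConfig <- function(outputDir, schemes = 3, n = 60, imagesDir = NULL,
                      assaysCsv = NULL, deriveGrades = FALSE,
                      featureSets = c("ALL", "COR"),
                      algorithms = c("rf", "gbdt"),
                      featureCfg = featureConfig(), trainFraction = 0.8,
                      threshold = 0.60,
                      pso = list(enabled = FALSE, swarmSize = 6,
                                 iterations = 5),
                      cv = list(enabled = FALSE, k = 5),
                      seed = 1L, size = 64) {
  if (!is.null(imagesDir) && !dir.exists(imagesDir))
    stop("imagesDir does not exist: ", imagesDir)
  if (!is.null(assaysCsv) && !file.exists(assaysCsv))
    stop("assaysCsv does not exist: ", assaysCsv)
  stopifnot(all(as.character(schemes) %in% c("3", "5", "6")))
  structure(list(outputDir = outputDir, schemes = schemes, n = n,
                 imagesDir = imagesDir, assaysCsv = assaysCsv,
                 deriveGrades = deriveGrades, featureSets = featureSets,
                 algorithms = algorithms, featureCfg = featureCfg,
                 trainFraction = trainFraction, threshold = threshold,
                 pso = utils::modifyList(list(enabled = FALSE, swarmSize = 6,
                                              iterations = 5), pso),
                 cv = utils::modifyList(list(enabled = FALSE, k = 5), cv),
                 seed = seed, size = size),
            class = "runConfig")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the [runConfig()] arguments.
#'
#' @param path YAML file path.
#' @return a `runConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(y)[names(y) == "FALSE"] <- "n"
  known <- names(formals(runConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$featureCfg)) y$featureCfg <- do.call(featureConfig, y$featureCfg)
  do.call(runConfig, y)
}

.logLine <- function(logPath, stage, status, seed = NA, detail = NULL) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, status = status, seed = seed,
              version = as.character(utils::packageVersion("PNSgrade")))
  if (!is.null(detail)) rec$detail <- detail
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
      file = logPath, append = TRUE)
}

#' Run the full grading pipeline
#'
#' Stages: load-or-simulate inputs, derive (or load) grade tables, extract
#' features, run the comparison grid, optionally PSO-tune and
#' cross-validate the best cell. Artifacts written into the run directory:
#' `grade_table_<scheme>.json`, `features.csv`, `assays.csv`,
#' `selection_<scheme>_<method>.json`, `grid.csv`, `eval.json`,
#' `tuning.json` (when enabled) and `run_log.jsonl`. A stage failure stops
#' the run with the stage named, keeping partial outputs.
#'
#' @param config a [runConfig()].
#' @return the run directory path, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outputDir, "run_log.jsonl")
  seed <- config$seed
  stage <- function(name, seedUsed, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error")) {
      .logLine(logPath, name, "failed", seedUsed,
               conditionMessage(attr(res, "condition")))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(attr(res, "condition")), call. = FALSE)
    }
    .logLine(logPath, name, "ok", seedUsed)
    res
  }

  ## inputs: simulate or load
  inputs <- stage("inputs", seed, {
    if (is.null(config$imagesDir)) {
      sim <- genDataset(config$n, scheme = 3, seed = seed,
                        size = config$size, config = config$featureCfg)
      utils::write.csv(sim$assays,
                       file.path(config$outputDir, "assays.csv"),
                       row.names = FALSE)
      list(images = sim$images, assays = sim$assays)
    } else {
      paths <- list.files(config$imagesDir, full.names = TRUE,
                          pattern = "\\.(png|jpe?g|tiff?)$", ignore.case = TRUE)
      imgs <- lapply(paths, readSliceImage, config = config$featureCfg)
      names(imgs) <- sub("\\.[^.]+$", "", basename(paths))
      assays <- utils::read.csv(config$assaysCsv)
      list(images = imgs, assays = assays)
    }
  })

  tables <- stage("derive-grades", stageSeed(seed, "derive"), {
    tabs <- lapply(config$schemes, function(sc) {
      tab <- if (config$deriveGrades)
        deriveGradeTable(inputs$assays$pns, as.integer(sc))
      else referenceGradeTable(sc)
      writeGradeTable(tab, file.path(config$outputDir,
                                     sprintf("grade_table_%s.json", sc)))
      tab
    })
    names(tabs) <- as.character(config$schemes)
    tabs
  })

  X <- stage("extract", stageSeed(seed, "extract"), {
    M <- extractFeatures(inputs$images, config = config$featureCfg)
    rownames(M) <- names(inputs$images)
    writeFeatures(M, file.path(config$outputDir, "features.csv"))
    M
  })

  datasets <- stage("label", seed, {
    idx <- match(rownames(X), inputs$assays$sample_id)
    stopifnot(!anyNA(idx))
    out <- lapply(tables, function(tab)
      LabeledDataset(X, factor(assignGrade(inputs$assays$pns[idx], tab),
                               levels = seq_len(gradeScheme(tab)))))
    out
  })

  grid <- stage("grid", seed, {
    g <- runGrid(datasets, schemes = names(datasets),
                 featureSets = config$featureSets,
                 algorithms = config$algorithms, seed = seed,
                 trainFraction = config$trainFraction,
                 threshold = config$threshold)
    utils::write.csv(g$table, file.path(config$outputDir, "grid.csv"),
                     row.names = FALSE)
    ok <- g$table[g$table$status == "ok", ]
    if (nrow(ok) == 0) stop("every grid cell failed")
    best <- ok[which.max(ok$accuracy), ]
    writeEvalReport(g$reports[[paste(best$scheme, best$featureSet,
                                     best$algorithm, sep = "/")]],
                    file.path(config$outputDir, "eval.json"))
    # persist the best cell's selection report
    sp <- stratifiedSplit(datasets[[as.character(best$scheme)]],
                          config$trainFraction,
                          seed = stageSeed(seed, "split"))
    writeSelection(selectFeatures(sp$train, best$featureSet,
                                  threshold = config$threshold,
                                  seed = stageSeed(seed, "select")),
                   file.path(config$outputDir, "selection.json"))
    list(grid = g, best = best)
  })

  if (isTRUE(config$pso$enabled)) {
    stage("tune", stageSeed(seed, "tune"), {
      best <- grid$best
      ds <- datasets[[as.character(best$scheme)]]
      sp <- stratifiedSplit(ds, config$trainFraction,
                            seed = stageSeed(seed, "split"))
      sel <- selectFeatures(sp$train, best$featureSet,
                            threshold = config$threshold,
                            seed = stageSeed(seed, "select"))
      alg <- if (algorithmRegistry()[[best$algorithm]]$backend == "xgboost")
        best$algorithm else "gbdt"
      tuned <- tuneModel(modelSpec(alg, seed = stageSeed(seed, "train")),
                         applySelection(sp$train, sel),
                         swarmSize = config$pso$swarmSize,
                         iterations = config$pso$iterations,
                         seed = stageSeed(seed, "tune"))
      writeTuningReport(tuned, paramBounds(),
                        file.path(config$outputDir, "tuning.json"))
      tuned
    })
  }

  if (isTRUE(config$cv$enabled)) {
    stage("cv", stageSeed(seed, "cv"), {
      best <- grid$best
      ds <- datasets[[as.character(best$scheme)]]
      res <- kfoldCV(modelSpec(best$algorithm,
                               seed = stageSeed(seed, "train")),
                     ds, k = config$cv$k, seed = stageSeed(seed, "cv"),
                     selection = if (best$featureSet == "ALL") NULL
                                 else best$featureSet)
      jsonlite::write_json(list(mean = as.list(res$mean),
                                sd = as.list(res$sd)),
                           file.path(config$outputDir, "cv.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  invisible(config$outputDir)
}
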