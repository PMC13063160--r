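#' @include AllClasses.R
NULL

#' Agglomerative clustering of assay values
#'
#' Average-linkage ("between-groups") agglomeration on squared Euclidean
#' distances between 1-D total-saponin values. Cuts of the dendrogram are
#' nested across K.
#'
#' @param pns numeric vector of total saponin contents (mg/g), or a
#'   data.frame with a `pns` column.
#' @param K number of clusters, `1 <= K <= n`.
#' @return list with `labels` (integer per-sample cluster index), `K`, and
#'   `linkage` (the `hclust` merge record).
#' @export
hcaCluster <- function(pns, K) {
  x <- if (is.data.frame(pns)) pns$pns else pns
  n <- length(x)
  if (K < 1 || K > n) stop("K must satisfy 1 <= K <= n")
  hc <- stats::hclust(stats::dist(x)^2, method = "average")
  list(labels = stats::cutree(hc, k = K), K = as.integer(K), linkage = hc)
}

#' Within-cluster sum-of-squares curve
#'
#' Total distortion J(K) = sum over clusters of squared deviations from the
#' cluster centroid, evaluated on the nested average-linkage cuts for
#' K = 1..Kmax.
#'
#' @param pns assay values as in [hcaCluster()].
#' @param Kmax largest cluster count to evaluate, `Kmax <= n`.
#' @return numeric vector `J` of length `Kmax` (named by K).
#' @export
wssCurve <- function(pns, Kmax) {
  x <- if (is.data.frame(pns)) pns$pns else pns
  if (Kmax > length(x)) stop("Kmax must not exceed the sample count")
  hc <- stats::hclust(stats::dist(x)^2, method = "average")
  J <- vapply(seq_len(Kmax), function(K) {
    lab <- stats::cutree(hc, k = K)
    sum(tapply(x, lab, function(v) sum((v - mean(v))^2)))
  }, 0)
  names(J) <- seq_len(Kmax)
  J
}

#' Export a WSS curve as CSV
#'
#' Two columns, `K` and `J`.
#'
#' @param J a [wssCurve()] result.
#' @param path CSV file path.
#' @export
writeWssCurve <- function(J, path) {
  utils::write.csv(data.frame(K = seq_along(J), J = unname(J)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Automated elbow detection on a WSS curve
#'
#' Ranks interior K by the second forward difference
#' `J(K-1) - 2 J(K) + J(K+1)` (largest = sharpest flattening) and returns
#' the top candidates. A flat or exactly linear curve has no elbow.
#'
#' @param J numeric WSS curve indexed K = 1..Kmax (length >= 4).
#' @param nElbows how many ranked candidates to return.
#' @return integer vector of candidate K values, best first (possibly
#'   empty, with a warning, for degenerate curves).
#' @export
detectElbows <- function(J, nElbows = 3) {
  if (length(J) < 4) stop("WSS curve must have at least 4 points")
  Ks <- 2:(length(J) - 1)
  d2 <- J[Ks - 1] - 2 * J[Ks] + J[Ks + 1]
  if (all(abs(d2) < max(1e-12, 1e-12 * max(abs(J))))) {
    warning("WSS curve is flat or linear; no elbow detected")
    return(integer(0))
  }
  ord <- order(-d2, Ks)
  utils::head(Ks[ord], nElbows)
}

#' Derive a grade-boundary table from assay values
#'
#' Clusters the assays at K, orders clusters by mean content (ascending =
#' grade 1..K) and places each internal boundary at the midpoint between
#' adjacent clusters, rounded to `digits`. Outer bounds are the observed
#' minimum and maximum. Intervals are lower-closed, upper-open; the top
#' interval is closed.
#'
#' @param pns assay values as in [hcaCluster()].
#' @param K number of grades.
#' @param digits rounding applied to boundaries (0 = integer mg/g, as in
#'   the shipped reference tables).
#' @return a [GradeTable-class].
#' @export
deriveGradeTable <- function(pns, K, digits = 0) {
  x <- if (is.data.frame(pns)) pns$pns else pns
  cl <- hcaCluster(x, K)
  mu <- tapply(x, cl$labels, mean)
  ord <- order(mu)  # cluster ids in ascending content order
  lo <- hi <- numeric(K)
  for (g in seq_len(K)) {
    v <- x[cl$labels == ord[g]]
    lo[g] <- min(v); hi[g] <- max(v)
  }
  if (K > 1 && any(hi[-K] >= lo[-1]))
    stop("clusters interleave along the content axis; cannot form bands")
  bounds <- numeric(K + 1)
  bounds[1] <- round(min(x), digits)
  bounds[K + 1] <- round(max(x), digits)
  if (K > 1)
    bounds[2:K] <- round((hi[-K] + lo[-1]) / 2, digits)
  if (any(diff(bounds) <= 0))
    stop("boundary rounding collapsed adjacent grades; increase 'digits'")
  GradeTable(K, data.frame(grade = seq_len(K),
                           lo = bounds[-(K + 1)], hi = bounds[-1]))
}

#' @describeIn assignGrade values below the table clamp to grade 1 and
#'   values above clamp to grade K (both reported via `message`); interval
#'   membership is lower-closed, upper-open, top interval closed.
#' @export
setMethod("assignGrade", signature(pns = "numeric", table = "GradeTable"),
  function(pns, table) {
    if (any(!is.finite(pns))) stop("assay values must be finite")
    r <- gradeRows(table)
    K <- nrow(r)
    breaks <- c(r$lo[1], r$hi)
    g <- findInterval(pns, breaks, rightmost.closed = TRUE)
    nClamped <- sum(g < 1 | g > K)
    if (nClamped > 0)
      message(sprintf("%d value(s) outside the table range clamped", nClamped))
    as.integer(pmin(pmax(g, 1L), K))
  })

#' Read / write grade tables as JSON
#'
#' The JSON schema is `{scheme, rows: [{grade, lo, hi}]}`; `readGradeTable`
#' also accepts a named list of such objects (as in the shipped reference
#' file) when `scheme` is given.
#'
#' @param table a [GradeTable-class].
#' @param path JSON file path.
#' @param scheme for `readGradeTable` on a multi-table file: which scheme
#'   to load (3, 5 or 6).
#' @return `readGradeTable` returns a [GradeTable-class].
#' @export
writeGradeTable <- function(table, path) {
  jsonlite::write_json(
    list(scheme = gradeScheme(table), rows = gradeRows(table)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGradeTable
#' @export
readGradeTable <- function(path, scheme = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$scheme)) {
    if (is.null(scheme))
      stop("file holds several tables; pass 'scheme' to pick one")
    obj <- obj[[as.character(scheme)]]
    if (is.null(obj)) stop("no table for scheme ", scheme, " in ", path)
  }
  if (!all(c("scheme", "rows") %in% names(obj)))
    stop("grade-table JSON is missing field 'scheme' or 'rows'")
  GradeTable(obj$scheme, obj$rows)
}

#' Reference grade tables for PNS content
#'
#' The published 3/5/6-grade boundary tables for total saponin content
#' (mg/g) shipped with the package.
#'
#' @param scheme 3, 5 or 6.
#' @return a [GradeTable-class].
#' @export
referenceGradeTable <- function(scheme = 3) {
  path <- system.file("extdata", "reference_grade_tables.json",
                      package = "PNSgrade", mustWork = TRUE)
  readGradeTable(path, scheme = scheme)
}
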