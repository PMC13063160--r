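test_that("average-linkage clustering on 1-D assays behaves at the margins", {
  x <- c(1, 2, 10, 11)
  cl <- hcaCluster(x, 2)
  expect_true(samePartition(cl$labels, c(1, 1, 2, 2)))
  expect_equal(length(unique(hcaCluster(x, 4)$labels)), 4)
  expect_equal(length(unique(hcaCluster(x, 1)$labels)), 1)
  expect_error(hcaCluster(x, 5), "K")
})

test_that("clustering matches the brute-force average-linkage oracle (n <= 8)", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(4:8, 1)
      x <- runif(n, 0, 100)
      K <- sample(2:(n - 1), 1)
    })
    expect_true(samePartition(hcaCluster(x, K)$labels,
                              bruteAverageLinkage(x, K)),
                info = sprintf("seed %d", seed))
  }
})

test_that("cuts are nested across K", {
  withr::with_seed(3, x <- runif(40, 54, 162))
  labs <- lapply(1:10, function(K) hcaCluster(x, K)$labels)
  for (K in 2:10) {
    # every cluster at K sits inside one cluster at K - 1
    tab <- table(labs[[K]], labs[[K - 1]])
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("the WSS curve follows its analytic values and monotonicity", {
  expect_equal(unname(wssCurve(c(0, 2), 1)), 2)  # (0-1)^2 + (2-1)^2
  withr::with_seed(4, x <- runif(30, 0, 10))
  J <- wssCurve(x, 30)
  expect_equal(unname(J[30]), 0)
  expect_true(all(diff(J) <= 1e-9))
  expect_true(all(J >= -1e-12))
})

test_that("elbow detection ranks by second difference and rejects flat curves", {
  expect_warning(e <- detectElbows(c(10, 8, 6, 4, 2)), "flat or linear")
  expect_length(e, 0)
  # piecewise-linear curve with a single sharp kink at K = 4
  J <- c(100, 80, 60, 40, 38, 36, 34)
  expect_equal(detectElbows(J, 1), 4L)
  # three well-separated 1-D Gaussians, middle-heavy occupancy
  withr::with_seed(8, x <- c(rnorm(20, 10, 1), rnorm(80, 50, 1), rnorm(35, 90, 1)))
  expect_equal(detectElbows(wssCurve(x, 10), 1), 3L)
})

test_that("grade tables use midpoint boundaries, observed extremes, contiguity", {
  # low cluster tops out at 100, high cluster starts at 110 -> boundary 105
  x <- c(96, 98, 100, 110, 112, 114)
  tab <- deriveGradeTable(x, 2)
  r <- gradeRows(tab)
  expect_equal(r$lo, c(96, 105))
  expect_equal(r$hi, c(105, 114))
  t1 <- deriveGradeTable(x, 1)
  expect_equal(gradeRows(t1)$lo, 96)
  expect_equal(gradeRows(t1)$hi, 114)
  withr::with_seed(5, x2 <- runif(60, 54, 162))
  for (K in c(3, 5, 6)) {
    rr <- gradeRows(deriveGradeTable(x2, K))
    expect_equal(nrow(rr), K)
    expect_equal(rr$lo[-1], rr$hi[-K])           # contiguous
    expect_true(all(diff(c(rr$lo, rr$hi[K])) > 0))  # strictly increasing
  }
})

test_that("grade assignment honors the published boundary tables", {
  ref3 <- referenceGradeTable(3)
  expect_equal(assignGrade(90, ref3), 1L)
  expect_equal(assignGrade(130, ref3), 3L)
  expect_equal(assignGrade(101, ref3), 2L)  # shared endpoint: lower-closed
  expect_equal(assignGrade(162, ref3), 3L)  # top interval closed
  expect_message(g <- assignGrade(c(10, 500), ref3), "clamped")
  expect_equal(g, c(1L, 3L))
  expect_error(assignGrade(NaN, ref3), "finite")
  # monotone in content
  withr::with_seed(6, v <- sort(runif(50, 40, 180)))
  expect_true(!is.unsorted(suppressMessages(assignGrade(v, ref3))))
})

test_that("derive-then-assign reproduces each sample's own cluster rank", {
  withr::with_seed(7, x <- c(runif(20, 54, 80), runif(20, 100, 120),
                             runif(20, 140, 162)))
  K <- 3
  tab <- deriveGradeTable(x, K)
  cl <- hcaCluster(x, K)
  rank <- match(cl$labels, order(tapply(x, cl$labels, mean)))
  expect_equal(assignGrade(x, tab), as.integer(rank))
})

test_that("WSS curves export to a two-column CSV", {
  J <- wssCurve(c(1, 2, 10, 11, 30), 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeWssCurve(J, path)
  df <- read.csv(path)
  expect_identical(names(df), c("K", "J"))
  expect_equal(df$J, unname(J))
})

test_that("grade tables survive a JSON round-trip", {
  tab <- deriveGradeTable(c(54, 60, 100, 110, 150, 162), 3)
  path <- withr::local_tempfile(fileext = ".json")
  writeGradeTable(tab, path)
  rt <- readGradeTable(path)
  expect_equal(gradeScheme(rt), gradeScheme(tab))
  expect_equal(gradeRows(rt), gradeRows(tab))
  expect_error(readGradeTable(withr::local_tempfile(lines = "{\"rows\": []}",
                                                    fileext = ".json")),
               "scheme")
})
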