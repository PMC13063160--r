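test_that("assay draws stay in range and are seed-deterministic", {
  model <- assayModel()
  t1 <- genPNS(500, model, seed = 2)
  t2 <- genPNS(500, model, seed = 2)
  expect_identical(t1, t2)
  expect_true(all(t1$pns >= 54 & t1$pns <= 162))
  expect_false(anyDuplicated(t1$sample_id) > 0)
  # degenerate spread collapses to the mean
  expect_true(all(genPNS(50, assayModel(sd = 0), seed = 1)$pns == 97.3))
  expect_error(assayModel(range = c(162, 54)), "truncation")
  expect_error(mixtureAssayModel(weights = c(0.5, 0.4)), "length|sum")
})

test_that("the calibrated generator reproduces the assay statistics", {
  model <- assayModel()
  # truncated-distribution calibration hits the printed mean and sd
  expect_equal(unname(model$truncated["mean"]), 97.3, tolerance = 1e-6)
  expect_equal(unname(model$truncated["sd"]), 25.9, tolerance = 1e-6)
  v <- genPNS(10000, model, seed = 1)$pns
  expect_lt(abs(mean(v) - 97.3), 0.8)
  expect_lt(abs(stats::median(v) - unname(model$truncated["median"])), 2)
  expect_lt(abs(sd(v) - 25.9), 1)
})

test_that("sample moments converge toward the model mean", {
  for (n in c(100, 1000, 10000)) {
    v <- genPNS(n, assayModel(), seed = 4)$pns
    expect_lt(abs(mean(v) - 97.3), 3 * 25.9 / sqrt(n) + 0.1,
              label = sprintf("n = %d deviation", n))
  }
})

test_that("synthetic slices satisfy the image invariants", {
  img <- genSliceImage(100, seed = 5, size = 48)
  expect_s4_class(img, "SliceImage")
  expect_true(validObject(img))
  m <- sliceMask(img)
  expect_gt(mean(m), 0.1)
  expect_lt(mean(m), 0.9)
  expect_error(genSliceImage(100, size = 16), "at least 32")
  # bit-reproducible render at zero pixel noise
  app <- appearanceModel(noiseSd = 0)
  expect_identical(pixels(genSliceImage(80, app, seed = 6)),
                   pixels(genSliceImage(80, app, seed = 6)))
})

test_that("opposite assay extremes separate in mean hue by > 5 noise sigma", {
  mu <- function(pns, seeds) vapply(seeds, function(s)
    colorMoments(genSliceImage(pns, size = 48, seed = s))[["color_mu_H"]], 0)
  lo <- mu(60, 1:15)
  hi <- mu(155, 101:115)
  pooled <- sqrt((var(lo) + var(hi)) / 2)
  expect_gt(abs(mean(lo) - mean(hi)), 5 * pooled)
})

test_that("generated datasets are label-consistent end to end", {
  sim <- genDataset(12, scheme = 3, seed = 7, size = 32)
  expect_equal(nrow(features(sim$dataset)), 12)
  expect_equal(ncol(features(sim$dataset)), 113)
  relabel <- assignGrade(sim$assays$pns, sim$gradeTable)
  expect_equal(as.integer(as.character(grades(sim$dataset))), relabel)
  expect_identical(names(sim$images), sim$assays$sample_id)
})

test_that("a three-component mixture yields a three-elbow WSS curve", {
  pns <- genPNS(143, mixtureAssayModel(), seed = 7)
  expect_true(all(pns$pns >= 54 & pns$pns <= 162))
  top <- detectElbows(wssCurve(pns, 10), 1)
  expect_equal(top, 3L)
})
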