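# Phantom generator: symmetry, calibration inversion, rasterization accuracy,
# dataset reproducibility, rater simulation.

test_that("zero-rotation phantom is symmetric with zero asymmetry", {
  s <- testPhantom(0)
  a <- asymmetry(truth(s))
  expect_identical(aofw(a), 0)
  expect_identical(aofa(a), 0)
  expect_identical(aiww(a), 0)
  g <- maskGrid(phantomMasks(s)$left)
  gr <- maskGrid(phantomMasks(s)$right)
  expect_identical(g, gr[, rev(seq_len(ncol(gr)))])
})

test_that("asymmetry response inverts the rotation calibrations exactly", {
  s <- testPhantom(5)
  a <- asymmetry(truth(s))
  expect_equal(aofw(a), (5 + 0.912) / 1.644, tolerance = 1e-12)
  expect_equal(degrees(rotationFromAOFW(aofw(a))), 5, tolerance = 1e-12)
  expect_equal(degrees(rotationFromAIWW(aiww(a))), 5, tolerance = 1e-12)
  # iliac asymmetry clamps to zero below the AIWW zero crossing
  s2 <- generatePhantom(phantomSpec(rotationDeg = 0.05, profile = "test",
                                    noiseSD = 0))
  expect_identical(aiww(asymmetry(truth(s2))), 0)
})

test_that("phantom at -theta is the mirror image of +theta and AOFA flips sign", {
  sp <- testPhantom(6)
  sm <- testPhantom(-6)
  gl <- maskGrid(phantomMasks(sp)$left)
  gr <- maskGrid(phantomMasks(sm)$right)
  expect_identical(gl, gr[, rev(seq_len(ncol(gr)))])
  expect_equal(aofa(asymmetry(truth(sp)), signed = TRUE),
               -aofa(asymmetry(truth(sm)), signed = TRUE), tolerance = 1e-12)
  expect_equal(phantomImage(sp), phantomImage(sm)[, rev(seq_len(128))],
               tolerance = 1e-12)
})

test_that("rasterized mask area matches the analytic ellipse area within 2%", {
  for (theta in c(0, 4, 9)) {
    s <- generatePhantom(phantomSpec(rotationDeg = theta, profile = "full",
                                     noiseSD = 0))
    for (side in c("left", "right")) {
      analytic <- foramen(truth(s), side)$areaMM2
      rasterized <- maskArea(phantomMasks(s)[[side]])
      expect_lt(abs(rasterized - analytic) / analytic, 0.02)
    }
  }
})

test_that("mask-measured widths stay within one pixel spacing of truth", {
  for (theta in c(0, 2, 5, 9)) {
    s <- generatePhantom(phantomSpec(rotationDeg = theta, profile = "full",
                                     noiseSD = 0))
    m <- measurePelvis(phantomMasks(s)$left, phantomMasks(s)$right)
    for (side in c("left", "right")) {
      expect_lt(abs(foramen(m, side)$maxWidthMM -
                    foramen(truth(s), side)$maxWidthMM),
                1.0001 * pixelSpacing(s))
    }
  }
})

test_that("out-of-bounds and degenerate parameterizations are rejected", {
  expect_error(phantomSpec(foramenCenterOffset = 40, profile = "test"),
               "fit")
  expect_error(generatePhantom(phantomSpec(rotationDeg = 90, profile = "test",
                                           foramenSemiAxisA = 9,
                                           foramenSemiAxisB = 9)),
               "negative|bounds|overlap")
  expect_error(phantomSpec(foramenSemiAxisA = 5, foramenSemiAxisB = 9),
               "semiAxis")
  expect_error(phantomSpec(noiseSD = -1), "noiseSD")
})

test_that("generateDataset is reproducible and writes a complete tree", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateDataset(10, phantomSpec(profile = "test"), seed = 7, outDir = d1)
  generateDataset(10, phantomSpec(profile = "test"), seed = 7, outDir = d2)
  t1 <- readBin(file.path(d1, "truth.csv"), "raw", 1e6)
  t2 <- readBin(file.path(d2, "truth.csv"), "raw", 1e6)
  expect_identical(t1, t2)
  expect_length(list.files(file.path(d1, "images")), 10L)
  expect_length(list.files(file.path(d1, "masks")), 20L)
  expect_length(list.files(file.path(d1, "annotations")), 10L)
  # n = 1 cardinality
  d3 <- withr::local_tempdir()
  ds <- generateDataset(1, phantomSpec(profile = "test"), seed = 1,
                        outDir = d3)
  expect_length(list.files(file.path(d3, "images")), 1L)
  expect_length(list.files(file.path(d3, "annotations")), 1L)
  expect_identical(nrow(ds$truth), 1L)
})

test_that("rotation-linked asymmetry makes theta and |AOFA| strongly correlated", {
  ds <- generateDataset(200, phantomSpec(profile = "test", noiseSD = 0),
                        rotationRange = c(0, 10), seed = 21)
  tt <- ds$truth
  r <- cor(tt$rotation_deg, abs(tt$area_left_mm2 - tt$area_right_mm2))
  expect_gt(r, 0.95)
})

test_that("simulateRater reproduces its bias and collapses cleanly at zero error", {
  perfect <- simulateRater(c(10, 20, 30), bias = 0, errorSD = 0, seed = 1)
  expect_identical(perfect$true, perfect$rated)
  biased <- simulateRater(rep(50, 4), bias = 10, errorSD = 0, seed = 1)
  ba <- blandAltman(a = biased$rated, b = biased$true)
  expect_equal(ba$loaLow, 10, tolerance = 1e-12)
  expect_equal(ba$loaHigh, 10, tolerance = 1e-12)
  # Monte-Carlo at the scale of a published model-vs-examiner comparison
  set.seed(33)
  truthVals <- runif(2000, 0, 200)
  paired <- simulateRater(truthVals, bias = 5.59, errorSD = 16.38, seed = 9)
  ba2 <- blandAltman(a = paired$rated, b = paired$true)
  expect_lt(abs(ba2$meanDiff - 5.59), 1)
  expect_lt(abs(ba2$loaLow - (-26.51)), 2.5)
  expect_lt(abs(ba2$loaHigh - 37.69), 2.5)
  expect_error(simulateRater(numeric(0)), "nonempty")
})
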