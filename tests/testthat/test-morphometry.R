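# Morphometry: shoelace areas, rasterization, widths, iliac distances,
# asymmetry conventions, and scaling laws.

test_that("polygonArea handles squares, orientation, and ellipse approximations", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(polygonArea(sq, 1), 1)
  expect_identical(polygonArea(sq[4:1, ], 1), 1)
  # 360-gon vs closed-form ellipse area, a = 20 px, b = 10 px, spacing 0.5
  poly <- ellipsePoly(50, 50, 20, 10, 360L)
  expect_lt(abs(polygonArea(poly, 0.5) - pi * 10 * 5) / (pi * 10 * 5), 0.001)
  # invalid geometry
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1)), 1), "3 vertices")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(polygonArea(bowtie, 1), "self-intersecting")
})

test_that("rasterizePolygon follows the pixel-center-inside rule", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  m <- rasterizePolygon(sq, c(10, 10), 1)
  expect_identical(sum(maskGrid(m)), 16L)  # centers 0..3 in each axis
  expect_true(all(maskGrid(m)[1:4, 1:4]))
  expect_error(rasterizePolygon(rbind(c(1, 1), c(3, 3), c(5, 5)), c(10, 10), 1),
               "degenerate|zero-area")
  expect_error(rasterizePolygon(sq + 20, c(10, 10), 1), "bounds")
  # ellipse: rasterized area within 2% of the shoelace area at 0.2 mm
  poly <- ellipsePoly(100, 100, 60, 45, 180L)
  pa <- polygonArea(poly, 0.2)
  ma <- maskArea(rasterizePolygon(poly, c(200, 200), 0.2))
  expect_lt(abs(ma - pa) / pa, 0.02)
})

test_that("maskArea multiplies pixel counts by pixel area and rejects empties", {
  g <- matrix(FALSE, 4, 4); g[seq_len(10)] <- TRUE
  expect_identical(maskArea(binaryMask(g, 0.5)), 10 * 0.25)
  expect_error(maskArea(binaryMask(matrix(FALSE, 3, 3), 1)), "empty")
  # brute-force loop oracle on a random mask
  set.seed(5)
  rg <- matrix(runif(400) > 0.6, 20, 20)
  cnt <- 0L
  for (i in 1:20) for (j in 1:20) if (rg[i, j]) cnt <- cnt + 1L
  expect_identical(maskArea(binaryMask(rg, 0.3)), cnt * 0.09)
})

test_that("maxHorizontalWidth uses the inclusive extent with first-row ties", {
  g <- matrix(FALSE, 8, 14); g[3:6, 3:12] <- TRUE  # 10 x 4 px rectangle
  r <- maxHorizontalWidth(binaryMask(g, 0.5))
  expect_identical(r$widthMM, 5)
  expect_identical(r$chord[1, 2], 2)  # first widest row (0-based row 2)
  # ellipse mask: a = 20 px horizontal semi-axis -> 2a+1 pixel convention
  poly <- ellipsePoly(30, 30, 20, 10, 360L)
  em <- rasterizePolygon(poly, c(60, 60), 0.5)
  ew <- maxHorizontalWidth(em)$widthMM
  expect_lte(abs(ew - 20.5), 0.5)
  # axis exchange: transposing the region exchanges width and height
  gt <- t(g)
  expect_identical(maxHorizontalWidth(binaryMask(gt, 0.5))$widthMM, 2)
  expect_error(maxHorizontalWidth(binaryMask(matrix(FALSE, 3, 3), 1)), "empty")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(maxHorizontalWidth(binaryMask(two, 1)), "components")
  # polygon path: exact boundary extent, no +1 convention
  pw <- maxHorizontalWidth(poly, 0.5)
  expect_equal(pw$widthMM, 20, tolerance = 1e-9)
})

test_that("iliacWidth is a symmetric Euclidean distance in mm", {
  expect_identical(iliacWidth(c(0, 0), c(3, 4), 1), 5)
  expect_identical(iliacWidth(c(0, 0), c(10, 0), 0.2), 2)
  expect_identical(iliacWidth(c(3, 4), c(0, 0), 1),
                   iliacWidth(c(0, 0), c(3, 4), 1))
  expect_error(iliacWidth(c(1, 1), c(1, 1), 1), "coincide")
})

test_that("asymmetry is signed left-minus-right and antisymmetric under side swap", {
  s <- testPhantom(5)
  tr <- truth(s)
  a <- asymmetry(tr)
  expect_equal(aofa(a, signed = TRUE),
               foramen(tr, "left")$areaMM2 - foramen(tr, "right")$areaMM2)
  expect_identical(aofa(a), abs(aofa(a, signed = TRUE)))
  # swap sides by mirroring the generating rotation
  am <- asymmetry(truth(testPhantom(-5)))
  expect_equal(aofa(am, signed = TRUE), -aofa(a, signed = TRUE),
               tolerance = 1e-12)
  expect_equal(aofw(am, signed = TRUE), -aofw(a, signed = TRUE),
               tolerance = 1e-12)
  expect_equal(aiww(am, signed = TRUE), -aiww(a, signed = TRUE),
               tolerance = 1e-12)
})

test_that("missing iliac landmarks flag AIWW unavailable instead of zero", {
  s <- testPhantom(3)
  m <- measurePelvis(phantomMasks(s)$left, phantomMasks(s)$right)
  a <- asymmetry(m)
  expect_false(aiwwAvailable(a))
  expect_identical(aiww(a), NA_real_)
})

test_that("areas scale as spacing^2 and widths as spacing", {
  poly <- ellipsePoly(30, 30, 15, 8, 90L)
  expect_equal(polygonArea(poly, 0.6), polygonArea(poly, 0.2) * 9,
               tolerance = 1e-12)
  expect_equal(maxHorizontalWidth(poly, 0.6)$widthMM,
               maxHorizontalWidth(poly, 0.2)$widthMM * 3, tolerance = 1e-12)
  g <- rasterizePolygon(poly, c(60, 60), 1)
  expect_equal(maskArea(binaryMask(maskGrid(g), 0.4)),
               maskArea(binaryMask(maskGrid(g), 0.2)) * 4, tolerance = 1e-12)
})

test_that("polygon and mask areas agree within discretization tolerance", {
  s <- testPhantom(4)
  polyArea <- polygonArea(annotation(s)$left, pixelSpacing(s))
  mskArea <- maskArea(phantomMasks(s)$left)
  expect_lt(abs(polyArea - mskArea) / polyArea, 0.03)
})
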