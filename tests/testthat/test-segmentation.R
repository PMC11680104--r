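# Segmentation: splits, augmentation, Dice/IoU algebra, the network's
# forward/backward consistency, seeded training determinism, prediction and
# evaluation plumbing.

test_that("splitDataset partitions deterministically with the documented sizes", {
  sp <- splitDataset(1:312, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp), c(train = 248L, val = 32L, test = 32L))
  expect_identical(sort(unname(unlist(sp))), 1:312)
  sp2 <- splitDataset(1:312, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(sp, sp2)
  small <- splitDataset(1:10, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(lengths(small), c(train = 8L, val = 1L, test = 1L))
  expect_error(splitDataset(1:2, c(0.8, 0.1, 0.1)), "fewer items")
  expect_error(splitDataset(c(1, 1, 2), c(0.8, 0.1, 0.1)), "unique")
})

test_that("augmentation is identity at prob 0, involutive for flips, and area-safe", {
  s <- testPhantom(4)
  img <- phantomImage(s)
  msk <- maskGrid(phantomMasks(s)$left) | maskGrid(phantomMasks(s)$right)
  a0 <- augmentSample(img, msk, prob = 0, seed = 1)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)
  f1 <- augmentSample(img, msk, prob = 1, transforms = "flip", seed = 2)
  f2 <- augmentSample(f1$image, f1$mask, prob = 1, transforms = "flip",
                      seed = 3)
  expect_identical(f2$image, img)
  expect_identical(f2$mask, msk)
  # rigid rotation preserves interior mask pixel counts within 5%
  r <- augmentSample(img, msk, prob = 1, transforms = "rotate", seed = 4)
  expect_lt(abs(sum(r$mask) - sum(msk)) / sum(msk), 0.05)
  expect_true(is.logical(r$mask))
  expect_error(augmentSample(img, msk[1:10, ], prob = 0.5), "shapes differ")
})

test_that("Dice and IoU satisfy their defining algebra", {
  g <- matrix(FALSE, 10, 10); g[2:5, 2:5] <- TRUE
  h <- matrix(FALSE, 10, 10); h[4:7, 4:7] <- TRUE
  expect_identical(diceScore(g, g), 1)
  expect_identical(iouScore(g, g), 1)
  disj <- matrix(FALSE, 10, 10); disj[8:9, 8:9] <- TRUE
  expect_identical(diceScore(g, disj), 0)
  # |A| = |B| = 100, |A n B| = 50 -> dice 0.5, iou 1/3
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[1:10, 6:15] <- TRUE
  expect_equal(diceScore(a, b), 0.5)
  expect_equal(iouScore(a, b), 1 / 3)
  # identity dice = 2 iou / (1 + iou), symmetry, bounds on random pairs
  set.seed(6)
  for (i in 1:20) {
    x <- matrix(runif(100) > 0.5, 10, 10)
    y <- matrix(runif(100) > 0.5, 10, 10)
    d <- diceScore(x, y); j <- iouScore(x, y)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_identical(d, diceScore(y, x))
    expect_true(d >= 0 && d <= 1 && j <= d)
  }
  empty <- matrix(FALSE, 5, 5)
  expect_identical(diceScore(empty, empty), 1)
  expect_identical(iouScore(empty, empty), 1)
  expect_error(diceScore(g, matrix(FALSE, 5, 5)), "shapes differ")
})

test_that("network gradients match numerical differentiation", {
  C <- 4L
  np <- pelviQC:::cpp_unet_nparams(C)
  set.seed(2)
  p <- rnorm(np, 0, 0.3)
  img <- matrix(runif(16 * 16), 16, 16)
  msk <- matrix(rbinom(256, 1, 0.3), 16, 16)
  g <- pelviQC:::cpp_unet_grad(img, msk, p, C, 1.0)
  idx <- sample(np, 20)
  eps <- 1e-6
  num <- sapply(idx, function(i) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    (pelviQC:::cpp_unet_grad(img, msk, p1, C, 1)$loss -
       pelviQC:::cpp_unet_grad(img, msk, p2, C, 1)$loss) / (2 * eps)
  })
  expect_lt(max(abs(num - g$grad[idx]) / (abs(num) + 1e-8)), 1e-5)
})

test_that("training is deterministic under a fixed seed and validates its config", {
  ds <- generateDataset(24, phantomSpec(profile = "test",
                                        imageSize = c(64L, 64L),
                                        pixelSpacing = 1.4),
                        seed = 13)
  cfg <- segmentationConfig(inputSize = 64L, maxEpochs = 3L,
                            earlyStopPatience = 3L, batchSize = 4L, seed = 5L)
  s1 <- trainSegmenter(ds$samples, cfg)
  s2 <- trainSegmenter(ds$samples, cfg)
  expect_identical(trainingHistory(s1)$loss, trainingHistory(s2)$loss)
  expect_identical(trainingHistory(s1)$val_dice, trainingHistory(s2)$val_dice)
  expect_identical(s1@params, s2@params)
  expect_error(segmentationConfig(maxEpochs = 0L), "maxEpochs")
  expect_error(segmentationConfig(splitFractions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(trainSegmenter(ds$samples[1:2],
                              segmentationConfig(inputSize = 64L,
                                                 splitFractions = c(1, 0, 0))),
               "validation")
})

test_that("prediction fails loudly without two usable components", {
  ds <- generateDataset(24, phantomSpec(profile = "test",
                                        imageSize = c(64L, 64L),
                                        pixelSpacing = 1.4),
                        seed = 13)
  cfg <- segmentationConfig(inputSize = 64L, maxEpochs = 1L, seed = 5L)
  seg <- trainSegmenter(ds$samples, cfg)
  # an untrained/1-epoch net on a blank image: all background
  blank <- matrix(0.5, 64, 64)
  expect_error(predictMasks(seg, blank, 1.4), "segmentation failure")
  # evaluateSegmenter reports failures instead of crashing
  rep <- evaluateSegmenter(seg, list(bad = list(image = blank,
                                                maskLeft = matrix(FALSE, 64, 64),
                                                maskRight = matrix(FALSE, 64, 64),
                                                pixelSpacing = 1.4)))
  expect_identical(rep@nFailed, 1L)
  expect_identical(perImage(rep)$status, "failed")
})

test_that("an oracle predictor evaluates to perfect Dice and IoU", {
  ds <- generateDataset(4, phantomSpec(profile = "test"), seed = 17)
  oracle <- function(image, spacing) {
    i <- which(vapply(ds$samples, function(s)
      identical(phantomImage(s), image), logical(1)))
    phantomMasks(ds$samples[[i]])
  }
  rep <- evaluateSegmenter(oracle, ds$samples)
  expect_equal(meanDice(rep), 1)
  expect_equal(meanIoU(rep), 1)
  expect_identical(rep@nFailed, 0L)
})
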