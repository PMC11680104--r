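# Segmentation: a compact trainable encoder-decoder network (one-level
# U-Net, see src/unet.cpp), dataset splitting, augmentation, training with
# Adam on a compound soft-Dice + cross-entropy loss, prediction with
# connected-component side assignment, and Dice/IoU evaluation.

#' Construct a SegmentationConfig
#'
#' @param inputSize square resize target in px (even). 448 matches clinical
#'   preprocessing; test-scale runs use 128.
#' @param encoderScale "small" (base width 8; trains on a CPU in minutes) or
#'   "large" (base width 32, a larger-capacity variant of the same
#'   architecture).
#' @param learningRate Adam learning rate.
#' @param batchSize images per optimizer step.
#' @param augmentProb per-transform augmentation probability during training.
#' @param maxEpochs,earlyStopPatience schedule; training stops early after
#'   \code{earlyStopPatience} epochs without validation-Dice improvement.
#' @param splitFractions train/val/test fractions (sum 1).
#' @param probThreshold probability cut for binarizing predictions.
#' @param minComponentPx smallest connected component kept at prediction.
#' @param diceWeight weight of the soft-Dice loss term.
#' @param seed integer RNG seed (init, split, shuffling, augmentation).
#' @return A \linkS4class{SegmentationConfig}.
#' @export
segmentationConfig <- function(inputSize = 448L, encoderScale = "small",
                               learningRate = 0.001, batchSize = 8L,
                               augmentProb = 0.5, maxEpochs = 25L,
                               earlyStopPatience = 5L,
                               splitFractions = c(0.8, 0.1, 0.1),
                               probThreshold = 0.5, minComponentPx = 20L,
                               diceWeight = 1.0, seed = 1L) {
  if (maxEpochs < 1) stop("maxEpochs must be >= 1")
  new("SegmentationConfig", inputSize = as.integer(inputSize),
      encoderScale = encoderScale, learningRate = learningRate,
      batchSize = as.integer(batchSize), augmentProb = augmentProb,
      maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      splitFractions = splitFractions, probThreshold = probThreshold,
      minComponentPx = as.integer(minComponentPx), diceWeight = diceWeight,
      seed = as.integer(seed))
}

.encoderWidth <- function(scale) if (scale == "large") 32L else 8L

# He-normal initialization matching the parameter layout in src/unet.cpp
.unetInit <- function(C, seed) {
  sizes <- c(9L * C, C, 9L * C * 2L * C, 2L * C, 9L * 3L * C * C, C, C, 1L)
  fanin <- c(9 * 1, NA, 9 * C, NA, 9 * 3 * C, NA, C, NA)
  .withSeed(seed, {
    unlist(lapply(seq_along(sizes), function(i) {
      if (is.na(fanin[i])) numeric(sizes[i])            # biases start at 0
      else rnorm(sizes[i], 0, sqrt(2 / fanin[i]))
    }))
  })
}

#' Split item ids into train/validation/test sets
#'
#' Deterministic under the seed; partitions are disjoint and exhaustive.
#' Validation and test receive \code{ceiling(fraction * n)} items each, the
#' training set the remainder (312 items at 0.8/0.1/0.1 give 248/32/32).
#'
#' @param items vector of unique ids.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer.
#' @return list with \code{train}, \code{val}, \code{test}.
#' @examples
#' lengths(splitDataset(1:312, c(0.8, 0.1, 0.1), seed = 1))  # 248 32 32
#' @export
splitDataset <- function(items, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(items)
  if (anyDuplicated(items)) stop("item ids must be unique")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0))
    stop("fractions must be 3 non-negative values summing to 1")
  ngroups <- sum(fractions > 0)
  if (n < ngroups) stop("fewer items (", n, ") than nonempty groups (", ngroups, ")")
  nVal <- if (fractions[2] > 0) ceiling(fractions[2] * n) else 0L
  nTest <- if (fractions[3] > 0) ceiling(fractions[3] * n) else 0L
  if (nVal + nTest >= n && fractions[1] > 0)
    stop("fractions leave no training items for n = ", n)
  perm <- .withSeed(seed, sample(n))
  idx <- items[perm]
  list(train = idx[seq_len(n - nVal - nTest)],
       val = if (nVal) idx[n - nVal - nTest + seq_len(nVal)] else items[0],
       test = if (nTest) idx[n - nTest + seq_len(nTest)] else items[0])
}

#' Randomly augment an image/mask pair
#'
#' Each member of the transform family (horizontal flip, rotation within
#' +/-15 degrees, brightness shift within +/-20%, contrast scale within
#' +/-20%) is applied independently with probability \code{prob}. Geometric
#' transforms are applied identically to image and mask; the mask is
#' resampled nearest-neighbour so it stays binary.
#'
#' @param image numeric matrix in [0, 1].
#' @param mask logical matrix, same shape.
#' @param prob per-transform probability.
#' @param transforms subset of c("flip", "rotate", "brightness", "contrast").
#' @param seed optional seed for reproducible augmentation.
#' @return list with \code{image}, \code{mask}, \code{applied}.
#' @export
augmentSample <- function(image, mask, prob = 0.5,
                          transforms = c("flip", "rotate", "brightness",
                                         "contrast"),
                          seed = NULL) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  transforms <- match.arg(transforms, several.ok = TRUE)
  run <- function() {
    applied <- character(0)
    m <- mask
    if ("flip" %in% transforms && runif(1) < prob) {
      image <- image[, rev(seq_len(ncol(image)))]
      m <- m[, rev(seq_len(ncol(m)))]
      applied <- c(applied, "flip")
    }
    if ("rotate" %in% transforms && runif(1) < prob) {
      ang <- runif(1, -15, 15)
      image <- .rotateMatrix(image, ang, "bilinear", bg = image[1, 1])
      m <- .rotateMatrix(m * 1, ang, "nearest", bg = 0) > 0.5
      applied <- c(applied, sprintf("rotate(%.2f)", ang))
    }
    if ("brightness" %in% transforms && runif(1) < prob) {
      image <- pmin(pmax(image + runif(1, -0.2, 0.2), 0), 1)
      applied <- c(applied, "brightness")
    }
    if ("contrast" %in% transforms && runif(1) < prob) {
      mu <- mean(image)
      image <- pmin(pmax(mu + (image - mu) * runif(1, 0.8, 1.2), 0), 1)
      applied <- c(applied, "contrast")
    }
    list(image = image, mask = m, applied = applied)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

.minmax <- function(m) {
  rg <- range(m)
  if (rg[2] - rg[1] < 1e-12) return(m * 0)
  (m - rg[1]) / (rg[2] - rg[1])
}

# pull (image, union mask) pairs from PhantomSamples or plain lists
.asTrainingPairs <- function(samples, inputSize) {
  lapply(samples, function(s) {
    if (is(s, "PhantomSample")) {
      img <- phantomImage(s)
      mk <- phantomMasks(s)
      msk <- maskGrid(mk$left) | maskGrid(mk$right)
    } else {
      img <- s$image
      msk <- s$mask
      if (is(msk, "BinaryMask")) msk <- maskGrid(msk)
    }
    if (!is.logical(msk)) {
      if (!all(msk %in% c(0, 1))) stop("masks must be binary")
      msk <- msk > 0.5
    }
    if (!all(dim(img) == c(inputSize, inputSize))) {
      img <- .resizeMatrix(img, inputSize, inputSize, "bilinear")
      msk <- .resizeMatrix(msk * 1, inputSize, inputSize, "nearest") > 0.5
    }
    list(image = .minmax(img), mask = msk)
  })
}

#' Train the segmentation network
#'
#' Splits the samples (per \code{splitFractions}), optimizes the compound
#' soft-Dice + pixel-wise cross-entropy loss with Adam, applies augmentation
#' to training images each epoch, and keeps the weights of the epoch with the
#' best validation Dice. Fully deterministic under the config seed.
#'
#' @param samples list of \linkS4class{PhantomSample} or of
#'   \code{list(image=, mask=)} pairs.
#' @param config a \linkS4class{SegmentationConfig}.
#' @param quiet suppress per-epoch progress messages.
#' @return A \linkS4class{TrainedSegmenter}.
#' @export
trainSegmenter <- function(samples, config = segmentationConfig(),
                           quiet = TRUE) {
  validObject(config)
  split <- splitDataset(seq_along(samples), config@splitFractions,
                        config@seed)
  if (length(split$train) == 0L || length(split$val) == 0L)
    stop("training requires nonempty train and validation splits")
  pairs <- .asTrainingPairs(samples, config@inputSize)
  tr <- pairs[split$train]; va <- pairs[split$val]
  C <- .encoderWidth(config@encoderScale)
  params <- .unetInit(C, config@seed)

  mAdam <- vAdam <- numeric(length(params))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tAdam <- 0
  lr <- config@learningRate

  valDice <- function(p) {
    mean(vapply(va, function(s) {
      pred <- cpp_unet_forward(s$image, p, C) >= config@probThreshold
      .dice(pred, s$mask)
    }, numeric(1)))
  }

  best <- list(params = params, dice = -Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_dice = numeric(0))
  sinceBest <- 0L
  .withSeed(config@seed + 1L, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(length(tr))
      epochLoss <- 0
      nb <- 0L
      for (b0 in seq(1, length(ord), by = config@batchSize)) {
        bidx <- ord[b0:min(b0 + config@batchSize - 1, length(ord))]
        gacc <- numeric(length(params))
        lacc <- 0
        for (i in bidx) {
          s <- tr[[i]]
          if (config@augmentProb > 0) {
            s <- augmentSample(s$image, s$mask, config@augmentProb)
          }
          res <- cpp_unet_grad(s$image, s$mask * 1, params, C,
                               config@diceWeight)
          gacc <- gacc + as.numeric(res$grad)
          lacc <- lacc + res$loss
        }
        g <- gacc / length(bidx)
        tAdam <- tAdam + 1
        mAdam <- b1 * mAdam + (1 - b1) * g
        vAdam <- b2 * vAdam + (1 - b2) * g^2
        params <- params - lr * (mAdam / (1 - b1^tAdam)) /
          (sqrt(vAdam / (1 - b2^tAdam)) + epsA)
        epochLoss <- epochLoss + lacc / length(bidx)
        nb <- nb + 1L
      }
      vd <- valDice(params)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epochLoss / nb,
                                     val_dice = vd))
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f, val Dice %.4f", epoch,
                        epochLoss / nb, vd))
      if (vd > best$dice + 1e-4) {
        best <- list(params = params, dice = vd, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config@earlyStopPatience) break
      }
    }
  })
  new("TrainedSegmenter", params = best$params, baseWidth = C,
      config = config, history = hist, bestEpoch = best$epoch,
      valDice = best$dice, splitIds = split)
}

#' Predict per-side foramen masks for an image
#'
#' Normalizes and resizes the image to the training input size, runs the
#' network, resizes the probability map back to native resolution, thresholds
#' it, drops speckle components below \code{minComponentPx}, and keeps the
#' two largest components, assigned to the animal's right (viewer-left
#' columns) and left by centroid column.
#'
#' @param segmenter a \linkS4class{TrainedSegmenter}.
#' @param image numeric intensity matrix.
#' @param pixelSpacingMM mm per pixel of \code{image}.
#' @return list with \code{left}, \code{right} (\linkS4class{BinaryMask}) and
#'   \code{prob} (native-resolution probability map). Fails with a
#'   segmentation-failure error when fewer than two usable components exist.
#' @export
predictMasks <- function(segmenter, image, pixelSpacingMM) {
  cfg <- segmenter@config
  inp <- .minmax(.resizeMatrix(image, cfg@inputSize, cfg@inputSize,
                               "bilinear"))
  prob <- cpp_unet_forward(inp, segmenter@params, segmenter@baseWidth)
  probNative <- .resizeMatrix(prob, nrow(image), ncol(image), "bilinear")
  hard <- probNative >= cfg@probThreshold
  lab <- .labelComponents(hard)
  if (lab$n < 1L)
    stop("segmentation failure: no foreground component found")
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which(sizes >= cfg@minComponentPx)
  if (length(keep) < 2L)
    stop("segmentation failure: fewer than two components of at least ",
         cfg@minComponentPx, " px (image unassessable)")
  keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  cent <- vapply(keep, function(k) {
    mean((which(lab$labels == k) - 1L) %/% nrow(image))  # mean 0-based column
  }, numeric(1))
  rightLab <- keep[which.min(cent)]   # viewer-left = animal-right
  leftLab <- keep[which.max(cent)]
  list(left = binaryMask(lab$labels == leftLab, pixelSpacingMM),
       right = binaryMask(lab$labels == rightLab, pixelSpacingMM),
       prob = probNative)
}

.asGrid <- function(x) {
  if (is(x, "BinaryMask")) maskGrid(x)
  else if (is.logical(x)) x
  else x > 0.5
}

.dice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Dice similarity between two binary regions
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both regions are empty.
#'
#' @param a,b \linkS4class{BinaryMask} or logical matrices of equal shape.
#' @return score in [0, 1].
#' @examples
#' g <- matrix(FALSE, 4, 4); g[1:2, 1:2] <- TRUE
#' diceScore(g, g)  # 1
#' @export
diceScore <- function(a, b) {
  a <- .asGrid(a); b <- .asGrid(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  .dice(a, b)
}

#' Intersection over union between two binary regions
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both regions are empty.
#'
#' @inheritParams diceScore
#' @return score in [0, 1].
#' @export
iouScore <- function(a, b) {
  a <- .asGrid(a); b <- .asGrid(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Evaluate a segmenter on labelled samples
#'
#' Computes per-image Dice/IoU on the union of both foramina plus per-side
#' Dice. Prediction failures are recorded (status "failed", scores 0), never
#' raised.
#'
#' @param segmenter a \linkS4class{TrainedSegmenter}, or a function
#'   \code{(image, pixelSpacingMM)} returning \code{list(left=, right=)}
#'   masks (useful as a reference/oracle predictor).
#' @param samples list of \linkS4class{PhantomSample} (or pairs with
#'   ground-truth masks \code{maskLeft}/\code{maskRight} and
#'   \code{pixelSpacing}).
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateSegmenter <- function(segmenter, samples) {
  predictor <- if (is.function(segmenter)) segmenter
               else function(img, sp) predictMasks(segmenter, img, sp)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (is(s, "PhantomSample")) {
      img <- phantomImage(s); mk <- phantomMasks(s); sp <- pixelSpacing(s)
      gl <- maskGrid(mk$left); gr <- maskGrid(mk$right)
    } else {
      img <- s$image; sp <- s$pixelSpacing
      gl <- .asGrid(s$maskLeft); gr <- .asGrid(s$maskRight)
    }
    id <- if (!is.null(names(samples))) names(samples)[i] else as.character(i)
    gu <- gl | gr
    pred <- tryCatch(predictor(img, sp), error = function(e) NULL)
    if (is.null(pred))
      return(data.frame(id = id, dice = 0, iou = 0, dice_left = NA_real_,
                        dice_right = NA_real_, status = "failed"))
    pu <- maskGrid(pred$left) | maskGrid(pred$right)
    data.frame(id = id, dice = .dice(pu, gu), iou = iouScore(pu, gu),
               dice_left = .dice(maskGrid(pred$left), gl),
               dice_right = .dice(maskGrid(pred$right), gr),
               status = "ok")
  })
  per <- do.call(rbind, rows)
  new("EvalReport", perImage = per, meanDice = mean(per$dice),
      meanIoU = mean(per$iou), nFailed = sum(per$status == "failed"))
}
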