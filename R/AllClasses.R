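# S4 classes for the phantom, morphometry, rotation and segmentation layers.
# Statistics functions return plain lists / data.frames (documented per
# function), as is usual for test-style outputs.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Binary mask with physical pixel spacing
#'
#' A logical pixel grid plus the physical size of a pixel, the common currency
#' between rasterized annotations, phantom ground truth and network
#' predictions. Areas are \code{sum(grid) * prod(spacing)} mm^2.
#'
#' @slot grid logical matrix, \code{TRUE} = foreground.
#' @slot pixelSpacing numeric of length 1 (isotropic) or 2 as (row mm, col mm).
#' @export
setClass("BinaryMask",
  representation(grid = "matrix", pixelSpacing = "numeric"),
  validity = function(object) {
    if (!is.logical(object@grid)) return("grid must be a logical matrix")
    sp <- object@pixelSpacing
    if (!length(sp) %in% c(1L, 2L) || any(!is.finite(sp)) || any(sp <= 0))
      return("pixelSpacing must be 1 or 2 positive finite values")
    TRUE
  })

#' Construct a BinaryMask
#'
#' @param grid logical (or coercible 0/1 numeric) matrix.
#' @param pixelSpacing pixel size in mm; scalar or (row, col).
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' m <- binaryMask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), 0.5)
#' maskArea(m)
#' @export
binaryMask <- function(grid, pixelSpacing) {
  if (is.numeric(grid)) {
    grid <- matrix(grid > 0.5, nrow(grid), ncol(grid))
  }
  new("BinaryMask", grid = grid, pixelSpacing = as.numeric(pixelSpacing))
}

#' Per-foramen measurement
#'
#' @slot side "left" or "right" (the animal's side).
#' @slot areaMM2 projected area in mm^2.
#' @slot maxWidthMM maximum medial-lateral extent in mm.
#' @slot chord 2x2 matrix of (col, row) endpoints of the widest chord.
#' @export
setClass("ForamenMeasurement",
  representation(side = "character", areaMM2 = "numeric",
                 maxWidthMM = "numeric", chord = "matrix"),
  validity = function(object) {
    if (!object@side %in% c("left", "right")) return("side must be left/right")
    if (object@areaMM2 <= 0) return("areaMM2 must be positive")
    if (object@maxWidthMM <= 0) return("maxWidthMM must be positive")
    TRUE
  })

#' Pelvis measurement set for one radiograph
#'
#' Carries both foramen measurements and (optionally) the two iliac wing
#' widths, with the pixel spacing they were derived under. Iliac widths are
#' \code{NA_real_} when the landmarks were not annotated; \code{\link{asymmetry}}
#' then flags the iliac index as unavailable instead of reporting zero.
#'
#' @slot foramenLeft,foramenRight \linkS4class{ForamenMeasurement}.
#' @slot iliacLeftMM,iliacRightMM iliac wing widths (mm) or \code{NA}.
#' @slot pixelSpacingMM provenance spacing (mm).
#' @export
setClass("PelvisMeasurements",
  representation(foramenLeft = "ForamenMeasurement",
                 foramenRight = "ForamenMeasurement",
                 iliacLeftMM = "numeric", iliacRightMM = "numeric",
                 pixelSpacingMM = "numeric"),
  validity = function(object) {
    for (v in c(object@iliacLeftMM, object@iliacRightMM))
      if (!is.na(v) && v <= 0) return("iliac widths must be positive when present")
    if (xor(is.na(object@iliacLeftMM), is.na(object@iliacRightMM)))
      return("iliac widths must be present for both sides or neither")
    if (any(object@pixelSpacingMM <= 0)) return("pixelSpacingMM must be positive")
    TRUE
  })

#' Left-right asymmetry indices
#'
#' Signed values follow the left-minus-right convention; magnitudes
#' (largest minus smallest) are what grouping and thresholding consume.
#' \code{aiwwAvailable} is \code{FALSE} when iliac landmarks were absent.
#'
#' @slot aofaSigned,aofwSigned,aiwwSigned signed left-right differences
#'   (mm^2, mm, mm).
#' @slot aiwwAvailable logical flag.
#' @export
setClass("AsymmetryResult",
  representation(aofaSigned = "numeric", aofwSigned = "numeric",
                 aiwwSigned = "numeric", aiwwAvailable = "logical"))

#' Phantom generation parameters
#'
#' Defines a synthetic VDHE-like radiograph: two near-elliptical radiolucent
#' obturator foramina on a bone-like bright background, whose projected
#' widths respond to pelvic longitudinal rotation as the exact inverse of the
#' regression calibrations used by \code{\link{rotationFromAOFW}} and
#' \code{\link{rotationFromAIWW}}.
#'
#' @slot rotationDeg signed rotation (positive = animal's right side closer
#'   to the table).
#' @slot foramenSemiAxisA,foramenSemiAxisB ellipse semi-axes in mm
#'   (a = longest, horizontal at baseline; b = shortest, vertical).
#' @slot foramenCenterOffset lateral distance of each foramen center from the
#'   midline, mm.
#' @slot iliacWidth baseline iliac wing width, mm.
#' @slot imageSize integer (rows, cols).
#' @slot pixelSpacing mm per pixel (isotropic).
#' @slot noiseSD additive Gaussian intensity noise SD (image in [0,1]).
#' @slot blurSigma Gaussian blur sigma in pixels.
#' @slot magnificationTopside multiplicative scale >= 1 applied to the
#'   topside foramen (geometric magnification of structures nearer the tube).
#' @slot seed integer RNG seed for the noise.
#' @export
setClass("PhantomSpec",
  representation(rotationDeg = "numeric",
                 foramenSemiAxisA = "numeric", foramenSemiAxisB = "numeric",
                 foramenCenterOffset = "numeric", iliacWidth = "numeric",
                 imageSize = "integer", pixelSpacing = "numeric",
                 noiseSD = "numeric", blurSigma = "numeric",
                 magnificationTopside = "numeric", seed = "integer"),
  validity = function(object) {
    a <- object@foramenSemiAxisA; b <- object@foramenSemiAxisB
    if (!(a >= b && b > 0)) return("need semiAxisA >= semiAxisB > 0")
    if (object@pixelSpacing <= 0) return("pixelSpacing must be positive")
    if (!is.finite(object@rotationDeg)) return("rotationDeg must be finite")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    if (object@magnificationTopside < 1) return("magnificationTopside must be >= 1")
    if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
      return("imageSize must be two integers >= 16")
    # both foramina (with bone margin) must fit at baseline geometry
    fh <- object@imageSize * object@pixelSpacing / 2
    if (object@foramenCenterOffset + a * 1.6 + 2 > fh[2] ||
        b * 1.6 + 2 > fh[1])
      return("foramina (plus bone margin) do not fit inside the image")
    TRUE
  })

#' Synthetic phantom sample
#'
#' @slot image numeric intensity matrix in [0, 1].
#' @slot maskLeft,maskRight \linkS4class{BinaryMask} ground truth (animal side).
#' @slot truth \linkS4class{PelvisMeasurements} with exact analytic values
#'   (pre-rasterization).
#' @slot rotationDeg the generating rotation.
#' @slot annotation list with polygon matrices \code{left}, \code{right}
#'   ((col, row) vertices, 0-based) and iliac landmark segments.
#' @slot pixelSpacing mm per pixel.
#' @export
setClass("PhantomSample",
  representation(image = "matrix", maskLeft = "BinaryMask",
                 maskRight = "BinaryMask", truth = "PelvisMeasurements",
                 rotationDeg = "numeric", annotation = "list",
                 pixelSpacing = "numeric"),
  validity = function(object) {
    if (any(object@maskLeft@grid & object@maskRight@grid))
      return("left/right masks must be disjoint")
    TRUE
  })

#' Rotation estimate from an asymmetry magnitude
#'
#' @slot degrees estimated rotation in degrees (raw regression output; may be
#'   negative below the calibration range).
#' @slot method "AOFW" or "AIWW".
#' @slot inputMM asymmetry magnitude used (mm).
#' @slot belowCalibration TRUE when the regression output was negative.
#' @export
setClass("RotationEstimate",
  representation(degrees = "numeric", method = "character",
                 inputMM = "numeric", belowCalibration = "logical"),
  validity = function(object) {
    if (!object@method %in% c("AOFW", "AIWW")) return("method must be AOFW/AIWW")
    if (!is.finite(object@degrees)) return("degrees must be finite")
    TRUE
  })

#' Positioning quality decision
#'
#' @slot aofaAbsMM2 obturator-foramina area asymmetry magnitude (mm^2).
#' @slot thresholdMM2 decision bound (mm^2).
#' @slot acceptable TRUE iff \code{aofaAbsMM2 <= thresholdMM2}.
#' @slot rotation optional \linkS4class{RotationEstimate} (or NULL).
#' @slot group rotation group label or \code{NA}.
#' @export
setClass("QualityDecision",
  representation(aofaAbsMM2 = "numeric", thresholdMM2 = "numeric",
                 acceptable = "logical", rotation = "ANY", group = "character"),
  validity = function(object) {
    if (object@acceptable != (object@aofaAbsMM2 <= object@thresholdMM2))
      return("acceptable flag inconsistent with threshold")
    TRUE
  })

#' Segmentation training configuration
#'
#' @slot inputSize square resize target in px (even; default 448, test-scale
#'   runs use 128).
#' @slot encoderScale "small" (base width 8) or "large" (base width 32, a
#'   larger-capacity variant of the same architecture).
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot batchSize images per optimizer step (default 8).
#' @slot augmentProb per-transform augmentation probability (default 0.5).
#' @slot maxEpochs,earlyStopPatience training schedule.
#' @slot splitFractions train/val/test fractions summing to 1.
#' @slot probThreshold probability cut for binarization (default 0.5).
#' @slot minComponentPx minimum connected-component size kept (default 20).
#' @slot diceWeight weight of the soft-Dice term added to cross-entropy.
#' @slot seed integer RNG seed.
#' @export
setClass("SegmentationConfig",
  representation(inputSize = "integer", encoderScale = "character",
                 learningRate = "numeric", batchSize = "integer",
                 augmentProb = "numeric", maxEpochs = "integer",
                 earlyStopPatience = "integer", splitFractions = "numeric",
                 probThreshold = "numeric", minComponentPx = "integer",
                 diceWeight = "numeric", seed = "integer"),
  validity = function(object) {
    if (abs(sum(object@splitFractions) - 1) > 1e-8 ||
        length(object@splitFractions) != 3L || any(object@splitFractions < 0))
      return("splitFractions must be 3 non-negative values summing to 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@augmentProb < 0 || object@augmentProb > 1)
      return("augmentProb must lie in [0, 1]")
    if (object@inputSize %% 2L != 0L || object@inputSize < 16L)
      return("inputSize must be even and >= 16")
    if (!object@encoderScale %in% c("small", "large"))
      return("encoderScale must be 'small' or 'large'")
    if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
    TRUE
  })

#' Trained segmentation model
#'
#' @slot params flattened network weights.
#' @slot baseWidth encoder base channel width.
#' @slot config the \linkS4class{SegmentationConfig} used.
#' @slot history data.frame (epoch, loss, val_dice).
#' @slot bestEpoch epoch whose validation Dice selected the weights.
#' @slot valDice best validation mean Dice.
#' @slot splitIds list of train/val/test indices used.
#' @export
setClass("TrainedSegmenter",
  representation(params = "numeric", baseWidth = "integer",
                 config = "SegmentationConfig", history = "data.frame",
                 bestEpoch = "integer", valDice = "numeric",
                 splitIds = "list"))

#' Segmentation evaluation report
#'
#' @slot perImage data.frame with id, dice, iou (union of both foramina),
#'   per-side dice, and a status column ("ok" or "failed").
#' @slot meanDice,meanIoU means over all test images (failures count as 0).
#' @slot nFailed number of images where prediction failed.
#' @export
setClass("EvalReport",
  representation(perImage = "data.frame", meanDice = "numeric",
                 meanIoU = "numeric", nFailed = "integer"),
  validity = function(object) {
    ok <- stats::complete.cases(object@perImage[, c("dice", "iou")])
    d <- object@perImage$dice[ok]; i <- object@perImage$iou[ok]
    if (any(d < 0 | d > 1 | i < 0 | i > 1)) return("dice/iou out of [0,1]")
    if (any(i > d + 1e-12)) return("iou must not exceed dice")
    TRUE
  })

#' Radiograph container
#'
#' @slot pixels numeric intensity matrix (rows x cols), MONOCHROME2
#'   convention (higher = brighter).
#' @slot pixelSpacing (row mm, col mm).
#' @slot sourceId origin identifier.
#' @slot photometric original photometric interpretation.
#' @export
setClass("Radiograph",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 sourceId = "character", photometric = "character"),
  validity = function(object) {
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
      return("pixelSpacing must be two positive values (row, col)")
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    TRUE
  })
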