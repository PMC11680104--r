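# Accessor generics and show() methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for pelviQC classes
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @description Small read-only accessors: \code{maskGrid} returns the logical
#' pixel grid of a \linkS4class{BinaryMask}; \code{pixelSpacing} the physical
#' pixel size in mm; \code{phantomImage}, \code{phantomMasks}, \code{truth}
#' the parts of a \linkS4class{PhantomSample}; \code{rotationDeg} the
#' generating or estimated rotation; \code{degrees}, \code{rotationMethod},
#' \code{isBelowCalibration} the fields of a \linkS4class{RotationEstimate};
#' \code{aofa}, \code{aofw}, \code{aiww} the asymmetry indices of an
#' \linkS4class{AsymmetryResult} (signed or magnitude); \code{isAcceptable}
#' and \code{rotationGroup} the verdict of a \linkS4class{QualityDecision};
#' \code{meanDice}, \code{meanIoU}, \code{perImage} the contents of an
#' \linkS4class{EvalReport}.
NULL

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "BinaryMask", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PhantomSample", function(x) x@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PelvisMeasurements", function(x) x@pixelSpacingMM)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "Radiograph", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setMethod("phantomImage", "PhantomSample", function(x) x@image)

#' @rdname accessors
#' @export
setGeneric("phantomMasks", function(x) standardGeneric("phantomMasks"))
#' @rdname accessors
#' @export
setMethod("phantomMasks", "PhantomSample",
          function(x) list(left = x@maskLeft, right = x@maskRight))

#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setMethod("truth", "PhantomSample", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setMethod("annotation", "PhantomSample", function(x) x@annotation)

#' @rdname accessors
#' @export
setGeneric("rotationDeg", function(x) standardGeneric("rotationDeg"))
#' @rdname accessors
#' @export
setMethod("rotationDeg", "PhantomSample", function(x) x@rotationDeg)
#' @rdname accessors
#' @export
setMethod("rotationDeg", "PhantomSpec", function(x) x@rotationDeg)

#' @rdname accessors
#' @export
setGeneric("foramen", function(x, side) standardGeneric("foramen"))
#' @rdname accessors
#' @param side "left" or "right" (the animal's side).
#' @export
setMethod("foramen", "PelvisMeasurements", function(x, side) {
  side <- match.arg(side, c("left", "right"))
  f <- if (side == "left") x@foramenLeft else x@foramenRight
  list(side = f@side, areaMM2 = f@areaMM2, maxWidthMM = f@maxWidthMM,
       chord = f@chord)
})

#' @rdname accessors
#' @export
setGeneric("iliacWidths", function(x) standardGeneric("iliacWidths"))
#' @rdname accessors
#' @export
setMethod("iliacWidths", "PelvisMeasurements",
          function(x) c(left = x@iliacLeftMM, right = x@iliacRightMM))

#' @rdname accessors
#' @param signed logical; return the signed left-minus-right value instead of
#'   the magnitude.
#' @export
setGeneric("aofa", function(x, signed = FALSE) standardGeneric("aofa"))
#' @rdname accessors
#' @export
setMethod("aofa", "AsymmetryResult", function(x, signed = FALSE)
  if (signed) x@aofaSigned else abs(x@aofaSigned))

#' @rdname accessors
#' @export
setGeneric("aofw", function(x, signed = FALSE) standardGeneric("aofw"))
#' @rdname accessors
#' @export
setMethod("aofw", "AsymmetryResult", function(x, signed = FALSE)
  if (signed) x@aofwSigned else abs(x@aofwSigned))

#' @rdname accessors
#' @export
setGeneric("aiww", function(x, signed = FALSE) standardGeneric("aiww"))
#' @rdname accessors
#' @export
setMethod("aiww", "AsymmetryResult", function(x, signed = FALSE) {
  if (!x@aiwwAvailable) return(NA_real_)
  if (signed) x@aiwwSigned else abs(x@aiwwSigned)
})

#' @rdname accessors
#' @export
setGeneric("aiwwAvailable", function(x) standardGeneric("aiwwAvailable"))
#' @rdname accessors
#' @export
setMethod("aiwwAvailable", "AsymmetryResult", function(x) x@aiwwAvailable)

#' @rdname accessors
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))
#' @rdname accessors
#' @export
setMethod("degrees", "RotationEstimate", function(x) x@degrees)

#' @rdname accessors
#' @export
setGeneric("rotationMethod", function(x) standardGeneric("rotationMethod"))
#' @rdname accessors
#' @export
setMethod("rotationMethod", "RotationEstimate", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("isBelowCalibration", function(x) standardGeneric("isBelowCalibration"))
#' @rdname accessors
#' @export
setMethod("isBelowCalibration", "RotationEstimate", function(x) x@belowCalibration)

#' @rdname accessors
#' @export
setGeneric("isAcceptable", function(x) standardGeneric("isAcceptable"))
#' @rdname accessors
#' @export
setMethod("isAcceptable", "QualityDecision", function(x) x@acceptable)

#' @rdname accessors
#' @export
setGeneric("rotationGroup", function(x) standardGeneric("rotationGroup"))
#' @rdname accessors
#' @export
setMethod("rotationGroup", "QualityDecision", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("meanDice", function(x) standardGeneric("meanDice"))
#' @rdname accessors
#' @export
setMethod("meanDice", "EvalReport", function(x) x@meanDice)

#' @rdname accessors
#' @export
setGeneric("meanIoU", function(x) standardGeneric("meanIoU"))
#' @rdname accessors
#' @export
setMethod("meanIoU", "EvalReport", function(x) x@meanIoU)

#' @rdname accessors
#' @export
setGeneric("perImage", function(x) standardGeneric("perImage"))
#' @rdname accessors
#' @export
setMethod("perImage", "EvalReport", function(x) x@perImage)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "TrainedSegmenter", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Radiograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@imageSize[1], "x", object@imageSize[2], "px @",
      object@pixelSpacing, "mm/px\n")
  cat("  rotation:", object@rotationDeg, "deg; foramen semi-axes:",
      object@foramenSemiAxisA, "x", object@foramenSemiAxisB, "mm\n")
  cat("  noise SD:", object@noiseSD, "; blur sigma:", object@blurSigma,
      "px; topside magnification:", object@magnificationTopside, "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "PhantomSample", function(object) {
  cat("PhantomSample:", nrow(object@image), "x", ncol(object@image), "px @",
      object@pixelSpacing, "mm/px, rotation", object@rotationDeg, "deg\n")
  a <- asymmetry(object@truth)
  cat(sprintf("  truth |AOFA| = %.2f mm^2, |AOFW| = %.3f mm\n",
              aofa(a), aofw(a)))
})

#' @rdname accessors
#' @export
setMethod("show", "PelvisMeasurements", function(object) {
  cat("PelvisMeasurements (mm / mm^2):\n")
  cat(sprintf("  foramen left : area %.2f, width %.3f\n",
              object@foramenLeft@areaMM2, object@foramenLeft@maxWidthMM))
  cat(sprintf("  foramen right: area %.2f, width %.3f\n",
              object@foramenRight@areaMM2, object@foramenRight@maxWidthMM))
  if (!is.na(object@iliacLeftMM))
    cat(sprintf("  iliac widths : left %.3f, right %.3f\n",
                object@iliacLeftMM, object@iliacRightMM))
  else cat("  iliac widths : not annotated\n")
})

#' @rdname accessors
#' @export
setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf("AsymmetryResult: AOFA %+.2f mm^2, AOFW %+.3f mm",
              object@aofaSigned, object@aofwSigned))
  if (object@aiwwAvailable) cat(sprintf(", AIWW %+.3f mm", object@aiwwSigned))
  cat(" (signed, left - right)\n")
})

#' @rdname accessors
#' @export
setMethod("show", "RotationEstimate", function(object) {
  cat(sprintf("RotationEstimate: %.3f deg from %s = %.3f mm%s\n",
              object@degrees, object@method, object@inputMM,
              if (object@belowCalibration) " [below calibration range]" else ""))
})

#' @rdname accessors
#' @export
setMethod("show", "QualityDecision", function(object) {
  cat(sprintf("QualityDecision: |AOFA| = %.2f mm^2 vs threshold %.2f mm^2 -> %s\n",
              object@aofaAbsMM2, object@thresholdMM2,
              if (object@acceptable) "ACCEPTABLE" else "NOT acceptable"))
  if (!is.na(object@group)) cat("  rotation group:", object@group, "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig:", object@encoderScale, "encoder, input",
      object@inputSize, "px\n")
  cat("  lr", object@learningRate, ", batch", object@batchSize,
      ", augment p =", object@augmentProb, ", max epochs", object@maxEpochs, "\n")
  cat("  split", paste(object@splitFractions, collapse = "/"),
      ", seed", object@seed, "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "TrainedSegmenter", function(object) {
  cat("TrainedSegmenter:", length(object@params), "parameters (base width",
      object@baseWidth, ")\n")
  cat(sprintf("  best epoch %d, validation Dice %.4f\n",
              object@bestEpoch, object@valDice))
})

#' @rdname accessors
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d images, mean Dice %.4f, mean IoU %.4f (%d failed)\n",
              nrow(object@perImage), object@meanDice, object@meanIoU,
              object@nFailed))
})

#' @rdname accessors
#' @export
setMethod("show", "Radiograph", function(object) {
  cat("Radiograph", object@sourceId, ":", nrow(object@pixels), "x",
      ncol(object@pixels), "px @", paste(object@pixelSpacing, collapse = " x "),
      "mm,", object@photometric, "\n")
})
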