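# Rotation: convert asymmetry magnitudes to degrees of pelvic longitudinal
# rotation via the published regression calibrations, group the result, and
# issue the accept/reject positioning-quality decision.

.AOFW_SLOPE <- 1.644
.AOFW_INTERCEPT <- -0.912
.AIWW_SLOPE <- 0.997
.AIWW_INTERCEPT <- 0.061

#' Default acceptable AOFA threshold (mm^2)
#'
#' Mean AOFA of the minimal rotation group (33.28 mm^2) plus the measurement
#' model's SEM (17.18 mm^2); see \code{\link{deriveThreshold}}.
#' @export
DEFAULT_AOFA_THRESHOLD <- 50.46

#' Rotation group definitions
#'
#' The four positive-degree rotation groups: minimal (0-2), moderate (3-4),
#' marked (5-6) and extreme (>= 7). Estimates are rounded to the nearest
#' integer degree before grouping.
#'
#' @return data.frame with group, lower and upper integer bound (upper
#'   \code{Inf} for extreme).
#' @export
rotationGroups <- function() {
  data.frame(group = c("minimal", "moderate", "marked", "extreme"),
             lower = c(0L, 3L, 5L, 7L),
             upper = c(2, 4, 6, Inf))
}

.rotationEstimate <- function(x, slope, intercept, method) {
  if (length(x) != 1L || !is.finite(x)) stop("asymmetry must be a finite scalar")
  if (x < 0) stop("asymmetry magnitude must be >= 0 (got ", x, ")")
  deg <- slope * x + intercept
  new("RotationEstimate", degrees = deg, method = method, inputMM = x,
      belowCalibration = deg < 0)
}

#' Pelvic rotation from obturator-foramina width asymmetry
#'
#' Applies the calibration \eqn{y = 1.644 x - 0.912} (degrees from mm of
#' width asymmetry). Outputs below zero are reported as-is but flagged as
#' below the calibration range (tiny rotations are not resolvable by this
#' index); \code{\link{classifyRotation}} clamps them to zero degrees.
#'
#' @param aofwMM width-asymmetry magnitude in mm (>= 0).
#' @return A \linkS4class{RotationEstimate}.
#' @examples
#' degrees(rotationFromAOFW(5))       # 7.308
#' degrees(rotationFromAOFW(0.912 / 1.644))  # 0
#' @export
rotationFromAOFW <- function(aofwMM)
  .rotationEstimate(aofwMM, .AOFW_SLOPE, .AOFW_INTERCEPT, "AOFW")

#' Pelvic rotation from iliac-wing width asymmetry
#'
#' Applies the calibration \eqn{y = 0.997 x + 0.061}.
#'
#' @param aiwwMM width-asymmetry magnitude in mm (>= 0).
#' @return A \linkS4class{RotationEstimate}.
#' @examples
#' degrees(rotationFromAIWW(10))  # 10.031
#' @export
rotationFromAIWW <- function(aiwwMM)
  .rotationEstimate(aiwwMM, .AIWW_SLOPE, .AIWW_INTERCEPT, "AIWW")

# round half away from zero (0.5 -> 1), unlike banker's round()
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classify a rotation magnitude into a rotation group
#'
#' Degrees are rounded to the nearest integer (half away from zero by
#' default) and mapped to minimal (0-2), moderate (3-4), marked (5-6) or
#' extreme (>= 7). Negative inputs (below-calibration regression outputs) are
#' clamped to 0 before rounding.
#'
#' @param deg rotation magnitude in degrees, or a
#'   \linkS4class{RotationEstimate}.
#' @param rounding "half-away" (default) or "half-even" (base R
#'   \code{round}).
#' @return group label, one of \code{rotationGroups()$group}.
#' @examples
#' classifyRotation(1.7)  # "minimal"
#' classifyRotation(2.5)  # "moderate" (2.5 rounds to 3 half-away-from-zero)
#' classifyRotation(7.0)  # "extreme"
#' @export
classifyRotation <- function(deg, rounding = c("half-away", "half-even")) {
  rounding <- match.arg(rounding)
  if (is(deg, "RotationEstimate")) deg <- degrees(deg)
  if (length(deg) != 1L || !is.finite(deg)) stop("degrees must be a finite scalar")
  deg <- max(0, deg)
  r <- if (rounding == "half-away") .roundHalfAway(deg) else round(deg)
  g <- rotationGroups()
  g$group[which(r >= g$lower & r <= g$upper)[1]]
}

#' Derive an acceptable-asymmetry threshold
#'
#' Acceptable AOFA = mean AOFA of the minimal rotation group plus the
#' measurement model's standard error of measurement, so that radiographs
#' within the natural variability of well-positioned pelves plus measurement
#' error are not rejected.
#'
#' @param minimalGroupMeanMM2 mean AOFA of the minimal group, mm^2.
#' @param semMM2 standard error of measurement, mm^2.
#' @return threshold in mm^2.
#' @examples
#' deriveThreshold(33.28, 17.18)  # 50.46
#' @export
deriveThreshold <- function(minimalGroupMeanMM2, semMM2) {
  if (minimalGroupMeanMM2 < 0 || semMM2 < 0)
    stop("threshold components must be non-negative")
  minimalGroupMeanMM2 + semMM2
}

#' Positioning-quality decision from area asymmetry
#'
#' A radiograph is acceptable when its AOFA magnitude does not exceed the
#' threshold (boundary inclusive).
#'
#' @param aofaAbsMM2 AOFA magnitude in mm^2 (>= 0).
#' @param thresholdMM2 decision bound, default
#'   \code{DEFAULT_AOFA_THRESHOLD} (50.46 mm^2).
#' @param rotation optional \linkS4class{RotationEstimate} to carry along;
#'   when given, its group label is attached to the decision.
#' @return A \linkS4class{QualityDecision}.
#' @examples
#' isAcceptable(assessQuality(33.0))     # TRUE
#' isAcceptable(assessQuality(50.46))    # TRUE (inclusive boundary)
#' isAcceptable(assessQuality(120.0))    # FALSE
#' @export
assessQuality <- function(aofaAbsMM2, thresholdMM2 = DEFAULT_AOFA_THRESHOLD,
                          rotation = NULL) {
  if (length(aofaAbsMM2) != 1L || !is.finite(aofaAbsMM2) || aofaAbsMM2 < 0)
    stop("aofaAbsMM2 must be a finite scalar >= 0")
  if (!is.finite(thresholdMM2) || thresholdMM2 < 0)
    stop("thresholdMM2 must be a finite value >= 0")
  grp <- NA_character_
  if (!is.null(rotation)) {
    stopifnot(is(rotation, "RotationEstimate"))
    grp <- classifyRotation(rotation)
  }
  new("QualityDecision", aofaAbsMM2 = aofaAbsMM2, thresholdMM2 = thresholdMM2,
      acceptable = aofaAbsMM2 <= thresholdMM2, rotation = rotation, group = grp)
}

#' Assess a table of measurements
#'
#' Vectorized convenience over a measurement table (one radiograph per row,
#' columns as written by \code{\link{generateDataset}} /
#' \code{\link{measureDataset}}): computes asymmetry magnitudes, the rotation
#' estimate by the chosen method, the rotation group and the accept flag.
#'
#' @param measurements data.frame with columns \code{area_left_mm2},
#'   \code{area_right_mm2}, \code{width_left_mm}, \code{width_right_mm} and
#'   optionally \code{iliac_left_mm}, \code{iliac_right_mm},
#'   \code{sample_id}.
#' @param thresholdMM2 AOFA decision bound, mm^2.
#' @param method rotation estimator, "aofw" or "aiww".
#' @return data.frame with sample_id, aofa_abs_mm2, input_mm, degrees,
#'   below_calibration, rotation_group, acceptable.
#' @export
assessTable <- function(measurements, thresholdMM2 = DEFAULT_AOFA_THRESHOLD,
                        method = c("aofw", "aiww")) {
  method <- match.arg(method)
  need <- c("area_left_mm2", "area_right_mm2", "width_left_mm", "width_right_mm")
  if (!all(need %in% names(measurements)))
    stop("measurement table must contain columns: ", paste(need, collapse = ", "))
  if (method == "aiww" &&
      !all(c("iliac_left_mm", "iliac_right_mm") %in% names(measurements)))
    stop("method 'aiww' needs iliac_left_mm / iliac_right_mm columns")
  est <- function(x) if (method == "aofw") rotationFromAOFW(x) else rotationFromAIWW(x)
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    m <- measurements[i, ]
    aofaAbs <- abs(m$area_left_mm2 - m$area_right_mm2)
    input <- if (method == "aofw") abs(m$width_left_mm - m$width_right_mm)
             else abs(m$iliac_left_mm - m$iliac_right_mm)
    r <- est(input)
    data.frame(sample_id = if ("sample_id" %in% names(m)) m$sample_id else i,
               aofa_abs_mm2 = aofaAbs, input_mm = input,
               degrees = degrees(r), below_calibration = isBelowCalibration(r),
               rotation_group = classifyRotation(r),
               acceptable = aofaAbs <= thresholdMM2)
  })
  do.call(rbind, rows)
}
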