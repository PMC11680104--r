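# Synthetic VDHE-like pelvis phantom: two near-elliptical radiolucent
# obturator foramina on a bone-like background, with analytic ground truth.
#
# The asymmetry response is the exact inverse of the rotation calibrations:
# at rotation theta (degrees, magnitude), the foramen width difference is
# delta_w = (theta + 0.912) / 1.644 mm and the iliac width difference is
# delta_iw = max(0, (theta - 0.061) / 0.997) mm, split symmetrically between
# the sides (underside widens, topside narrows), so that measuring the
# phantom and applying rotationFromAOFW()/rotationFromAIWW() recovers theta
# exactly in the noiseless case. At theta == 0 both differences are defined
# as 0 (perfectly symmetric pelvis); the AOFW calibration's negative
# intercept makes its inverse discontinuous there, reflecting that the width
# index cannot resolve rotations below ~0.9 degrees.

.phantomDeltaW <- function(theta) {
  a <- abs(theta)
  if (a == 0) 0 else max(0, (a + 0.912) / 1.644)
}

.phantomDeltaIW <- function(theta) {
  a <- abs(theta)
  if (a == 0) 0 else max(0, (a - 0.061) / 0.997)
}

#' Construct a PhantomSpec
#'
#' Defaults describe a medium-size dog pelvis: baseline foramen width 24 mm
#' (semi-axes 12 x 9 mm), centers 18 mm lateral of the midline, iliac wing
#' width 10 mm. The \code{full} profile renders 448 x 448 px at 0.2 mm/px
#' (the resolution segmentation models train at); the \code{test} profile
#' covers the same 89.6 mm field at 128 x 128 px (0.7 mm/px) so tests stay
#' fast.
#'
#' @param rotationDeg signed pelvic rotation in degrees (positive = animal's
#'   right side closer to the table).
#' @param profile "full" (448 px at 0.2 mm) or "test" (128 px at 0.7 mm);
#'   explicit \code{imageSize}/\code{pixelSpacing} override the profile.
#' @param foramenSemiAxisA,foramenSemiAxisB baseline ellipse semi-axes, mm.
#' @param foramenCenterOffset lateral offset of each foramen center, mm.
#' @param iliacWidth baseline iliac wing width, mm.
#' @param imageSize integer (rows, cols).
#' @param pixelSpacing mm per pixel.
#' @param noiseSD additive Gaussian intensity noise SD.
#' @param blurSigma Gaussian blur sigma, px.
#' @param magnificationTopside geometric magnification (>= 1) of the topside
#'   foramen.
#' @param seed RNG seed for the noise.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(rotationDeg = 5, profile = "test")
#' @export
phantomSpec <- function(rotationDeg = 0, profile = c("full", "test"),
                        foramenSemiAxisA = 12, foramenSemiAxisB = 9,
                        foramenCenterOffset = 18, iliacWidth = 10,
                        imageSize = NULL, pixelSpacing = NULL,
                        noiseSD = 0.02, blurSigma = 1,
                        magnificationTopside = 1, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(imageSize))
    imageSize <- if (profile == "full") c(448L, 448L) else c(128L, 128L)
  if (is.null(pixelSpacing))
    pixelSpacing <- if (profile == "full") 0.2 else 0.7
  new("PhantomSpec", rotationDeg = as.numeric(rotationDeg),
      foramenSemiAxisA = foramenSemiAxisA, foramenSemiAxisB = foramenSemiAxisB,
      foramenCenterOffset = foramenCenterOffset, iliacWidth = iliacWidth,
      imageSize = as.integer(imageSize), pixelSpacing = pixelSpacing,
      noiseSD = noiseSD, blurSigma = blurSigma,
      magnificationTopside = magnificationTopside, seed = as.integer(seed))
}

# analytic side geometry for a spec: per-side ellipse (center x in mm,
# semi-axes in mm) and iliac widths
.phantomGeometry <- function(spec) {
  theta <- spec@rotationDeg
  w0 <- 2 * spec@foramenSemiAxisA
  dw <- .phantomDeltaW(theta)
  diw <- .phantomDeltaIW(theta)
  # positive rotation: right side is the underside (more exposed, wider),
  # left side is the topside (concealed, narrower, geometrically magnified)
  sgn <- if (theta >= 0) 1 else -1
  wRight <- w0 + sgn * dw / 2
  wLeft <- w0 - sgn * dw / 2
  iwRight <- spec@iliacWidth + sgn * diw / 2
  iwLeft <- spec@iliacWidth - sgn * diw / 2
  if (min(wRight, wLeft, iwRight, iwLeft) <= 0)
    stop("rotation ", theta, " deg drives a width negative; ",
         "increase the baseline widths")
  mag <- spec@magnificationTopside
  magLeft <- if (theta > 0) mag else 1
  magRight <- if (theta < 0) mag else 1
  list(
    left = list(cxMM = spec@foramenCenterOffset,
                saMM = wLeft / 2 * magLeft,
                sbMM = spec@foramenSemiAxisB * magLeft),
    right = list(cxMM = -spec@foramenCenterOffset,
                 saMM = wRight / 2 * magRight,
                 sbMM = spec@foramenSemiAxisB * magRight),
    iliacLeftMM = iwLeft * magLeft, iliacRightMM = iwRight * magRight)
}

.ellipseMask <- function(xmm, ymm, cx, sa, sb) {
  outer((ymm / sb)^2, ((xmm - cx) / sa)^2, `+`) <= 1
}

.ellipsePolygon <- function(cxPx, cyPx, saPx, sbPx, n = 72L) {
  phi <- 2 * pi * (0:(n - 1)) / n
  cbind(cxPx + saPx * cos(phi), cyPx + sbPx * sin(phi))
}

#' Generate a synthetic phantom radiograph
#'
#' Renders the phantom image (bright bone plates, dark foramina, optional
#' blur and noise), the per-side ground-truth masks rasterized from the same
#' ellipses, exact analytic measurements, and a polygon annotation.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSample}.
#' @examples
#' s <- generatePhantom(phantomSpec(rotationDeg = 5, profile = "test",
#'                                  noiseSD = 0))
#' aofw(asymmetry(truth(s)))                    # (5 + 0.912)/1.644 = 3.5961
#' degrees(rotationFromAOFW(aofw(asymmetry(truth(s)))))  # 5
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  g <- .phantomGeometry(spec)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]; s <- spec@pixelSpacing
  cyPx <- (H - 1) / 2; cxPx <- (W - 1) / 2
  xmm <- ((0:(W - 1)) - cxPx) * s
  ymm <- ((0:(H - 1)) - cyPx) * s
  fh <- c(H, W) * s / 2

  boneMargin <- 1.5  # mm of cortical bone drawn around each foramen
  for (side in c("left", "right")) {
    e <- g[[side]]
    if (abs(e$cxMM) + e$saMM * 1.45 + boneMargin > fh[2] ||
        e$sbMM * 1.45 + boneMargin > fh[1])
      stop("foramen ellipse (", side, ") exceeds image bounds")
  }
  if (g$left$cxMM - g$left$saMM <= g$right$cxMM + g$right$saMM)
    stop("foramina overlap; reduce widths or increase the center offset")

  img <- matrix(0.35, H, W)
  # faint midline sacral band
  img[, abs(xmm) < 3] <- 0.55
  # iliac wing bars (horizontal segments of bright cortex, cranial = top)
  yI <- -0.58 * fh[1]
  ilRow <- abs(ymm - yI) <= 0.75
  landmarks <- list()
  for (side in c("left", "right")) {
    iw <- if (side == "left") g$iliacLeftMM else g$iliacRightMM
    cx <- g[[side]]$cxMM
    img[ilRow, abs(xmm - cx) <= iw / 2] <- 0.85
    pxY <- yI / s + cyPx
    landmarks[[paste0("iliac_", side)]] <-
      rbind(c((cx - iw / 2) / s + cxPx, pxY),
            c((cx + iw / 2) / s + cxPx, pxY))
  }
  # bone plates and radiolucent foramina
  masks <- list()
  polys <- list()
  for (side in c("left", "right")) {
    e <- g[[side]]
    plate <- .ellipseMask(xmm, ymm, e$cxMM, e$saMM * 1.45 + boneMargin,
                          e$sbMM * 1.45 + boneMargin)
    img[plate] <- 0.85
    for_ <- .ellipseMask(xmm, ymm, e$cxMM, e$saMM, e$sbMM)
    img[for_] <- 0.10
    masks[[side]] <- for_
    polys[[side]] <- .ellipsePolygon(e$cxMM / s + cxPx, cyPx,
                                     e$saMM / s, e$sbMM / s)
  }
  img <- .gaussianBlur(img, spec@blurSigma)
  if (spec@noiseSD > 0) {
    img <- .withSeed(spec@seed,
                     img + matrix(rnorm(H * W, 0, spec@noiseSD), H, W))
  }
  img <- pmin(pmax(img, 0), 1)

  mkTruth <- function(side) {
    e <- g[[side]]
    new("ForamenMeasurement", side = side,
        areaMM2 = pi * e$saMM * e$sbMM, maxWidthMM = 2 * e$saMM,
        chord = rbind(c((e$cxMM - e$saMM) / s + cxPx, cyPx),
                      c((e$cxMM + e$saMM) / s + cxPx, cyPx)))
  }
  truth <- new("PelvisMeasurements",
               foramenLeft = mkTruth("left"), foramenRight = mkTruth("right"),
               iliacLeftMM = g$iliacLeftMM, iliacRightMM = g$iliacRightMM,
               pixelSpacingMM = s)

  new("PhantomSample", image = img,
      maskLeft = binaryMask(masks$left, s),
      maskRight = binaryMask(masks$right, s),
      truth = truth, rotationDeg = spec@rotationDeg,
      annotation = c(list(left = polys$left, right = polys$right), landmarks),
      pixelSpacing = s)
}

#' Generate a reproducible phantom dataset
#'
#' Samples rotation angles, generates one phantom per angle, and (optionally)
#' writes the dataset to disk: PNG images, per-side PNG masks, LabelMe-style
#' JSON annotations, a truth CSV table and a small JSON manifest carrying the
#' pixel spacing.
#'
#' @param n number of samples (>= 1).
#' @param specTemplate a \linkS4class{PhantomSpec} whose rotation is replaced
#'   per sample.
#' @param rotationRange bounds of the uniform rotation sampler, degrees.
#' @param sampler optional function(n) returning n rotation angles (overrides
#'   \code{rotationRange}); must produce bounded values.
#' @param seed integer; fixes the rotation draw and all per-sample noise.
#' @param outDir optional output directory.
#' @return invisibly, a list with \code{samples} (list of
#'   \linkS4class{PhantomSample}), \code{truth} (data.frame) and \code{dir}.
#' @examples
#' ds <- generateDataset(3, phantomSpec(profile = "test", noiseSD = 0),
#'                       seed = 7)
#' ds$truth
#' @export
generateDataset <- function(n, specTemplate = phantomSpec(),
                            rotationRange = c(0, 10), sampler = NULL,
                            seed = 1L, outDir = NULL) {
  if (n < 1) stop("n must be >= 1")
  draws <- .withSeed(seed, {
    thetas <- if (is.null(sampler)) runif(n, rotationRange[1], rotationRange[2])
              else sampler(n)
    list(thetas = thetas,
         seeds = sample.int(.Machine$integer.max, n))
  })
  if (any(!is.finite(draws$thetas))) stop("rotation sampler produced non-finite values")
  ids <- sprintf("sample_%03d", seq_len(n))
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- specTemplate
    spec@rotationDeg <- draws$thetas[i]
    spec@seed <- draws$seeds[i]
    smp <- generatePhantom(spec)
    samples[[i]] <- smp
    tr <- truth(smp)
    iw <- iliacWidths(tr)
    rows[[i]] <- data.frame(
      sample_id = ids[i], rotation_deg = draws$thetas[i],
      area_left_mm2 = foramen(tr, "left")$areaMM2,
      area_right_mm2 = foramen(tr, "right")$areaMM2,
      width_left_mm = foramen(tr, "left")$maxWidthMM,
      width_right_mm = foramen(tr, "right")$maxWidthMM,
      iliac_left_mm = unname(iw["left"]), iliac_right_mm = unname(iw["right"]))
  }
  truthTab <- do.call(rbind, rows)
  names(samples) <- ids
  if (!is.null(outDir)) {
    for (d in file.path(outDir, c("images", "masks", "annotations")))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      smp <- samples[[i]]
      writeImagePNG(phantomImage(smp),
                    file.path(outDir, "images", paste0(ids[i], ".png")))
      mk <- phantomMasks(smp)
      writeMaskPNG(mk$left, file.path(outDir, "masks",
                                      paste0(ids[i], "_left.png")))
      writeMaskPNG(mk$right, file.path(outDir, "masks",
                                       paste0(ids[i], "_right.png")))
      writeAnnotation(annotation(smp),
                      file.path(outDir, "annotations", paste0(ids[i], ".json")),
                      imageHeight = nrow(phantomImage(smp)),
                      imageWidth = ncol(phantomImage(smp)),
                      imagePath = paste0("images/", ids[i], ".png"),
                      pixelSpacingMM = pixelSpacing(smp))
    }
    write.csv(truthTab, file.path(outDir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n = n, seed = seed,
           pixel_spacing_mm = specTemplate@pixelSpacing,
           image_size = specTemplate@imageSize,
           rotation_range = if (is.null(sampler)) rotationRange else range(draws$thetas)),
      file.path(outDir, "dataset.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(samples = samples, truth = truthTab, dir = outDir))
}

#' Simulate a second rater with bias and random error
#'
#' Produces paired measurements (true, true + bias + Gaussian error) for
#' exercising agreement analyses (Bland-Altman, ICC, paired t) against known
#' ground truth.
#'
#' @param trueValues numeric vector of reference measurements (e.g. AOFA in
#'   mm^2).
#' @param bias systematic offset added to every rating.
#' @param errorSD SD of the additive Gaussian rating error (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{true} and \code{rated}.
#' @examples
#' simulateRater(c(10, 20, 30), bias = 1, errorSD = 0, seed = 1)
#' @export
simulateRater <- function(trueValues, bias = 0, errorSD = 0, seed = 1L) {
  if (length(trueValues) == 0L) stop("trueValues must be nonempty")
  if (errorSD < 0) stop("errorSD must be >= 0")
  rated <- .withSeed(seed,
                     trueValues + bias + rnorm(length(trueValues), 0, errorSD))
  data.frame(true = trueValues, rated = rated)
}
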