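# Morphometry: areas, maximum medial-lateral widths and left-right asymmetry
# indices from polygons, masks and landmark pairs, always in mm units.
#
# Conventions (used consistently across phantom truth and measurement):
#  * coordinates are 0-based (col, row) pixel centers;
#  * "horizontal" is the image-column direction (the VDHE view is assumed
#    axis-aligned, no pelvis-axis realignment);
#  * mask widths use the inclusive pixel-extent convention
#    (rightmost - leftmost + 1) * spacing; polygon widths use the exact
#    boundary extent;
#  * anisotropic spacing is (row mm, col mm): widths use col mm, areas the
#    product.

.spacing2 <- function(pixelSpacing) {
  if (length(pixelSpacing) == 1L) rep(pixelSpacing, 2L) else pixelSpacing
}

.checkPolygon <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("polygon must be an n x 2 matrix of (col, row) vertices")
  if (nrow(points) < 3L) stop("polygon needs at least 3 vertices")
  if (any(!is.finite(points))) stop("polygon vertices must be finite")
  invisible(points)
}

# proper-crossing test between all non-adjacent edge pairs (vectorized)
.isSimplePolygon <- function(points) {
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]
  nx <- c(2:n, 1)
  ij <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  if (nrow(ij) == 0L) return(TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  ax <- x[i]; ay <- y[i]; bx <- x[nx[i]]; by <- y[nx[i]]
  cx <- x[j]; cy <- y[j]; dx <- x[nx[j]]; dy <- y[nx[j]]
  o <- function(px, py, qx, qy, rx, ry) sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  d1 <- o(ax, ay, bx, by, cx, cy); d2 <- o(ax, ay, bx, by, dx, dy)
  d3 <- o(cx, cy, dx, dy, ax, ay); d4 <- o(cx, cy, dx, dy, bx, by)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Polygon area in mm^2 (shoelace formula)
#'
#' Computes the enclosed area of a simple polygon given in pixel coordinates,
#' scaled to mm^2 by the pixel spacing. Orientation independent.
#'
#' @param points n x 2 matrix of (col, row) vertices, 0-based pixel units.
#' @param pixelSpacing mm per pixel; scalar or (row, col).
#' @return area in mm^2.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygonArea(sq, 1)            # 1
#' polygonArea(sq[4:1, ], 1)     # orientation independent
#' @export
polygonArea <- function(points, pixelSpacing) {
  .checkPolygon(points)
  if (!.isSimplePolygon(points)) stop("polygon is self-intersecting")
  sp <- .spacing2(pixelSpacing)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  areaPx <- abs(sum(x * yn - xn * y)) / 2
  areaPx * sp[1] * sp[2]
}

#' Rasterize a polygon to a BinaryMask
#'
#' Scanline fill under the pixel-center-inside rule (even-odd, half-open
#' spans so shared edges are not double counted). The mask area converges to
#' \code{\link{polygonArea}} as spacing shrinks.
#'
#' @param points n x 2 matrix of (col, row) vertices, 0-based pixel units.
#' @param imageShape integer (rows, cols).
#' @param pixelSpacing mm per pixel; scalar or (row, col).
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' m <- rasterizePolygon(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)), c(8, 8), 1)
#' sum(maskGrid(m))  # 16 pixel centers inside
#' @export
rasterizePolygon <- function(points, imageShape, pixelSpacing) {
  .checkPolygon(points)
  if (!.isSimplePolygon(points)) stop("polygon is self-intersecting")
  if (abs(polygonArea(points, 1)) <= 0) stop("degenerate zero-area polygon")
  if (any(points[, 1] < 0) || any(points[, 2] < 0) ||
      any(points[, 1] > imageShape[2] - 1) || any(points[, 2] > imageShape[1] - 1))
    stop("polygon exceeds image bounds")
  grid <- matrix(FALSE, imageShape[1], imageShape[2])
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  for (r in floor(min(y)):ceiling(max(y))) {
    lo <- pmin(y, yn); hi <- pmax(y, yn)
    hit <- lo <= r & r < hi           # half-open rule in y
    if (!any(hit)) next
    xs <- sort(x[hit] + (r - y[hit]) * (xn[hit] - x[hit]) / (yn[hit] - y[hit]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- ceiling(xs[k]); c1 <- ceiling(xs[k + 1]) - 1
      if (c1 >= c0) grid[r + 1, (c0:c1) + 1] <- TRUE
    }
  }
  binaryMask(grid, pixelSpacing)
}

#' Mask area in mm^2
#'
#' @param mask a \linkS4class{BinaryMask}, or a logical matrix together with
#'   \code{pixelSpacing}.
#' @param pixelSpacing required when \code{mask} is a plain matrix.
#' @return foreground pixel count times the pixel area, mm^2.
#' @examples
#' maskArea(binaryMask(matrix(c(rep(TRUE, 10), rep(FALSE, 6)), 4), 0.5))  # 2.5
#' @export
maskArea <- function(mask, pixelSpacing = NULL) {
  mask <- .asMask(mask, pixelSpacing)
  n <- sum(mask@grid)
  if (n == 0L) stop("empty mask has no area")
  sp <- .spacing2(mask@pixelSpacing)
  n * sp[1] * sp[2]
}

.asMask <- function(mask, pixelSpacing = NULL) {
  if (is(mask, "BinaryMask")) return(mask)
  if (is.null(pixelSpacing))
    stop("pixelSpacing is required when mask is a plain matrix")
  binaryMask(mask, pixelSpacing)
}

# 4-connected component labelling (small masks; flood fill)
.labelComponents <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  nlab <- 0L
  idx <- which(grid)
  nr <- nrow(grid)
  for (start in idx) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (p in cur) {
        r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
        nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                if (cc > 1L) p - nr, if (cc < ncol(grid)) p + nr)
        nb <- nb[grid[nb] & lab[nb] == 0L]
        lab[nb] <- nlab
        queue <- c(queue, nb)
      }
    }
  }
  list(labels = lab, n = nlab)
}

#' Maximum medial-lateral (horizontal) width
#'
#' For a mask: the maximum over rows of
#' \code{(rightmost column - leftmost column + 1) * col spacing}, ties broken
#' by the smallest row index; the region must be a single connected component.
#' For a polygon: the exact horizontal extent of the boundary.
#'
#' @param region a \linkS4class{BinaryMask} (or logical matrix with
#'   \code{pixelSpacing}), or an n x 2 polygon vertex matrix.
#' @param pixelSpacing required for plain matrices and polygons.
#' @return list with \code{widthMM} and \code{chord} (2 x 2 matrix of
#'   (col, row) endpoints, 0-based).
#' @examples
#' g <- matrix(FALSE, 6, 12); g[3:6, 2:11] <- TRUE
#' maxHorizontalWidth(binaryMask(g, 0.5))$widthMM  # 5
#' @export
maxHorizontalWidth <- function(region, pixelSpacing = NULL) {
  if (is.matrix(region) && !is.logical(region) && ncol(region) == 2L &&
      !is(region, "BinaryMask")) {
    .checkPolygon(region)
    if (is.null(pixelSpacing)) stop("pixelSpacing required for polygons")
    sp <- .spacing2(pixelSpacing)
    i0 <- which.min(region[, 1]); i1 <- which.max(region[, 1])
    return(list(widthMM = (region[i1, 1] - region[i0, 1]) * sp[2],
                chord = rbind(region[i0, ], region[i1, ])))
  }
  mask <- .asMask(region, pixelSpacing)
  if (!any(mask@grid)) stop("empty region has no width")
  comp <- .labelComponents(mask@grid)
  if (comp$n > 1L) stop("region has ", comp$n, " connected components; expected 1")
  sp <- .spacing2(mask@pixelSpacing)
  rows <- which(apply(mask@grid, 1, any))
  ext <- vapply(rows, function(r) {
    w <- which(mask@grid[r, ])
    c(min(w), max(w))
  }, numeric(2))
  widths <- ext[2, ] - ext[1, ] + 1
  best <- which.max(widths)   # which.max takes the first (smallest row) on ties
  r <- rows[best]
  list(widthMM = widths[best] * sp[2],
       chord = rbind(c(ext[1, best] - 1, r - 1), c(ext[2, best] - 1, r - 1)))
}

#' Iliac wing width from a dorsal/ventral landmark pair
#'
#' Euclidean distance between the two cortical landmarks, in mm.
#'
#' @param dorsalPt,ventralPt (col, row) pixel coordinates.
#' @param pixelSpacing mm per pixel; scalar or (row, col).
#' @return width in mm.
#' @examples
#' iliacWidth(c(0, 0), c(3, 4), 1)  # 5
#' @export
iliacWidth <- function(dorsalPt, ventralPt, pixelSpacing) {
  if (all(dorsalPt == ventralPt)) stop("landmark points coincide")
  sp <- .spacing2(pixelSpacing)
  sqrt(((dorsalPt[1] - ventralPt[1]) * sp[2])^2 +
       ((dorsalPt[2] - ventralPt[2]) * sp[1])^2)
}

#' Assemble pelvis measurements from per-side masks
#'
#' Measures area and maximum horizontal width of each foramen mask and,
#' when landmark pairs are supplied, the two iliac wing widths.
#'
#' @param maskLeft,maskRight \linkS4class{BinaryMask} for the animal's left
#'   and right obturator foramen.
#' @param iliacLeft,iliacRight optional 2 x 2 matrices of (col, row) landmark
#'   pairs (dorsal; ventral).
#' @param pixelSpacing used when the masks are plain matrices.
#' @return A \linkS4class{PelvisMeasurements}.
#' @examples
#' s <- generatePhantom(phantomSpec(rotationDeg = 4, profile = "test",
#'                                  noiseSD = 0))
#' m <- phantomMasks(s)
#' measurePelvis(m$left, m$right)
#' @export
measurePelvis <- function(maskLeft, maskRight, iliacLeft = NULL,
                          iliacRight = NULL, pixelSpacing = NULL) {
  maskLeft <- .asMask(maskLeft, pixelSpacing)
  maskRight <- .asMask(maskRight, pixelSpacing)
  sp <- maskLeft@pixelSpacing
  mk <- function(mask, side) {
    w <- maxHorizontalWidth(mask)
    new("ForamenMeasurement", side = side, areaMM2 = maskArea(mask),
        maxWidthMM = w$widthMM, chord = w$chord)
  }
  il <- ir <- NA_real_
  if (!is.null(iliacLeft) && !is.null(iliacRight)) {
    il <- iliacWidth(iliacLeft[1, ], iliacLeft[2, ], sp)
    ir <- iliacWidth(iliacRight[1, ], iliacRight[2, ], sp)
  }
  new("PelvisMeasurements", foramenLeft = mk(maskLeft, "left"),
      foramenRight = mk(maskRight, "right"),
      iliacLeftMM = il, iliacRightMM = ir,
      pixelSpacingMM = .spacing2(sp)[2])
}

#' Pelvis measurements from polygon annotations
#'
#' Exact (un-rasterized) measurement path: areas via the shoelace formula and
#' widths via the boundary extent.
#'
#' @param polygons named list with elements \code{left} and \code{right},
#'   each an n x 2 (col, row) vertex matrix.
#' @param pixelSpacing mm per pixel; scalar or (row, col).
#' @param landmarks optional named list with 2 x 2 matrices \code{iliac_left},
#'   \code{iliac_right}.
#' @return A \linkS4class{PelvisMeasurements}.
#' @export
measurePolygons <- function(polygons, pixelSpacing, landmarks = NULL) {
  stopifnot(all(c("left", "right") %in% names(polygons)))
  mk <- function(poly, side) {
    w <- maxHorizontalWidth(poly, pixelSpacing)
    new("ForamenMeasurement", side = side,
        areaMM2 = polygonArea(poly, pixelSpacing),
        maxWidthMM = w$widthMM, chord = w$chord)
  }
  il <- ir <- NA_real_
  if (!is.null(landmarks) &&
      all(c("iliac_left", "iliac_right") %in% names(landmarks))) {
    il <- iliacWidth(landmarks$iliac_left[1, ], landmarks$iliac_left[2, ],
                     pixelSpacing)
    ir <- iliacWidth(landmarks$iliac_right[1, ], landmarks$iliac_right[2, ],
                     pixelSpacing)
  }
  new("PelvisMeasurements", foramenLeft = mk(polygons$left, "left"),
      foramenRight = mk(polygons$right, "right"),
      iliacLeftMM = il, iliacRightMM = ir,
      pixelSpacingMM = .spacing2(pixelSpacing)[2])
}

#' Left-right asymmetry indices
#'
#' Signed indices are left minus right (AOFA in mm^2, AOFW and AIWW in mm);
#' magnitudes are available through the accessors with \code{signed = FALSE}.
#' When iliac widths were not measured the AIWW index is flagged unavailable
#' (\code{NA}), never reported as zero.
#'
#' @param x a \linkS4class{PelvisMeasurements}.
#' @return An \linkS4class{AsymmetryResult}.
#' @examples
#' s <- generatePhantom(phantomSpec(rotationDeg = 5, profile = "test",
#'                                  noiseSD = 0))
#' a <- asymmetry(truth(s))
#' aofw(a)   # (5 + 0.912) / 1.644
#' @export
setGeneric("asymmetry", function(x) standardGeneric("asymmetry"))

#' @rdname asymmetry
#' @export
setMethod("asymmetry", "PelvisMeasurements", function(x) {
  avail <- !is.na(x@iliacLeftMM) && !is.na(x@iliacRightMM)
  new("AsymmetryResult",
      aofaSigned = x@foramenLeft@areaMM2 - x@foramenRight@areaMM2,
      aofwSigned = x@foramenLeft@maxWidthMM - x@foramenRight@maxWidthMM,
      aiwwSigned = if (avail) x@iliacLeftMM - x@iliacRightMM else NA_real_,
      aiwwAvailable = avail)
})
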