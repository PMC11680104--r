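# File-format adapters: a minimal DICOM reader (no R DICOM reader is
# available in the supported dependency set, so single-frame monochrome
# little-endian parsing is implemented here), LabelMe-style JSON annotations,
# PNG images/masks, and CSV measurement tables.
#
# Internally everything is mm / mm^2; pixels appear only at these I/O
# boundaries.

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

#' Read a single-frame monochrome DICOM radiograph
#'
#' Supports implicit and explicit VR little endian transfer syntaxes with
#' uncompressed 8- or 16-bit monochrome pixel data. Pixel spacing is taken
#' from PixelSpacing (0028,0030) or, failing that, ImagerPixelSpacing
#' (0018,1164); a file carrying neither is rejected rather than silently
#' assigned a default. MONOCHROME1 intensities are inverted to the
#' MONOCHROME2 convention (higher value = brighter).
#'
#' @param path DICOM file path.
#' @return A \linkS4class{Radiograph}.
#' @export
readDicom <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  pos <- 1L
  explicit <- TRUE
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  } else {
    # no preamble: bare implicit-VR dataset
    explicit <- FALSE
  }
  tags <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(bytes)) {
    grp <- .u16(bytes[pos:(pos + 1L)])
    ele <- .u16(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    isMeta <- grp == 2L
    exp <- if (isMeta) TRUE else explicit
    if (exp) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% longVRs) {
        len <- .u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- ""
      len <- .u32(bytes[(pos):(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length element (", sprintf("%04x,%04x", grp, ele),
                                "): compressed or sequence data is not supported")
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x,%04x", grp, ele)
    tags[[key]] <- val
    if (key == "7fe0,0010") break
    if (key == "0002,0010") {
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts == "1.2.840.10008.1.2.1") explicit <- TRUE
      else stop("unsupported transfer syntax: ", ts)
    }
  }
  str_ <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    trimws(rawToChar(v[v != as.raw(0)]))
  }
  us_ <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) return(NULL)
    .u16(v[1:2])
  }
  nf <- str_("0028,0008")
  if (!is.null(nf) && as.integer(nf) > 1L)
    stop("multi-frame DICOM is not supported")
  rows <- us_("0028,0010"); cols <- us_("0028,0011")
  bits <- us_("0028,0100"); pixrep <- us_("0028,0103")
  photometric <- str_("0028,0004")
  if (is.null(photometric)) photometric <- "MONOCHROME2"
  pix <- tags[["7fe0,0010"]]
  if (is.null(pix) || is.null(rows) || is.null(cols))
    stop("DICOM file is missing pixel data or image dimensions")
  spacingStr <- str_("0028,0030")
  if (is.null(spacingStr)) spacingStr <- str_("0018,1164")
  if (is.null(spacingStr))
    stop("no pixel spacing: neither PixelSpacing (0028,0030) nor ",
         "ImagerPixelSpacing (0018,1164) is present")
  spacing <- as.numeric(strsplit(spacingStr, "\\\\")[[1]])
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (is.null(bits)) bits <- 16L
  signed <- !is.null(pixrep) && pixrep == 1L
  v <- if (bits <= 8L)
    as.numeric(readBin(pix, "integer", n = length(pix), size = 1L,
                       signed = signed))
  else
    as.numeric(readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
                       signed = signed, endian = "little"))
  if (length(v) < rows * cols) stop("pixel data shorter than Rows x Columns")
  m <- matrix(v[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  if (identical(photometric, "MONOCHROME1")) m <- max(m) - m
  srcId <- str_("0008,0018")
  new("Radiograph", pixels = m, pixelSpacing = spacing,
      sourceId = if (is.null(srcId)) basename(path) else srcId,
      photometric = photometric)
}

.KNOWN_LABELS <- c("obturator_left", "obturator_right", "iliac_left",
                   "iliac_right")

#' Read a LabelMe-style polygon annotation
#'
#' Expects a JSON object with a \code{shapes} array of
#' \code{{label, points, shape_type}} entries. Polygons labelled
#' \code{obturator_left}/\code{obturator_right} become the foramen outlines;
#' two-point \code{iliac_left}/\code{iliac_right} shapes become landmark
#' pairs. Unknown labels are kept (under \code{extra}) but ignored by the
#' pipeline, with a warning; duplicated labels resolve deterministically to
#' the first occurrence, with a warning.
#'
#' @param path JSON file path.
#' @return list with \code{polygons} (named list of n x 2 (col, row)
#'   matrices, names "left"/"right"), \code{landmarks} (named list of 2 x 2
#'   matrices), \code{extra}, \code{imageHeight}, \code{imageWidth},
#'   \code{pixelSpacingMM} (NA when absent).
#' @export
readAnnotation <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("annotation JSON has no 'shapes' array")
  polygons <- list(); landmarks <- list(); extra <- list()
  seen <- character(0)
  for (sh in doc$shapes) {
    lab <- sh$label
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (lab %in% seen) {
      warning("duplicate label '", lab, "': keeping the first occurrence")
      next
    }
    seen <- c(seen, lab)
    if (lab %in% c("obturator_left", "obturator_right")) {
      if (nrow(pts) < 3L) stop("polygon '", lab, "' has fewer than 3 points")
      polygons[[sub("obturator_", "", lab)]] <- pts
    } else if (lab %in% c("iliac_left", "iliac_right")) {
      if (nrow(pts) != 2L) stop("landmark '", lab, "' must have 2 points")
      landmarks[[lab]] <- pts
    } else {
      warning("unknown label '", lab, "' kept but ignored by the pipeline")
      extra[[lab]] <- pts
    }
  }
  list(polygons = polygons, landmarks = landmarks, extra = extra,
       imageHeight = doc$imageHeight, imageWidth = doc$imageWidth,
       pixelSpacingMM = if (is.null(doc$pixelSpacingMM)) NA_real_
                        else doc$pixelSpacingMM)
}

#' Write a LabelMe-style annotation
#'
#' @param annotation named list with polygon matrices \code{left},
#'   \code{right} and optional 2 x 2 \code{iliac_left}, \code{iliac_right}
#'   landmark matrices (as produced by \code{\link{generatePhantom}}).
#' @param path output JSON path.
#' @param imageHeight,imageWidth image dimensions in px.
#' @param imagePath relative path stored in the annotation.
#' @param pixelSpacingMM optional mm-per-pixel stored alongside.
#' @return invisibly, the path.
#' @export
writeAnnotation <- function(annotation, path, imageHeight, imageWidth,
                            imagePath = "", pixelSpacingMM = NULL) {
  shapes <- list()
  toPts <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  for (side in c("left", "right")) {
    if (!is.null(annotation[[side]]))
      shapes[[length(shapes) + 1L]] <-
        list(label = paste0("obturator_", side),
             points = toPts(annotation[[side]]), shape_type = "polygon")
  }
  for (lm in c("iliac_left", "iliac_right")) {
    if (!is.null(annotation[[lm]]))
      shapes[[length(shapes) + 1L]] <-
        list(label = lm, points = toPts(annotation[[lm]]),
             shape_type = "line")
  }
  doc <- list(shapes = shapes, imageHeight = imageHeight,
              imageWidth = imageWidth, imagePath = imagePath)
  if (!is.null(pixelSpacingMM)) doc$pixelSpacingMM <- pixelSpacingMM
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an intensity image as PNG
#'
#' Values are clipped to [0, 1] and stored as 8-bit grayscale.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a grayscale PNG as a numeric matrix in [0, 1]
#'
#' @param path PNG path.
#' @return numeric matrix.
#' @export
readImagePNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write a binary mask as an 8-bit 0/255 PNG
#'
#' @param mask \linkS4class{BinaryMask} or logical matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMaskPNG <- function(mask, path) {
  g <- if (is(mask, "BinaryMask")) maskGrid(mask) else mask
  png::writePNG(g * 1.0, path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#'
#' @param path PNG path.
#' @param pixelSpacingMM mm per pixel to attach.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMaskPNG <- function(path, pixelSpacingMM) {
  binaryMask(readImagePNG(path) > 0.5, pixelSpacingMM)
}

#' Measure every sample of an on-disk phantom dataset
#'
#' Reads the dataset written by \code{\link{generateDataset}} and produces a
#' measurement table with the same columns as the truth CSV, measured either
#' from the rasterized masks or from the exact polygon annotations.
#'
#' @param dir dataset directory (must contain \code{dataset.json}).
#' @param source "masks" or "annotations".
#' @return data.frame: sample_id, area/width per side, iliac widths.
#' @export
measureDataset <- function(dir, source = c("masks", "annotations")) {
  source <- match.arg(source)
  manifest <- jsonlite::fromJSON(file.path(dir, "dataset.json"))
  sp <- manifest$pixel_spacing_mm
  files <- sort(list.files(file.path(dir, "annotations"), "\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no annotations found under ", dir)
  rows <- lapply(files, function(f) {
    id <- sub("\\.json$", "", basename(f))
    ann <- readAnnotation(f)
    if (source == "annotations") {
      pm <- measurePolygons(ann$polygons, sp, ann$landmarks)
    } else {
      ml <- readMaskPNG(file.path(dir, "masks", paste0(id, "_left.png")), sp)
      mr <- readMaskPNG(file.path(dir, "masks", paste0(id, "_right.png")), sp)
      pm <- measurePelvis(ml, mr, iliacLeft = ann$landmarks$iliac_left,
                          iliacRight = ann$landmarks$iliac_right)
    }
    iw <- iliacWidths(pm)
    data.frame(sample_id = id,
               area_left_mm2 = foramen(pm, "left")$areaMM2,
               area_right_mm2 = foramen(pm, "right")$areaMM2,
               width_left_mm = foramen(pm, "left")$maxWidthMM,
               width_right_mm = foramen(pm, "right")$maxWidthMM,
               iliac_left_mm = unname(iw["left"]),
               iliac_right_mm = unname(iw["right"]))
  })
  do.call(rbind, rows)
}

#' Read/write measurement CSV tables
#'
#' Comma separated, UTF-8, "." decimal, header row mandatory.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readMeasurementCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("area_left_mm2", "area_right_mm2", "width_left_mm",
            "width_right_mm")
  if (!all(need %in% names(df)))
    stop("measurement CSV must contain columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname readMeasurementCSV
#' @param df data.frame to write.
#' @export
writeMeasurementCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
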