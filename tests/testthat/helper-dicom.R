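# Minimal test-only DICOM writer (explicit VR little endian, single-frame
# monochrome). Only used to exercise readDicom() round trips; the package
# itself does not write DICOM.

.raw16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

.dcmStr <- function(group, elem, vr, s) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1)
    v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(.raw16(group), .raw16(elem), charToRaw(vr), .raw16(length(v)), v)
}

.dcmUS <- function(group, elem, x)
  c(.raw16(group), .raw16(elem), charToRaw("US"), .raw16(2L), .raw16(x))

.dcmPixelData <- function(pix16) {
  v <- writeBin(as.integer(pix16), raw(), size = 2, endian = "little")
  c(.raw16(0x7fe0), .raw16(0x0010), charToRaw("OW"), .raw16(0L),
    writeBin(length(v), raw(), size = 4, endian = "little"), v)
}

# pixels: integer matrix (row-major image); spacing: c(row, col) mm or NULL
writeTestDicom <- function(path, pixels, spacing = c(0.2, 0.2),
                           photometric = "MONOCHROME2",
                           spacingTag = c("pixel", "imager"),
                           frames = NULL) {
  spacingTag <- match.arg(spacingTag)
  out <- c(raw(128), charToRaw("DICM"),
           .dcmStr(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
           .dcmStr(0x0008, 0x0018, "UI", "1.2.3.4.5"),
           .dcmStr(0x0028, 0x0004, "CS", photometric))
  if (!is.null(frames))
    out <- c(out, .dcmStr(0x0028, 0x0008, "IS", as.character(frames)))
  out <- c(out,
           .dcmUS(0x0028, 0x0010, nrow(pixels)),
           .dcmUS(0x0028, 0x0011, ncol(pixels)))
  if (!is.null(spacing)) {
    s <- paste(format(spacing, trim = TRUE), collapse = "\\")
    if (spacingTag == "pixel")
      out <- c(out, .dcmStr(0x0028, 0x0030, "DS", s))
    else
      out <- c(out, .dcmStr(0x0018, 0x1164, "DS", s))
  }
  out <- c(out,
           .dcmUS(0x0028, 0x0100, 16L),
           .dcmUS(0x0028, 0x0103, 0L),
           .dcmPixelData(as.vector(t(pixels))))
  writeBin(out, path)
  invisible(path)
}
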