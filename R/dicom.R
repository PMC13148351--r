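# Minimal single-frame DICOM RT Dose I/O (explicit VR, little endian).
#
# Only the planar RT Dose tag set needed by the QA workflow is handled:
# dose grid scaling, pixel spacing, image position, and 16-bit unsigned
# pixel data. Multi-frame files are rejected (the workflow is strictly 2-D).

RTDOSE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# --- byte-level helpers ------------------------------------------------------

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

padEven <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

strRaw <- function(s, pad = as.raw(0x20)) padEven(charToRaw(s), pad)

# One explicit-VR data element.
dcmElement <- function(group, element, vr, value) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  hdr <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (long) {
    c(hdr, as.raw(c(0, 0)), uint32le(length(value)), value)
  } else {
    c(hdr, uint16le(length(value)), value)
  }
}

dsValue <- function(x) strRaw(paste(formatC(x, digits = 12, format = "g"),
                                    collapse = "\\"))

# Deterministic instance UID derived from grid content.
doseUid <- function(m) {
  h <- (sum(abs(m)) * 1e6 + nrow(m) * 7919 + ncol(m) * 104729) %% 1e14
  sprintf("2.25.%d%d%.0f", nrow(m), ncol(m), h)
}

#' Write a DoseMap as a single-frame DICOM RT Dose file
#'
#' Doses are stored as 16-bit unsigned integers with a dose-grid scaling of
#' \code{max(dose)/65535} Gy per count (1e-4 if the map is all zero), so the
#' maximum dose uses the full integer range and the quantization error per
#' pixel is at most scaling/2. The file uses the explicit-VR little-endian
#' transfer syntax with the minimal planar RT Dose tag set (rows, columns,
#' pixel spacing, image position, dose units GY, dose grid scaling, pixel
#' data).
#'
#' @param map a [DoseMap-class]
#' @param path output path
#' @return invisibly, the dose-grid scaling used (Gy per count)
#' @export
writeRTDose <- function(map, path) {
  validObject(map)
  m <- map@dose
  maxd <- max(m)
  scaling <- if (maxd > 0) maxd / 65535 else 1e-4
  stored <- matrix(as.integer(round(m / scaling)), nrow(m), ncol(m))
  sop <- doseUid(m)
  # DICOM pixel data is row-major; ImagePositionPatient is (x, y, z) with
  # x along columns and y along rows
  body <- c(
    dcmElement(0x0008, 0x0016, "UI", strRaw(RTDOSE_SOP_CLASS, as.raw(0))),
    dcmElement(0x0008, 0x0018, "UI", strRaw(sop, as.raw(0))),
    dcmElement(0x0008, 0x0060, "CS", strRaw("RTDOSE")),
    dcmElement(0x0020, 0x0032, "DS",
               dsValue(c(map@origin[2], map@origin[1], 0))),
    dcmElement(0x0020, 0x0037, "DS", dsValue(c(1, 0, 0, 0, 1, 0))),
    dcmElement(0x0028, 0x0002, "US", uint16le(1L)),
    dcmElement(0x0028, 0x0004, "CS", strRaw("MONOCHROME2")),
    dcmElement(0x0028, 0x0010, "US", uint16le(nrow(m))),
    dcmElement(0x0028, 0x0011, "US", uint16le(ncol(m))),
    dcmElement(0x0028, 0x0030, "DS", dsValue(map@pixelSpacing)),
    dcmElement(0x0028, 0x0100, "US", uint16le(16L)),
    dcmElement(0x0028, 0x0101, "US", uint16le(16L)),
    dcmElement(0x0028, 0x0102, "US", uint16le(15L)),
    dcmElement(0x0028, 0x0103, "US", uint16le(0L)),
    dcmElement(0x3004, 0x0002, "CS", strRaw("GY")),
    dcmElement(0x3004, 0x0004, "CS", strRaw("PHYSICAL")),
    dcmElement(0x3004, 0x000E, "DS", dsValue(scaling)),
    dcmElement(0x7FE0, 0x0010, "OW",
               writeBin(as.vector(t(stored)), raw(), size = 2L,
                        endian = "little"))
  )
  metaBody <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcmElement(0x0002, 0x0002, "UI", strRaw(RTDOSE_SOP_CLASS, as.raw(0))),
    dcmElement(0x0002, 0x0003, "UI", strRaw(sop, as.raw(0))),
    dcmElement(0x0002, 0x0010, "UI", strRaw(TS_EXPLICIT_LE, as.raw(0))),
    dcmElement(0x0002, 0x0012, "UI", strRaw("2.25.826123", as.raw(0)))
  )
  meta <- c(dcmElement(0x0002, 0x0000, "UL", uint32le(length(metaBody))),
            metaBody)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(scaling)
}

# Read one explicit-VR element header; returns list(tag, vr, len, next position).
readElementHeader <- function(bytes, pos) {
  u16 <- function(p) readBin(bytes[p:(p + 1L)], "integer", size = 2L,
                             endian = "little", signed = FALSE)
  group <- u16(pos); element <- u16(pos + 2L)
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                   endian = "little")
    list(group = group, element = element, vr = vr, len = len,
         valuePos = pos + 12L)
  } else {
    list(group = group, element = element, vr = vr, len = u16(pos + 6L),
         valuePos = pos + 8L)
  }
}

parseDS <- function(bytes) {
  as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]])
}

#' Read a single-frame DICOM RT Dose file
#'
#' Parses an explicit-VR little-endian RT Dose file and reconstructs the dose
#' grid as \code{stored integers x dose-grid scaling} (Gy). Pixel spacing and
#' origin are taken from the geometry tags. Multi-frame files and files
#' missing DoseGridScaling or PixelSpacing raise an error naming the tag.
#'
#' @param path DICOM file path
#' @return a [DoseMap-class]
#' @export
readRTDose <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  stopIfNot(length(bytes) > 132L &&
              identical(rawToChar(bytes[129:132]), "DICM"),
            "not a DICOM file (missing DICM magic)")
  pos <- 133L
  tags <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    h <- readElementHeader(bytes, pos)
    if (h$len < 0)
      stop("undefined-length element encountered: unsupported encoding",
           call. = FALSE)
    key <- sprintf("%04X,%04X", h$group, h$element)
    val <- if (h$len > 0) bytes[h$valuePos:(h$valuePos + h$len - 1L)] else raw(0)
    tags[[key]] <- list(vr = h$vr, value = val)
    pos <- h$valuePos + h$len
    if (key == "7FE0,0010") break
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts)) {
    tsuid <- trimws(rawToChar(ts$value[ts$value != as.raw(0)]))
    stopIfNot(identical(tsuid, TS_EXPLICIT_LE),
              sprintf("unsupported transfer syntax: %s", tsuid))
  }
  need <- function(key, name) {
    t <- tags[[key]]
    if (is.null(t))
      stop(sprintf("required tag %s (%s) missing", name, key), call. = FALSE)
    t
  }
  nf <- tags[["0028,0008"]]
  if (!is.null(nf)) {
    frames <- suppressWarnings(as.integer(trimws(rawToChar(nf$value))))
    if (!is.na(frames) && frames > 1L)
      stop(sprintf("multi-frame RT Dose (NumberOfFrames = %d) not supported: 2-D grids only",
                   frames), call. = FALSE)
  }
  u16 <- function(r) readBin(r, "integer", size = 2L, endian = "little",
                             signed = FALSE)
  rows <- u16(need("0028,0010", "Rows")$value)
  cols <- u16(need("0028,0011", "Columns")$value)
  spacing <- parseDS(need("0028,0030", "PixelSpacing")$value)
  scaling <- parseDS(need("3004,000E", "DoseGridScaling")$value)
  pix <- need("7FE0,0010", "PixelData")$value
  origin <- c(0, 0)
  ipp <- tags[["0020,0032"]]
  if (!is.null(ipp)) {
    xyz <- parseDS(ipp$value)
    origin <- c(xyz[2], xyz[1])
  }
  stored <- readBin(pix, "integer", n = rows * cols, size = 2L,
                    endian = "little", signed = FALSE)
  stopIfNot(length(stored) == rows * cols,
            "PixelData length does not match Rows x Columns")
  dose <- t(matrix(stored, nrow = cols, ncol = rows)) * scaling
  DoseMap(dose, pixelSpacing = spacing, origin = origin)
}
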