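#' Construct a ScannedFilm
#'
#' @param pixels numeric array \code{[rows, cols, 3]} of integer-valued counts
#' @param bitDepth bits per channel (8 or 16)
#' @param pixelSpacing numeric length-2 (row, col) spacing in mm, or a single
#'   value used for both axes
#' @param orientationApplied character vector of applied transforms
#' @param metadata provenance list
#' @return a [ScannedFilm-class]
#' @export
ScannedFilm <- function(pixels, bitDepth = 16L, pixelSpacing = c(0.254, 0.254),
                        orientationApplied = character(0), metadata = list()) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("ScannedFilm", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSpacing = as.numeric(pixelSpacing),
      orientationApplied = orientationApplied, metadata = metadata)
}

#' Construct a DoseMap
#'
#' @param dose numeric matrix of absorbed dose in Gy
#' @param pixelSpacing numeric length-2 (row, col) spacing in mm, or a single
#'   value used for both axes
#' @param origin numeric length-2 (row, col) mm position of pixel (1,1) center
#' @return a [DoseMap-class]
#' @export
DoseMap <- function(dose, pixelSpacing = c(1, 1), origin = c(0, 0)) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("DoseMap", dose = dose, pixelSpacing = as.numeric(pixelSpacing),
      origin = as.numeric(origin))
}

#' Read a scanner TIFF as a ScannedFilm
#'
#' Reads an uncompressed RGB TIFF (8 or 16 bits per channel) and restores the
#' raw integer pixel values. The physical pixel spacing is taken from the
#' TIFF resolution tags (\code{25.4 / dpi} mm on each axis); if the file
#' carries no resolution metadata an explicit \code{dpi} must be supplied —
#' the spacing is never guessed, because a wrong spacing silently corrupts
#' every distance-to-agreement computation downstream.
#'
#' @param path TIFF file path
#' @param dpi optional scan resolution override (dots per inch)
#' @return a [ScannedFilm-class]
#' @examples
#' \dontrun{film <- readTiffFilm("scan.tif", dpi = 100)}
#' @export
readTiffFilm <- function(path, dpi = NULL) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  img <- tiff::readTIFF(path, info = TRUE)
  d <- dim(img)
  if (length(d) != 3L || d[3] < 3L)
    stop("not a 3-channel image: expected an RGB TIFF", call. = FALSE)
  if (d[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  bits <- as.integer(bits[1])
  if (!bits %in% c(8L, 16L))
    stop(sprintf("unsupported bit depth: %d (need 8 or 16)", bits), call. = FALSE)
  if (is.null(dpi)) {
    xr <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (is.null(xr) || is.null(unit) || !identical(unit, "inch"))
      stop(paste0("missing resolution metadata (x.resolution/resolution.unit",
                  " tags): supply dpi explicitly"), call. = FALSE)
    yr <- attr(img, "y.resolution")
    if (is.null(yr)) yr <- xr
    spacing <- c(25.4 / yr, 25.4 / xr)
    dpi <- c(yr, xr)
  } else {
    spacing <- rep(25.4 / dpi, 2L)
  }
  # readTIFF scales to [0, 1]; restore the stored integer counts
  pv <- array(round(as.vector(img) * (2^bits - 1)), dim(img))
  ScannedFilm(pv, bitDepth = bits, pixelSpacing = spacing,
              metadata = list(path = path, dpi = dpi))
}

#' Write a ScannedFilm as an uncompressed TIFF
#'
#' Pixel values are stored at the film's bit depth without rescaling. The
#' underlying TIFF writer does not emit resolution tags, so the dpi is not
#' embedded; [readTiffFilm()] then requires an explicit \code{dpi} argument
#' for files written by this function.
#'
#' @param film a [ScannedFilm-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeTiffFilm <- function(film, path) {
  bits <- film@bitDepth
  img <- film@pixels / (2^bits - 1)
  tiff::writeTIFF(img, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Resample a dose map onto a new pixel spacing
#'
#' Bilinear interpolation onto a grid with the requested spacing. The
#' physical extent (rows x spacing, cols x spacing, edge-to-edge) is
#' preserved to within one target pixel and the resampled first-pixel center
#' is placed so the covered area is unchanged. Constant fields resample
#' exactly; affine fields are reproduced to numerical tolerance in the
#' interior. Negative interpolation round-off is clamped to zero.
#'
#' @param map a [DoseMap-class]
#' @param targetSpacingMm numeric length-2 (row, col) target spacing in mm,
#'   or a single value for both axes
#' @return a [DoseMap-class] on the new grid
#' @export
resampleToGrid <- function(map, targetSpacingMm) {
  if (length(targetSpacingMm) == 1L) targetSpacingMm <- rep(targetSpacingMm, 2L)
  stopIfNot(all(is.finite(targetSpacingMm)) && all(targetSpacingMm > 0),
            "target spacing must be positive")
  sp <- map@pixelSpacing
  if (isTRUE(all.equal(sp, targetSpacingMm, tolerance = 1e-12))) return(map)
  d <- dim(map@dose)
  nNew <- pmax(1L, as.integer(round(d * sp / targetSpacingMm)))
  # keep the covered physical area centered: first new center shifts by half
  # the spacing difference
  originNew <- map@origin - sp / 2 + targetSpacingMm / 2
  # fractional source indices of the new pixel centers
  rows <- (originNew[1] + (seq_len(nNew[1]) - 1) * targetSpacingMm[1] -
             map@origin[1]) / sp[1] + 1
  cols <- (originNew[2] + (seq_len(nNew[2]) - 1) * targetSpacingMm[2] -
             map@origin[2]) / sp[2] + 1
  rc <- matrix(rows, nNew[1], nNew[2])
  cc <- matrix(cols, nNew[1], nNew[2], byrow = TRUE)
  v <- bilinearSample(map@dose, as.vector(rc), as.vector(cc), clamp = TRUE)
  DoseMap(matrix(pmax(v, 0), nNew[1], nNew[2]),
          pixelSpacing = targetSpacingMm, origin = originNew)
}
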