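#' Linearly rescale intensities to [0,1]
#'
#' Rescales by the image's own minimum and maximum. A constant image maps to
#' all zeros (degenerate range). The operation is idempotent: normalizing a
#' normalized image changes nothing.
#'
#' @param image an \linkS4class{Image2D}.
#' @return An \linkS4class{Image2D} with pixels in [0,1].
#' @export
normalizeIntensity <- function(image) {
  stopifnot(is(image, "Image2D"))
  p <- image@pixels
  rng <- range(p)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else p * 0
  Image2D(p, image@spacing)
}

.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
.isPng   <- function(path) grepl("\\.png$", path, ignore.case = TRUE)
.isTiff  <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

.readRaster <- function(path) {
  if (.isPng(path)) {
    px <- png::readPNG(path)
  } else if (.isTiff(path)) {
    px <- tiff::readTIFF(path)
  } else {
    stop("unsupported 2D image format (expected PNG or TIFF): ", path)
  }
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)  # collapse channels
  px
}

#' Read a grayscale image from disk
#'
#' Reads PNG or TIFF (2D) or NIfTI (.nii/.nii.gz, one slice of a volume) and
#' returns intensities linearly rescaled to [0,1] by the image's own range
#' (a constant image becomes all zeros). Pixel spacing comes from the NIfTI
#' header when present, else from \code{spacing_override}, else (1,1) mm.
#' Multichannel 2D images are collapsed to their channel mean before
#' rescaling.
#'
#' @param path image file path.
#' @param spacing_override optional numeric(2), mm per pixel (row, col);
#'   overrides a missing or absent header spacing.
#' @param slice slice index (1-based along the third axis), required for
#'   NIfTI volumes.
#' @return An \linkS4class{Image2D}.
#' @export
readImage2D <- function(path, spacing_override = NULL, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  spacing <- NULL
  if (.isNifti(path)) {
    vol <- RNifti::readNifti(path)
    pd <- attr(RNifti::niftiHeader(vol), "pixdim")
    pd <- RNifti::pixdim(vol)
    arr <- as.array(vol)
    if (length(dim(arr)) >= 3L && dim(arr)[3] > 1L) {
      if (is.null(slice))
        stop("a slice index is required for a 3D NIfTI volume")
      if (slice < 1L || slice > dim(arr)[3])
        stop("slice index out of range")
      px <- arr[, , slice]
    } else {
      px <- if (length(dim(arr)) == 2L) arr else arr[, , 1]
    }
    if (length(pd) >= 2L && all(pd[1:2] > 0)) spacing <- pd[1:2]
  } else {
    px <- .readRaster(path)
  }
  if (is.null(spacing)) {
    spacing <- if (!is.null(spacing_override)) spacing_override else c(1, 1)
  }
  normalizeIntensity(Image2D(px, spacing))
}

#' Write / read a binary mask
#'
#' Masks are written as 8-bit PNG or TIFF with foreground 1 mapped to white.
#' The round trip \code{readMask(writeMask(m, f))} reproduces \code{m}
#' exactly.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path ending in .png or .tif/.tiff.
#' @return \code{writeMask} returns \code{path} invisibly; \code{readMask}
#'   returns a \linkS4class{BinaryMask}.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  if (.isPng(path)) {
    png::writePNG(v, target = path)
  } else if (.isTiff(path)) {
    tiff::writeTIFF(v, where = path)
  } else {
    stop("unsupported mask format (expected PNG or TIFF): ", path)
  }
  invisible(path)
}

#' @rdname writeMask
#' @param spacing_override optional numeric(2) spacing for the mask read back.
#' @export
readMask <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- .readRaster(path)
  spacing <- if (!is.null(spacing_override)) spacing_override else c(1, 1)
  BinaryMask((px > 0.5) * 1, spacing)
}

#' Write an Image2D to disk
#'
#' Intensities are clipped to [0,1] and stored as PNG or TIFF.
#'
#' @param image an \linkS4class{Image2D}.
#' @param path output path ending in .png or .tif/.tiff.
#' @return \code{path}, invisibly.
#' @export
writeImage2D <- function(image, path) {
  stopifnot(is(image, "Image2D"))
  v <- pmin(pmax(image@pixels, 0), 1)
  if (.isPng(path)) {
    png::writePNG(v, target = path)
  } else if (.isTiff(path)) {
    tiff::writeTIFF(v, where = path)
  } else {
    stop("unsupported image format (expected PNG or TIFF): ", path)
  }
  invisible(path)
}
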