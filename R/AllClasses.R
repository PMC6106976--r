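#' @import methods
#' @importFrom stats rnorm runif sd var cor
#' @useDynLib UnifiedLSM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Image2D: a 2D grayscale image with physical pixel spacing
#'
#' The carrier for all grayscale rasters in the package: input CT slices,
#' intermediate filter outputs, bias fields and edge indicators. Pixels are a
#' numeric matrix (rows x cols, row-major screen convention: row 1 is the top
#' scanline); \code{spacing} holds the physical extent of one pixel in mm as
#' \code{(row_mm, col_mm)}. Images read from disk are linearly rescaled to
#' [0,1]; derived rasters (gradient magnitudes, bias fields) may exceed that
#' range, so the class only enforces finiteness.
#'
#' @slot pixels numeric matrix, at least 3 x 3, finite values only.
#' @slot spacing numeric(2), strictly positive, mm per pixel (row, col).
#' @export
setClass("Image2D",
  representation(pixels = "matrix", spacing = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 3L || ncol(p) < 3L) return("image must be at least 3 x 3")
    if (!all(is.finite(p))) return("pixels must be finite")
    s <- object@spacing
    if (length(s) != 2L || !all(is.finite(s)) || any(s <= 0))
      return("spacing must be two strictly positive numbers (row_mm, col_mm)")
    TRUE
  })

#' Construct an Image2D
#'
#' @param pixels numeric matrix of intensities.
#' @param spacing numeric(2) pixel spacing in mm, \code{(row_mm, col_mm)}.
#' @return An \linkS4class{Image2D}.
#' @examples
#' img <- Image2D(matrix(runif(25), 5, 5))
#' dim(img)
#' @export
Image2D <- function(pixels, spacing = c(1, 1)) {
  new("Image2D", pixels = pixels, spacing = as.numeric(spacing))
}

#' BinaryMask: a {0,1} raster aligned to an image
#'
#' Holds region-growing output, HMRF label fields, final segmentations and
#' ground truth. Values are stored as a numeric matrix containing exactly 0
#' and 1.
#'
#' @slot values numeric matrix with entries in {0,1}.
#' @slot spacing numeric(2), mm per pixel, inherited from the paired image.
#' @export
setClass("BinaryMask",
  representation(values = "matrix", spacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be a numeric matrix")
    if (!all(v %in% c(0, 1))) return("mask values must be exactly 0 or 1")
    s <- object@spacing
    if (length(s) != 2L || !all(is.finite(s)) || any(s <= 0))
      return("spacing must be two strictly positive numbers")
    TRUE
  })

#' Construct a BinaryMask
#'
#' @param values matrix (numeric or logical) with entries in {0,1}.
#' @param spacing numeric(2) pixel spacing in mm.
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' m <- BinaryMask(matrix(c(0, 1), 4, 4))
#' maskArea(m)
#' @export
BinaryMask <- function(values, spacing = c(1, 1)) {
  storage.mode(values) <- "double"
  new("BinaryMask", values = values, spacing = as.numeric(spacing))
}

#' LevelSetField: a scalar field phi whose zero level set is the contour
#'
#' The segmented object is the set {phi > 0} (see \code{\link{zeroLevelMask}}).
#'
#' @slot phi numeric matrix, finite.
#' @slot spacing numeric(2), mm per pixel.
#' @export
setClass("LevelSetField",
  representation(phi = "matrix", spacing = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@phi))) return("phi must be finite")
    s <- object@spacing
    if (length(s) != 2L || any(s <= 0)) return("spacing must be positive")
    TRUE
  })

#' Construct a LevelSetField
#' @param phi numeric matrix.
#' @param spacing numeric(2) pixel spacing in mm.
#' @return A \linkS4class{LevelSetField}.
#' @export
LevelSetField <- function(phi, spacing = c(1, 1)) {
  new("LevelSetField", phi = phi, spacing = as.numeric(spacing))
}

#' RoiRect: a half-open rectangular region of interest
#'
#' Indices are 0-based and half-open: the rectangle covers pixel rows
#' \code{[row0, row1)} and columns \code{[col0, col1)} of the full image.
#' This matches the rectangle a user draws around a tumor to restrict
#' segmentation.
#'
#' @slot row0,col0,row1,col1 integer corner indices, 0-based, half-open.
#' @export
setClass("RoiRect",
  representation(row0 = "integer", col0 = "integer",
                 row1 = "integer", col1 = "integer"),
  validity = function(object) {
    if (object@row0 < 0L || object@col0 < 0L) return("corners must be >= 0")
    if (object@row1 <= object@row0 || object@col1 <= object@col0)
      return("rectangle must have positive extent")
    area <- (object@row1 - object@row0) * (object@col1 - object@col0)
    if (area < 9L) return("ROI area must be at least 9 pixels")
    TRUE
  })

#' Construct a RoiRect
#' @param row0,col0 top-left corner (0-based, inclusive).
#' @param row1,col1 bottom-right corner (0-based, exclusive).
#' @return A \linkS4class{RoiRect}.
#' @examples
#' RoiRect(10, 10, 40, 50)
#' @export
RoiRect <- function(row0, col0, row1, col1) {
  new("RoiRect", row0 = as.integer(row0), col0 = as.integer(col0),
      row1 = as.integer(row1), col1 = as.integer(col1))
}

#' HMRFState: label field plus per-class Gaussian parameters
#'
#' State of the hidden Markov random field relabeling stage: a binary label
#' field and the Gaussian intensity model (mean, variance) of each of the two
#' classes.
#'
#' @slot labels numeric matrix with entries in {0,1}.
#' @slot mu numeric(2), class means (index 1 = label 0, index 2 = label 1).
#' @slot sigma2 numeric(2), class variances, strictly positive.
#' @slot pottsBeta single number, pairwise clique weight of the Potts prior.
#' @export
setClass("HMRFState",
  representation(labels = "matrix", mu = "numeric", sigma2 = "numeric",
                 pottsBeta = "numeric"),
  validity = function(object) {
    if (!all(object@labels %in% c(0, 1))) return("labels must be 0/1")
    if (length(object@mu) != 2L || length(object@sigma2) != 2L)
      return("mu and sigma2 must each have length 2")
    if (any(object@sigma2 <= 0)) return("class variances must be positive")
    TRUE
  })

#' MetricsReport: the five standard segmentation evaluation measures
#'
#' Volumetric overlap error and relative volume difference in percent;
#' average, root-mean-square and maximum symmetric surface distance in mm.
#' Zero in every slot means an exact match with the reference.
#'
#' @slot voe volumetric overlap error, percent, in [0,100].
#' @slot rvd signed relative volume difference, percent.
#' @slot asd average symmetric surface distance, mm.
#' @slot rmsd root-mean-square symmetric surface distance, mm.
#' @slot msd maximum symmetric surface distance, mm.
#' @export
setClass("MetricsReport",
  representation(voe = "numeric", rvd = "numeric", asd = "numeric",
                 rmsd = "numeric", msd = "numeric"),
  validity = function(object) {
    if (object@voe < 0 || object@voe > 100) return("voe must lie in [0,100]")
    if (object@asd < 0 || object@rmsd < 0 || object@msd < 0)
      return("surface distances must be nonnegative")
    TRUE
  })

setMethod("show", "Image2D", function(object) {
  cat(sprintf("Image2D: %d x %d px, spacing (%.3g, %.3g) mm, range [%.4g, %.4g]\n",
              nrow(object@pixels), ncol(object@pixels),
              object@spacing[1], object@spacing[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground (%.1f%%)\n",
              nrow(object@values), ncol(object@values),
              sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "LevelSetField", function(object) {
  cat(sprintf("LevelSetField: %d x %d px, phi in [%.3g, %.3g], |{phi>0}| = %d\n",
              nrow(object@phi), ncol(object@phi),
              min(object@phi), max(object@phi), sum(object@phi > 0)))
})

setMethod("show", "RoiRect", function(object) {
  cat(sprintf("RoiRect: rows [%d, %d) x cols [%d, %d)\n",
              object@row0, object@row1, object@col0, object@col1))
})

setMethod("show", "HMRFState", function(object) {
  cat(sprintf("HMRFState: %d x %d labels, mu = (%.4g, %.4g), sigma2 = (%.3g, %.3g), potts beta = %.3g\n",
              nrow(object@labels), ncol(object@labels),
              object@mu[1], object@mu[2],
              object@sigma2[1], object@sigma2[2], object@pottsBeta))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: VOE %.2f%%  RVD %.2f%%  ASD %.3f mm  RMSD %.3f mm  MSD %.3f mm\n",
              object@voe, object@rvd, object@asd, object@rmsd, object@msd))
})

#' @describeIn Image2D matrix dimensions of the pixel grid
#' @param x object.
#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

#' @describeIn BinaryMask matrix dimensions of the mask
#' @param x object.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

#' @describeIn Image2D extract the pixel matrix
#' @export
setMethod("as.matrix", "Image2D", function(x, ...) x@pixels)

#' @describeIn BinaryMask extract the 0/1 matrix
#' @export
setMethod("as.matrix", "BinaryMask", function(x, ...) x@values)

#' @describeIn LevelSetField extract the phi matrix
#' @export
setMethod("as.matrix", "LevelSetField", function(x, ...) x@phi)

#' Pixel spacing accessor
#' @param x an Image2D, BinaryMask or LevelSetField.
#' @return numeric(2): mm per pixel along (row, col).
#' @export
pixelSpacing <- function(x) {
  stopifnot(isVirtualClass(class(x)) == FALSE)
  x@spacing
}

#' Foreground pixel count of a mask
#' @param mask a \linkS4class{BinaryMask}.
#' @return integer: number of 1 pixels.
#' @export
maskArea <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  as.integer(sum(mask@values))
}
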