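#' Seeded region growing with a gray-level homogeneity criterion
#'
#' Grows a region from each seed over 4-connected neighbors: a candidate
#' pixel joins when the absolute difference between its gray value and the
#' running mean of the region is strictly less than \code{W}; the mean is
#' recomputed as pixels join. Candidates are processed in FIFO
#' (breadth-first) order, neighbors enqueued N, S, W, E; this fixed order
#' makes grayscale results deterministic. Each seed grows independently and
#' the result is the union of the per-seed regions.
#'
#' On a binary image any \code{W} in (0,1] extracts exactly the connected
#' component containing the seed, independent of where in the component the
#' seed sits -- which is why the pipeline binarizes first.
#'
#' @param image an \linkS4class{Image2D}.
#' @param seeds seed pixels, 1-based matrix indices: a length-2 vector
#'   \code{c(row, col)} or an n x 2 matrix with one seed per row.
#' @param W homogeneity threshold (> 0).
#' @return A \linkS4class{BinaryMask} covering all seed pixels.
#' @examples
#' ph <- makeLiverPhantom(liverPhantomSpec(noise_sigma = 0))
#' bw <- preprocessPipeline(ph$image)
#' rough <- regionGrow(Image2D(as.matrix(bw)), c(80, 62), W = 0.5)
#' @export
regionGrow <- function(image, seeds, W = 0.5) {
  stopifnot(is(image, "Image2D"))
  if (W <= 0) stop("W must be > 0")
  if (is.numeric(seeds) && is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2, byrow = TRUE)
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 2L || nrow(seeds) < 1L)
    stop("seeds must be a nonempty n x 2 matrix of (row, col)")
  d <- dim(image)
  if (any(seeds[, 1] < 1L) || any(seeds[, 1] > d[1]) ||
      any(seeds[, 2] < 1L) || any(seeds[, 2] > d[2]))
    stop("seed out of image bounds")
  storage.mode(seeds) <- "integer"
  BinaryMask(.regionGrowCpp(image@pixels, seeds, W), image@spacing)
}

#' Fill interior holes of a binary mask
#'
#' Background connected components (4-connectivity) that do not touch the
#' image border are set to foreground; foreground pixels are never changed.
#' Used after level set refinement to close holes left by vessels and noise
#' inside the liver.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return A \linkS4class{BinaryMask} with holes filled.
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  # pad the complement with a one-pixel background frame and flood from a
  # corner: everything reached is outside; unreached background is a hole
  comp <- matrix(0, nrow(v) + 2L, ncol(v) + 2L)
  comp[2:(nrow(v) + 1L), 2:(ncol(v) + 1L)] <- 1 - v
  comp[1, ] <- 1; comp[nrow(comp), ] <- 1
  comp[, 1] <- 1; comp[, ncol(comp)] <- 1
  outside <- .regionGrowCpp(comp, matrix(1L, 1, 2), 0.5)
  holes <- (comp == 1) & (outside == 0)
  filled <- v
  filled[holes[2:(nrow(v) + 1L), 2:(ncol(v) + 1L)]] <- 1
  BinaryMask(filled, mask@spacing)
}
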