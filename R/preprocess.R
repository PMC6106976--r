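#' Edge-preserving noise reduction (Perona-Malik anisotropic diffusion)
#'
#' Explicit 4-neighbor Perona-Malik scheme with exponential conductance
#' \code{g(s) = exp(-(s/conductance)^2)}: diffusion is strong in flat regions
#' and shuts down across large intensity differences, so noise is smoothed
#' while organ boundaries survive. Zero iterations return the input
#' unchanged. The output is clipped to the input's intensity range (the
#' explicit scheme cannot legitimately create new extrema).
#'
#' @param image an \linkS4class{Image2D}.
#' @param iterations number of explicit time steps (>= 0).
#' @param conductance edge threshold on the [0,1] intensity scale.
#' @param time_step explicit step size; must lie in (0, 0.25] for stability
#'   of the 4-neighbor scheme.
#' @return The smoothed \linkS4class{Image2D}.
#' @export
anisotropicDiffusion <- function(image, iterations = 10, conductance = 0.1,
                                 time_step = 0.125) {
  stopifnot(is(image, "Image2D"))
  if (iterations < 0) stop("iterations must be >= 0")
  if (time_step <= 0 || time_step > 0.25)
    stop("time_step must lie in (0, 0.25] for stability")
  m <- image@pixels
  rng <- range(m)
  for (it in seq_len(iterations)) {
    dN <- .shiftRep(m, -1L, 0L) - m
    dS <- .shiftRep(m,  1L, 0L) - m
    dW <- .shiftRep(m, 0L, -1L) - m
    dE <- .shiftRep(m, 0L,  1L) - m
    g <- function(d) exp(-(d / conductance)^2)
    m <- m + time_step * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  m <- pmin(pmax(m, rng[1]), rng[2])
  Image2D(m, image@spacing)
}

#' Scale-specific gradient magnitude
#'
#' Smooths with a Gaussian of standard deviation \code{gamma} pixels and
#' returns the magnitude of the central-difference gradient. Intensities are
#' multiplied by \code{gain} (default 255, the 8-bit gray convention on which
#' the downstream sigmoid constants beta = 4 and kappa = -1.5 were
#' calibrated) before differentiation; pass \code{gain = 1} to work on the
#' native [0,1] scale.
#'
#' @param image an \linkS4class{Image2D}.
#' @param gamma Gaussian standard deviation in pixels (> 0); default 0.5.
#' @param gain intensity gain applied before differentiation.
#' @return An \linkS4class{Image2D} of nonnegative gradient magnitudes.
#' @export
gradientMagnitude <- function(image, gamma = 0.5, gain = 255) {
  stopifnot(is(image, "Image2D"))
  if (gamma <= 0) stop("gamma must be > 0")
  sm <- .gaussSmooth(image@pixels * gain, gamma)
  Image2D(.gradMagnitude(sm), image@spacing)
}

#' Sigmoid contrast enhancement of a gradient-magnitude image
#'
#' Pointwise \code{f_s = 1 / (1 + exp(-(f_M - beta) / kappa))}. With the
#' default kappa = -1.5 the map is monotonically decreasing in the gradient
#' magnitude: homogeneous regions (low gradient) become bright, edges become
#' dark. beta centers the transition on the gradient scale.
#'
#' @param fm gradient-magnitude \linkS4class{Image2D}
#'   (see \code{\link{gradientMagnitude}}).
#' @param kappa sigmoid width; nonzero. Negative values invert the contrast.
#' @param beta sigmoid center on the gradient scale.
#' @return An \linkS4class{Image2D} with values in (0,1).
#' @export
sigmoidEnhance <- function(fm, kappa = -1.5, beta = 4) {
  stopifnot(is(fm, "Image2D"))
  if (kappa == 0) stop("kappa must be nonzero")
  Image2D(1 / (1 + exp(-(fm@pixels - beta) / kappa)), fm@spacing)
}

#' Range-relative binarization
#'
#' Thresholds at \code{(max(f_s) + min(f_s)) / theta} (inclusive >=). theta
#' must exceed 1; the trained operating range is 1.1 to 1.5. Larger theta
#' lowers the threshold, so masks are nested increasing in theta.
#'
#' @param fs an \linkS4class{Image2D} (typically sigmoid-enhanced).
#' @param theta threshold divisor (> 1).
#' @return A \linkS4class{BinaryMask}.
#' @export
binarizeImage <- function(fs, theta = 1.25) {
  stopifnot(is(fs, "Image2D"))
  if (theta <= 1) stop("theta must be > 1")
  thr <- (max(fs@pixels) + min(fs@pixels)) / theta
  BinaryMask((fs@pixels >= thr) * 1, fs@spacing)
}

#' Hybrid preprocessing chain: CT slice to binary image
#'
#' Composes the four preprocessing steps -- anisotropic diffusion, scale-
#' specific gradient magnitude, sigmoid enhancement, range-relative
#' binarization -- so that homogeneous tissue interiors come out white and
#' boundary bands black. Region growing on the result reduces to a flood
#' fill that cannot leak across organ boundaries.
#'
#' @param image an \linkS4class{Image2D}, intensities in [0,1].
#' @param config a \linkS4class{RunConfig}; the preprocessing slots are used.
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' ph <- makeLiverPhantom(liverPhantomSpec(noise_sigma = 0))
#' bw <- preprocessPipeline(ph$image, runConfig())
#' @export
preprocessPipeline <- function(image, config = runConfig()) {
  stopifnot(is(image, "Image2D"), is(config, "RunConfig"))
  fi <- anisotropicDiffusion(image, config@diffIterations,
                             config@conductance, config@diffTimeStep)
  fm <- gradientMagnitude(fi, config@gamma, config@gain)
  fs <- sigmoidEnhance(fm, config@kappa, config@beta)
  binarizeImage(fs, config@theta)
}
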