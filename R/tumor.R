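#' Crop / paste a rectangular ROI
#'
#' \code{cropRoi} extracts the half-open rectangle (0-based indices, rows
#' \code{[row0,row1)} x cols \code{[col0,col1)}) from an image;
#' \code{pasteRoi} embeds an ROI-sized mask back into a full-size zero mask.
#'
#' @param image an \linkS4class{Image2D}.
#' @param rect a \linkS4class{RoiRect}.
#' @return \code{cropRoi}: an \linkS4class{Image2D};
#'   \code{pasteRoi}: a \linkS4class{BinaryMask}.
#' @export
cropRoi <- function(image, rect) {
  stopifnot(is(image, "Image2D"), is(rect, "RoiRect"))
  d <- dim(image)
  if (rect@row1 > d[1] || rect@col1 > d[2])
    stop("ROI rectangle exceeds image bounds")
  Image2D(image@pixels[(rect@row0 + 1L):rect@row1,
                       (rect@col0 + 1L):rect@col1, drop = FALSE],
          image@spacing)
}

#' @rdname cropRoi
#' @param full_shape integer(2): size of the full image.
#' @param mask ROI-sized \linkS4class{BinaryMask}.
#' @export
pasteRoi <- function(full_shape, rect, mask) {
  stopifnot(is(rect, "RoiRect"), is(mask, "BinaryMask"))
  if (rect@row1 > full_shape[1] || rect@col1 > full_shape[2])
    stop("ROI rectangle exceeds image bounds")
  mv <- mask@values
  if (nrow(mv) != rect@row1 - rect@row0 || ncol(mv) != rect@col1 - rect@col0)
    stop("mask shape does not match the rectangle")
  out <- matrix(0, full_shape[1], full_shape[2])
  out[(rect@row0 + 1L):rect@row1, (rect@col0 + 1L):rect@col1] <- mv
  BinaryMask(out, mask@spacing)
}

#' Truncated Gaussian neighborhood kernel
#'
#' \code{K(u) = (1/a) exp(-|u|^2 / (2 tau^2))} for \code{|u| <= rho}, zero
#' outside, on a square \code{(2 rho + 1)^2} support. This is the weight of
#' the circular neighborhood in the local intensity clustering energy.
#' Defaults a = 1, tau = 4, rho = 3.
#'
#' @param rho neighborhood radius in px (>= 1).
#' @param tau Gaussian standard deviation (> 0).
#' @param a normalization constant (the center value is 1/a).
#' @return numeric matrix of size \code{(2 rho + 1)^2}.
#' @export
truncatedGaussianKernel <- function(rho = 3, tau = 4, a = 1) {
  if (rho < 1) stop("rho must be >= 1")
  if (tau <= 0) stop("tau must be > 0")
  x <- (-rho):rho
  d2 <- outer(x^2, x^2, `+`)
  k <- exp(-d2 / (2 * tau^2)) / a
  k[sqrt(d2) > rho] <- 0
  k
}

.membership <- function(phi, epsilon) {
  H <- .heavisideEps(phi, epsilon)
  list(H, 1 - H)
}

#' Closed-form updates of the local intensity clustering model
#'
#' The clustering energy treats the image as \code{I = b * J + n} with J
#' piecewise constant (values \code{c1}, \code{c2} on the two phases of
#' phi) and b a smooth bias field. Holding the other variables fixed, the
#' energy is quadratic in each of \code{c} and \code{b}, giving closed-form
#' minimizers:
#' \code{c_i = sum((b*K) I u_i) / sum((b^2*K) u_i)} and
#' \code{b = (K * (I J1)) / (K * J2)} with \code{J1 = sum_i c_i u_i},
#' \code{J2 = sum_i c_i^2 u_i}, where \code{*} is convolution with the
#' truncated Gaussian kernel and \code{u_1 = H_eps(phi)},
#' \code{u_2 = 1 - H_eps(phi)}.
#'
#' @param image ROI \linkS4class{Image2D}.
#' @param b current bias field (matrix or \linkS4class{Image2D}).
#' @param phi current level set (matrix or \linkS4class{LevelSetField}).
#' @param K kernel from \code{\link{truncatedGaussianKernel}}.
#' @param epsilon Heaviside width.
#' @return \code{licUpdateC}: list \code{(c1, c2)};
#'   \code{licUpdateBias}: the new bias field matrix (positive; denominator
#'   floored at 1e-10).
#' @export
licUpdateC <- function(image, b, phi, K, epsilon = 1.5) {
  stopifnot(is(image, "Image2D"))
  bv <- .asPixels(b, "bias field"); pv <- .asPixels(phi, "level set field")
  I <- image@pixels
  u <- .membership(pv, epsilon)
  bK <- .conv2Zero(bv, K)
  b2K <- .conv2Zero(bv^2, K)
  cs <- numeric(2)
  for (i in 1:2) {
    den <- sum(b2K * u[[i]])
    if (den <= .Machine$double.eps)
      stop("degenerate partition: phase ", i, " is empty")
    cs[i] <- sum(bK * I * u[[i]]) / den
  }
  list(c1 = cs[1], c2 = cs[2])
}

#' @rdname licUpdateC
#' @param cs list with \code{c1}, \code{c2} (phase constants).
#' @export
licUpdateBias <- function(image, cs, phi, K, epsilon = 1.5) {
  stopifnot(is(image, "Image2D"))
  pv <- .asPixels(phi, "level set field")
  I <- image@pixels
  if (cs$c1 == 0 && cs$c2 == 0) stop("phase constants must not both be zero")
  u <- .membership(pv, epsilon)
  J1 <- cs$c1 * u[[1]] + cs$c2 * u[[2]]
  J2 <- cs$c1^2 * u[[1]] + cs$c2^2 * u[[2]]
  num <- .conv2Zero(I * J1, K)
  den <- pmax(.conv2Zero(J2, K), 1e-10)
  num / den
}

#' Local intensity clustering energy (direct summation)
#'
#' Evaluates the clustering data energy
#' \code{sum_x sum_i u_i(x) [I(x)^2 (1*K) - 2 c_i I(x) (b*K) + c_i^2 (b^2*K)]}
#' and, when \code{full = TRUE}, adds the contour length term
#' \code{nu * sum |grad H_eps(phi)|} and the distance regularization
#' \code{delta_reg * sum (|grad phi| - 1)^2 / 2}.
#'
#' @param image ROI \linkS4class{Image2D}.
#' @param b bias field.
#' @param cs list with \code{c1}, \code{c2}.
#' @param phi level set field.
#' @param K neighborhood kernel.
#' @param epsilon Heaviside width.
#' @param full include the regularization terms.
#' @param nu,delta_reg regularization weights (used when \code{full}).
#' @return a single number.
#' @export
licEnergy <- function(image, b, cs, phi, K, epsilon = 1.5, full = FALSE,
                      nu = 1, delta_reg = 1) {
  stopifnot(is(image, "Image2D"))
  bv <- .asPixels(b, "bias field"); pv <- .asPixels(phi, "level set field")
  I <- image@pixels
  u <- .membership(pv, epsilon)
  oneK <- .conv2Zero(matrix(1, nrow(I), ncol(I)), K)
  bK <- .conv2Zero(bv, K)
  b2K <- .conv2Zero(bv^2, K)
  e <- 0
  for (i in 1:2) {
    ci <- if (i == 1) cs$c1 else cs$c2
    e <- e + sum(u[[i]] * (I^2 * oneK - 2 * ci * I * bK + ci^2 * b2K))
  }
  if (full) {
    H <- .heavisideEps(pv, epsilon)
    e <- e + nu * sum(.gradMagnitude(H)) +
      delta_reg * sum((.gradMagnitude(pv) - 1)^2 / 2)
  }
  e
}

#' Two-phase segmentation by local intensity clustering with bias field
#'
#' Alternates the closed-form updates of the phase constants and the bias
#' field with one explicit step of the level set flow
#' \deqn{\partial\phi/\partial t = -\delta_\epsilon(\phi)(e_1 - e_2)
#'   + \nu\, \delta_\epsilon(\phi)\, \mathrm{div}(\nabla\phi/|\nabla\phi|)
#'   + \delta_{reg} (\nabla^2\phi - \mathrm{div}(\nabla\phi/|\nabla\phi|))}
#' with \code{e_i = I^2 (1*K) - 2 c_i I (b*K) + c_i^2 (b^2*K)}. The contour
#' is initialized randomly -- a seeded per-pixel Rademacher field (+1/-1) --
#' since the model is robust to initialization.
#'
#' The phase reported as tumor is the one whose mean intensity differs most
#' from the mean of the ROI's 2-px border band (the border is assumed to be
#' liver parenchyma; this handles hypodense and hyperdense lesions alike).
#'
#' @param roi_image ROI \linkS4class{Image2D} (area >= 9 px).
#' @param config a \linkS4class{RunConfig}; uses the LIC slots and the seed.
#' @return list with \code{mask} (tumor-phase \linkS4class{BinaryMask}),
#'   \code{bias} (estimated field, \linkS4class{Image2D}), \code{c}
#'   (phase constants, tumor first element FALSE/TRUE order as fitted) and
#'   \code{phi} (final \linkS4class{LevelSetField}).
#' @examples
#' tp <- makeTumorPhantom(tumorPhantomSpec())
#' fit <- evolveLic(tp$image, runConfig(licIterations = 30))
#' @export
evolveLic <- function(roi_image, config = runConfig()) {
  stopifnot(is(roi_image, "Image2D"), is(config, "RunConfig"))
  d <- dim(roi_image)
  if (prod(d) < 9) stop("ROI area must be at least 9 px")
  I <- roi_image@pixels
  K <- truncatedGaussianKernel(config@rho, config@tau, config@a)
  eps <- config@epsilon
  phi <- .withSeed(config@seed,
                   matrix(sample(c(-1, 1), prod(d), replace = TRUE), d[1], d[2]))
  # the bias field starts from a coarse low-pass estimate of the image (unit
  # mean scale), standard practice in bias correction: the very first
  # classification threshold is then already bias-modulated instead of
  # global, which keeps a strong smooth bias from masquerading as the
  # two-phase structure
  b <- .gaussSmooth(I, min(d) / 3)
  b <- b / mean(b)
  cs <- list(c1 = max(I), c2 = min(I))
  oneK <- .conv2Zero(matrix(1, d[1], d[2]), K)
  ones <- matrix(1, d[1], d[2])
  # the random contour is symmetric between the phases, so the phase
  # constants start deliberately asymmetric (max/min) and are held through a
  # burn-in (half the iteration budget) while the phi steps classify against
  # the bias-modulated threshold; releasing c/b earlier lets the two
  # constants collapse onto the global mean before structure has emerged
  burnin <- max(1L, as.integer(config@licIterations) %/% 2L)
  for (it in seq_len(config@licIterations)) {
    bK <- .conv2Zero(b, K)
    b2K <- .conv2Zero(b^2, K)
    e1 <- I^2 * oneK - 2 * cs$c1 * I * bK + cs$c1^2 * b2K
    e2 <- I^2 * oneK - 2 * cs$c2 * I * bK + cs$c2^2 * b2K
    dirac <- .diracEps(phi, eps)
    curv <- .curvatureTerm(phi, ones)
    phi <- phi + config@licDt * (-dirac * (e1 - e2) +
                                 config@nu * dirac * curv +
                                 config@deltaReg * (.laplacian(phi) - curv))
    if (it > burnin) {
      cs <- licUpdateC(roi_image, b, phi, K, eps)
      b <- licUpdateBias(roi_image, cs, phi, K, eps)
    }
  }
  phase1 <- phi > 0
  if (all(phase1) || !any(phase1))
    stop("degenerate result: the contour collapsed to one phase")
  border <- matrix(FALSE, d[1], d[2])
  border[c(1:2, d[1] - 1, d[1]), ] <- TRUE
  border[, c(1:2, d[2] - 1, d[2])] <- TRUE
  borderMean <- mean(I[border])
  m1 <- mean(I[phase1]); m0 <- mean(I[!phase1])
  tumorPhase <- if (abs(m1 - borderMean) >= abs(m0 - borderMean)) phase1 else !phase1
  list(mask = BinaryMask(tumorPhase * 1, roi_image@spacing),
       bias = Image2D(b, roi_image@spacing),
       c = cs,
       phi = LevelSetField(phi, roi_image@spacing))
}

#' Initialize an HMRF state from a binary mask
#'
#' The mask provides the initial labels; the initial Gaussian parameters of
#' each class are the sample mean and variance of the intensities under
#' each label (variance floored at 1e-6).
#'
#' @param roi_image ROI \linkS4class{Image2D}.
#' @param mask initial \linkS4class{BinaryMask}; both classes nonempty.
#' @param potts_beta pairwise clique weight of the Potts prior.
#' @return An \linkS4class{HMRFState}.
#' @export
hmrfInit <- function(roi_image, mask, potts_beta = 0.5) {
  stopifnot(is(roi_image, "Image2D"), is(mask, "BinaryMask"))
  I <- roi_image@pixels
  lab <- mask@values
  if (!any(lab == 0) || !any(lab == 1))
    stop("both label classes must be nonempty in the initial mask")
  mu <- c(mean(I[lab == 0]), mean(I[lab == 1]))
  s2 <- pmax(c(var(I[lab == 0]), var(I[lab == 1])), 1e-6)
  s2[is.na(s2)] <- 1e-6  # single-pixel class
  new("HMRFState", labels = lab, mu = mu, sigma2 = s2,
      pottsBeta = potts_beta)
}

#' MAP label estimation by iterated conditional modes
#'
#' Sequential raster-order sweeps (column-major, R's native order): each
#' pixel takes the label minimizing
#' \code{(x - mu_l)^2 / (2 sigma_l^2) + ln sigma_l +
#' potts_beta * #\{8-neighbors with a different label\}}, using the labels
#' current at visit time. Stops after \code{n_sweeps} sweeps or as soon as
#' a sweep changes no label. With \code{potts_beta = 0} this is per-pixel
#' maximum likelihood classification.
#'
#' @param state an \linkS4class{HMRFState}.
#' @param roi_image ROI \linkS4class{Image2D}.
#' @param n_sweeps maximum number of sweeps.
#' @return label matrix (0/1).
#' @export
hmrfMapIcm <- function(state, roi_image, n_sweeps = 15) {
  stopifnot(is(state, "HMRFState"), is(roi_image, "Image2D"))
  .icmSweepsCpp(roi_image@pixels, state@labels, state@mu, state@sigma2,
                state@pottsBeta, as.integer(n_sweeps))
}

.neighborCounts <- function(lab) {
  # per pixel: number of 8-neighbors carrying label 1, and total neighbors
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  n1 <- matrix(0, nrow(lab), ncol(lab))
  ntot <- matrix(0, nrow(lab), ncol(lab))
  ones <- matrix(1, nrow(lab), ncol(lab))
  for (s in shifts) {
    n1 <- n1 + .shiftZero(lab, s[1], s[2])
    ntot <- ntot + .shiftZero(ones, s[1], s[2])
  }
  list(n1 = n1, ntot = ntot)
}

#' HMRF-EM refinement of a binary classification
#'
#' Alternates MAP label estimation (ICM, \code{map_iters} sweeps) with an
#' EM update of the class Gaussians: the per-pixel posterior is
#' \code{P(l | x) \%prop\% N(x; mu_l, sigma_l^2) *
#' exp(-potts_beta * #\{disagreeing 8-neighbors\})}, and the class means
#' and variances are refreshed as posterior-weighted sample moments. The
#' initial labels and parameters come from \code{\link{hmrfInit}} applied
#' to \code{init_mask}.
#'
#' @param roi_image ROI \linkS4class{Image2D}.
#' @param init_mask initial \linkS4class{BinaryMask} (both classes
#'   nonempty).
#' @param em_iters,map_iters iteration counts (trained defaults 15 and 15).
#' @param potts_beta Potts clique weight.
#' @return Final label field as a \linkS4class{BinaryMask}.
#' @examples
#' tp <- makeTumorPhantom(tumorPhantomSpec(contrast = 0.2, bias =
#'   list(type = "linear", amplitude = 0)))
#' out <- hmrfEm(tp$image, tp$truth, em_iters = 3, map_iters = 3)
#' @export
hmrfEm <- function(roi_image, init_mask, em_iters = 15, map_iters = 15,
                   potts_beta = 0.5) {
  stopifnot(is(roi_image, "Image2D"), is(init_mask, "BinaryMask"))
  state <- hmrfInit(roi_image, init_mask, potts_beta)
  I <- roi_image@pixels
  for (t in seq_len(em_iters)) {
    lab <- hmrfMapIcm(state, roi_image, map_iters)
    nb <- .neighborCounts(lab)
    post <- vector("list", 2)
    for (l in 0:1) {
      nSame <- if (l == 1) nb$n1 else nb$ntot - nb$n1
      lik <- exp(-(I - state@mu[l + 1])^2 / (2 * state@sigma2[l + 1])) /
        sqrt(2 * pi * state@sigma2[l + 1])
      prior <- exp(-potts_beta * (nb$ntot - nSame))
      post[[l + 1]] <- lik * prior
    }
    Z <- post[[1]] + post[[2]]
    Z[Z < .Machine$double.xmin] <- .Machine$double.xmin
    post[[1]] <- post[[1]] / Z
    post[[2]] <- post[[2]] / Z
    mu <- state@mu; s2 <- state@sigma2
    for (l in 1:2) {
      w <- sum(post[[l]])
      if (w < 1e-8) stop("degenerate result: class ", l - 1, " collapsed")
      mu[l] <- sum(post[[l]] * I) / w
      s2[l] <- max(sum(post[[l]] * (I - mu[l])^2) / w, 1e-6)
    }
    state <- new("HMRFState", labels = lab, mu = mu, sigma2 = s2,
                 pottsBeta = potts_beta)
  }
  BinaryMask(state@labels, roi_image@spacing)
}

#' Enhanced edge indicator
#'
#' Combines the vague but never-vanishing geodesic indicator of the raw ROI
#' with the crisp class boundary of a binary classification: the geodesic-form
#' indicator of the classification image is affinely rescaled so the class
#' boundary band is exactly 0 and the class interiors exactly 1, and the
#' enhanced indicator is the pointwise maximum with the original. The
#' result is 1 inside the classes (fast propagation) and equals the small
#' but positive original indicator on the boundary band, so evolution slows
#' there without stopping dead. A constant classification contributes a
#' zero field, leaving the original indicator unchanged.
#'
#' @param roi_image ROI \linkS4class{Image2D}.
#' @param classification \linkS4class{BinaryMask} (e.g. HMRF labels).
#' @param sigma Gaussian std of the indicator (px).
#' @param gain intensity gain of the indicator (see
#'   \code{\link{edgeIndicator}}).
#' @return An \linkS4class{Image2D} in [0, 1].
#' @export
enhancedEdgeIndicator <- function(roi_image, classification, sigma = 0.5,
                                  gain = 255) {
  stopifnot(is(roi_image, "Image2D"), is(classification, "BinaryMask"))
  if (!all(dim(roi_image) == dim(classification))) stop("shapes differ")
  g <- edgeIndicator(roi_image, sigma, gain)@pixels
  gb <- edgeIndicator(Image2D(classification@values,
                              classification@spacing), sigma, gain)@pixels
  rng <- range(gb)
  gb <- if (rng[2] > rng[1]) (gb - rng[1]) / (rng[2] - rng[1]) else gb * 0
  Image2D(pmax(gb, g), roi_image@spacing)
}

#' Segment a liver tumor inside an ROI
#'
#' The full tumor branch: crop the ROI, run the local-intensity-clustering
#' level set (bias-field robust) for an initial two-phase split, refine the
#' labels with HMRF-EM (noise/low-contrast robust), build the enhanced edge
#' indicator from the refined classification, then evolve the unified level
#' set from a user rectangle placed inside the tumor, with balloon
#' magnitude \code{vartheta} for a fixed number of iterations (no manual
#' termination is needed in this branch). The zero-level mask is pasted
#' back into full-image coordinates.
#'
#' @param image full \linkS4class{Image2D}.
#' @param roi \linkS4class{RoiRect} enclosing the tumor tightly.
#' @param init_rect \linkS4class{RoiRect} strictly inside \code{roi},
#'   placed inside the tumor (full-image coordinates).
#' @param config a \linkS4class{RunConfig}.
#' @param variant level set variant for the final evolution; the default
#'   \code{"unified"} uses both the enhanced indicator and the signed
#'   pressure force, \code{"edge"}/\code{"region"} are the
#'   single-information ablations.
#' @return Full-size \linkS4class{BinaryMask}.
#' @export
segmentTumor <- function(image, roi, init_rect, config = runConfig(),
                         variant = c("unified", "edge", "region")) {
  stopifnot(is(image, "Image2D"), is(roi, "RoiRect"), is(init_rect, "RoiRect"))
  variant <- match.arg(variant)
  if (init_rect@row0 <= roi@row0 || init_rect@row1 >= roi@row1 ||
      init_rect@col0 <= roi@col0 || init_rect@col1 >= roi@col1)
    stop("init_rect must lie strictly inside the ROI")
  roiImg <- cropRoi(image, roi)
  lic <- evolveLic(roiImg, config)
  # the HMRF likelihood assumes one global Gaussian per class, which a
  # strong bias field breaks; divide out the clustering stage's bias
  # estimate for the relabeling step only (the indicator and the final
  # evolution stay on the observed ROI)
  corrected <- Image2D(roiImg@pixels / pmax(lic$bias@pixels, 0.2),
                       roiImg@spacing)
  labels <- hmrfEm(corrected, lic$mask, config@emIters, config@mapIters,
                   config@pottsBeta)
  gEnh <- enhancedEdgeIndicator(roiImg, labels, config@sigma, config@gain)
  d <- dim(roiImg)
  init <- matrix(0, d[1], d[2])
  init[(init_rect@row0 - roi@row0 + 1L):(init_rect@row1 - roi@row0),
       (init_rect@col0 - roi@col0 + 1L):(init_rect@col1 - roi@col0)] <- 1
  phi0 <- initLevelSet(BinaryMask(init, image@spacing), config@omega)
  phi <- evolveLevelSet(phi0, roiImg, gEnh, variant = variant,
                        alpha = config@vartheta, lambda = config@lambda,
                        mu = config@mu, iterations = config@tumorIterations,
                        dt = config@dt, epsilon = config@epsilon)
  pasteRoi(dim(image), roi, zeroLevelMask(phi))
}
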