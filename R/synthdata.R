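# phantom generators: study-condition fixtures with exact ground truth

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.diskMask <- function(nr, nc, center, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Specification of a liver phantom
#'
#' Describes a piecewise-near-constant liver phantom exhibiting the
#' difficulties the segmentation pipeline targets: one or more discrete
#' liver components, dark internal vessels/tumors, adjacent organs whose
#' boundary with the liver is partially or wholly free of edge information,
#' and additive Gaussian noise.
#'
#' Each liver component is a disk \code{list(center = c(row, col), radius)}.
#' Each vessel/tumor is \code{list(center, radius, intensity)} and must lie
#' inside a component. Each adjacent organ is
#' \code{list(intensity, radius, angle, sep, edge_gap_fraction)}: the organ
#' disk is placed at \code{angle} degrees from the first component's center,
#' separated from the liver boundary by \code{sep} px of background
#' (\code{sep <= 0} places it in direct sharp-edge contact). A positive
#' \code{edge_gap_fraction} opens a channel -- of width that fraction of the
#' liver perimeter -- across the septum in which the intensity ramps
#' linearly from liver to organ over \code{ramp_len} px, so that boundary
#' segment carries region contrast but no localized edge.
#'
#' @param shape image size \code{c(rows, cols)}.
#' @param liver_intensity,background_intensity intensities in [0,1].
#' @param components list of liver component disks.
#' @param vessels list of internal vessel/tumor disks (hypodense by
#'   default in the presets; intensity is explicit here).
#' @param adjacent_organs list of adjacent organ descriptions (see above).
#' @param ramp_len length in px of the edge-free intensity ramp.
#' @param noise_sigma additive zero-mean Gaussian noise std.
#' @param seed RNG seed for the noise.
#' @return A validated spec (list) for \code{\link{makeLiverPhantom}}.
#' @export
liverPhantomSpec <- function(shape = c(160, 160),
                             liver_intensity = 0.60,
                             background_intensity = 0.15,
                             components = list(list(center = c(80, 62), radius = 42)),
                             vessels = list(),
                             adjacent_organs = list(),
                             ramp_len = 16,
                             noise_sigma = 0.02,
                             seed = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 16))
  for (v in c(liver_intensity, background_intensity))
    if (v < 0 || v > 1) stop("intensities must lie in [0,1]")
  if (length(components) < 1L) stop("at least one liver component is required")
  for (comp in components) {
    if (comp$radius < 2) stop("component radii must be >= 2 px")
  }
  if (length(components) > 1L) {
    for (i in seq_len(length(components) - 1L)) {
      for (j in (i + 1L):length(components)) {
        d <- sqrt(sum((components[[i]]$center - components[[j]]$center)^2))
        if (d <= components[[i]]$radius + components[[j]]$radius)
          stop("liver components must not overlap")
      }
    }
  }
  for (v in vessels) {
    if (v$radius < 2) stop("vessel radii must be >= 2 px")
    if (v$intensity < 0 || v$intensity > 1) stop("vessel intensity in [0,1]")
  }
  structure(list(shape = shape, liver_intensity = liver_intensity,
                 background_intensity = background_intensity,
                 components = components, vessels = vessels,
                 adjacent_organs = adjacent_organs, ramp_len = ramp_len,
                 noise_sigma = noise_sigma, seed = seed),
            class = "liverPhantomSpec")
}

#' Generate a liver phantom with ground truth
#'
#' Renders the spec as a piecewise-constant image plus iid Gaussian noise.
#' The ground truth is the union of the liver component disks -- the liver
#' envelope: internal vessels/tumors are *not* excluded, since the
#' refinement stage is expected to recover the envelope and fill such holes.
#'
#' @param spec a \code{\link{liverPhantomSpec}}.
#' @return list with \code{image} (\linkS4class{Image2D}),
#'   \code{truth} (\linkS4class{BinaryMask}) and \code{spec}.
#' @examples
#' ph <- makeLiverPhantom(liverPhantomSpec(noise_sigma = 0))
#' maskArea(ph$truth)
#' @export
makeLiverPhantom <- function(spec = liverPhantomSpec()) {
  stopifnot(inherits(spec, "liverPhantomSpec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  img <- matrix(spec$background_intensity, nr, nc)
  truth <- matrix(0, nr, nc)
  liv0 <- spec$components[[1]]

  for (org in spec$adjacent_organs) {
    ang <- org$angle * pi / 180
    u <- c(cos(ang), sin(ang))  # (row, col) direction
    d0 <- liv0$radius + org$sep + org$radius
    ocen <- liv0$center + d0 * u
    img[.diskMask(nr, nc, ocen, org$radius)] <- org$intensity
  }

  for (comp in spec$components) {
    m <- .diskMask(nr, nc, comp$center, comp$radius)
    img[m] <- spec$liver_intensity
    truth[m] <- 1
  }

  # edge-free ramp channels: intensity slides from liver to organ with no
  # localized gradient, leaving only region contrast along that arc
  for (org in spec$adjacent_organs) {
    gapw <- org$edge_gap_fraction * 2 * pi * liv0$radius
    if (gapw <= 0) next
    ang <- org$angle * pi / 180
    u <- c(cos(ang), sin(ang))
    rr <- matrix(seq_len(nr), nr, nc) - liv0$center[1]
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - liv0$center[2]
    s <- rr * u[1] + cc * u[2] - liv0$radius   # along-axis, 0 at liver edge
    t <- abs(-rr * u[2] + cc * u[1])           # off-axis distance
    L <- spec$ramp_len
    chan <- t <= gapw / 2 & s >= 0 & s <= L & truth == 0
    frac <- pmin(pmax(s / L, 0), 1)
    ramp <- spec$liver_intensity +
      (org$intensity - spec$liver_intensity) * frac
    img[chan] <- ramp[chan]
  }

  for (v in spec$vessels) {
    img[.diskMask(nr, nc, v$center, v$radius)] <- v$intensity
  }

  if (spec$noise_sigma > 0) {
    img <- .withSeed(spec$seed,
                     img + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
  }
  list(image = Image2D(img), truth = BinaryMask(truth), spec = spec)
}

#' Preset: comparison phantom with a partially edge-free liver boundary
#'
#' The phantom used to compare the unified, edge-only and region-only level
#' set variants. Two boundary defects separate them by their failure modes:
#' a hypodense adjacent organ reached through a 4-px-wide edge-free
#' intensity ramp (no localized gradient -- only the signed pressure force
#' can stop a contour there), and a hyperdense organ in direct sharp-edge
#' contact (a strong edge, but region information alone would happily cross
#' it).
#'
#' @param noise_sigma additive noise std.
#' @param seed RNG seed.
#' @return A \code{\link{liverPhantomSpec}}.
#' @export
comparisonPhantomSpec <- function(noise_sigma = 0.02, seed = 1) {
  liverPhantomSpec(
    shape = c(160, 160),
    background_intensity = 0.25,
    components = list(list(center = c(80, 62), radius = 42)),
    adjacent_organs = list(
      list(intensity = 0.30, radius = 22, angle = 35, sep = 6,
           edge_gap_fraction = 28 / (2 * pi * 42)),
      list(intensity = 0.82, radius = 28, angle = -60, sep = -2,
           edge_gap_fraction = 0)),
    ramp_len = 20,
    noise_sigma = noise_sigma, seed = seed)
}

#' Specification of a tumor ROI phantom
#'
#' A two-phase ROI -- liver parenchyma with one hypodense (default) or
#' hyperdense lesion -- under a smooth multiplicative bias field and
#' additive Gaussian noise, following the image model
#' \code{I = b * J + n}. The exact lesion mask and the true bias field are
#' returned for recovery tests.
#'
#' @param shape ROI size \code{c(rows, cols)}.
#' @param liver_intensity parenchyma intensity of the true image J.
#' @param tumor lesion description: \code{list(center, radius)} or
#'   \code{list(mask = <0/1 matrix>)}.
#' @param contrast lesion contrast delta in (0, 0.3]; the lesion intensity
#'   is \code{liver_intensity - sign * delta}.
#' @param edge_softness width (px) of the linear radial falloff across the
#'   lesion margin; 0 renders a sharp step. A length-2 vector
#'   \code{c(lo, hi)} renders a *variable* margin whose width oscillates
#'   around the lesion (three lobes), emulating the ambiguous, variable
#'   edges of real lesions. Ground truth is always the half-contrast
#'   radius. Default 4 px (uniform).
#' @param hypodense logical; TRUE (default) renders the lesion darker.
#' @param faded_sector optional \code{list(angle_deg, width_deg, frac)}:
#'   within an angular sector of the lesion margin the local contrast is
#'   scaled down to \code{frac} of its nominal value (with a smooth angular
#'   transition), emulating a boundary segment that all but disappears into
#'   the parenchyma. Ground truth is unchanged.
#' @param bias \code{list(type = "linear"|"quadratic", amplitude)}; the
#'   field spans \code{1 +/- amplitude/2} across the ROI and is slowly
#'   varying. \code{amplitude = 0} disables it (b identically 1).
#' @param noise_sigma additive zero-mean Gaussian noise std.
#' @param seed RNG seed.
#' @return A validated spec (list) for \code{\link{makeTumorPhantom}}.
#' @export
tumorPhantomSpec <- function(shape = c(64, 64),
                             liver_intensity = 0.55,
                             tumor = list(center = c(32, 32), radius = 14),
                             contrast = 0.10,
                             edge_softness = 4,
                             hypodense = TRUE,
                             faded_sector = NULL,
                             bias = list(type = "linear", amplitude = 0.3),
                             noise_sigma = 0.02,
                             seed = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 8))
  if (contrast <= 0 || contrast > 0.3)
    stop("contrast must lie in (0, 0.3]")
  if (any(edge_softness < 0) || !length(edge_softness) %in% 1:2)
    stop("edge_softness must be one or two nonnegative widths")
  if (bias$amplitude < 0 || bias$amplitude >= 2)
    stop("bias amplitude must keep the field strictly positive")
  structure(list(shape = shape, liver_intensity = liver_intensity,
                 tumor = tumor, contrast = contrast,
                 edge_softness = edge_softness, hypodense = hypodense,
                 faded_sector = faded_sector,
                 bias = bias, noise_sigma = noise_sigma, seed = seed),
            class = "tumorPhantomSpec")
}

#' Canonical tumor phantom study conditions
#'
#' Three preset difficulty classes used throughout the package's evaluation:
#' \describe{
#'   \item{clean}{high contrast (0.25), sharp margin, no bias,
#'     noise 0.02 -- an easily segmented lesion with a distinct boundary.}
#'   \item{lowcontrast}{contrast 0.10 under a 0.3-amplitude linear bias
#'     field, noise 0.02 -- the low-contrast inhomogeneous case.}
#'   \item{ambiguous}{contrast 0.12 with a variable margin (2-10 px) and a
#'     60-degree sector where the local contrast fades to 30\%, under a
#'     0.3-amplitude bias, noise 0.03 -- the ambiguous, variable-edge case.}
#' }
#'
#' @param type one of \code{"clean"}, \code{"lowcontrast"},
#'   \code{"ambiguous"}.
#' @param seed RNG seed for the noise.
#' @return A \code{\link{tumorPhantomSpec}}.
#' @export
tumorPhantomPreset <- function(type = c("clean", "lowcontrast", "ambiguous"),
                               seed = 1) {
  type <- match.arg(type)
  switch(type,
    clean = tumorPhantomSpec(contrast = 0.25, edge_softness = 0,
                             bias = list(type = "linear", amplitude = 0),
                             noise_sigma = 0.02, seed = seed),
    lowcontrast = tumorPhantomSpec(seed = seed),
    ambiguous = tumorPhantomSpec(contrast = 0.12,
                                 edge_softness = c(2, 10),
                                 faded_sector = list(angle_deg = 45,
                                                     width_deg = 60,
                                                     frac = 0.3),
                                 bias = list(type = "linear", amplitude = 0.3),
                                 noise_sigma = 0.03, seed = seed))
}

#' Generate a tumor ROI phantom with ground truth and true bias field
#'
#' Builds \code{I = b * J + n} with J piecewise constant (parenchyma /
#' lesion), b a smooth strictly positive bias field of unit mean scale and n
#' iid Gaussian noise. The returned \code{bias_truth} supports bias-recovery
#' tests of the local-intensity-clustering stage.
#'
#' @param spec a \code{\link{tumorPhantomSpec}}.
#' @return list with \code{image}, \code{truth}, \code{bias_truth},
#'   \code{spec}.
#' @examples
#' tp <- makeTumorPhantom(tumorPhantomSpec(noise_sigma = 0))
#' range(as.matrix(tp$bias_truth))
#' @export
makeTumorPhantom <- function(spec = tumorPhantomSpec()) {
  stopifnot(inherits(spec, "tumorPhantomSpec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  sgn <- if (isTRUE(spec$hypodense)) 1 else -1
  lesion <- spec$liver_intensity - sgn * spec$contrast
  if (!is.null(spec$tumor$mask)) {
    tmask <- (spec$tumor$mask > 0) * 1
    stopifnot(all(dim(tmask) == spec$shape))
    J <- matrix(spec$liver_intensity, nr, nc)
    J[tmask == 1] <- lesion
  } else {
    rr <- matrix(seq_len(nr), nr, nc) - spec$tumor$center[1]
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - spec$tumor$center[2]
    r <- sqrt(rr^2 + cc^2)
    tmask <- (r <= spec$tumor$radius) * 1   # truth: half-contrast radius
    soft <- spec$edge_softness
    if (length(soft) == 2L) {
      theta <- atan2(cc, rr)
      soft <- soft[1] + (soft[2] - soft[1]) * (1 + sin(3 * theta)) / 2
    }
    w <- if (any(soft > 0)) {
      pmin(pmax(0.5 + (spec$tumor$radius - r) / pmax(soft, 1e-6), 0), 1)
    } else {
      tmask
    }
    if (!is.null(spec$faded_sector)) {
      fs <- spec$faded_sector
      theta <- atan2(cc, rr) * 180 / pi
      dAng <- abs(((theta - fs$angle_deg + 180) %% 360) - 180)
      half <- fs$width_deg / 2
      # smooth 15-degree shoulder so the sector borders add no radial edge
      fade <- fs$frac + (1 - fs$frac) * pmin(pmax((dAng - half) / 15, 0), 1)
      w <- w * fade
    }
    J <- spec$liver_intensity + (lesion - spec$liver_intensity) * w
  }

  amp <- spec$bias$amplitude
  rr <- (matrix(seq_len(nr), nr, nc) - 1) / max(nr - 1, 1)
  cc <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 1) / max(nc - 1, 1)
  b <- if (amp == 0) {
    matrix(1, nr, nc)
  } else if (identical(spec$bias$type, "quadratic")) {
    q <- (rr - 0.5)^2 + (cc - 0.5)^2          # bowl, range 0..0.5
    1 - amp / 2 + amp * q / 0.5
  } else {
    1 - amp / 2 + amp * (rr + cc) / 2          # linear sheet
  }
  if (any(b <= 0)) stop("bias field must be strictly positive")

  img <- b * J
  if (spec$noise_sigma > 0) {
    img <- .withSeed(spec$seed,
                     img + matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc))
  }
  list(image = Image2D(img), truth = BinaryMask(tmask),
       bias_truth = Image2D(b), spec = spec)
}
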