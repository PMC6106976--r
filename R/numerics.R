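# Internal raster numerics shared by the filtering and level set code.
# All stencils use replicate padding at the image border.

.shiftRep <- function(m, dr, dc) {
  # translate by (dr, dc) with replicate padding; positive dr pulls content
  # from larger row indices (i.e. value at (i,j) becomes m[i+dr, j+dc])
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

.convSep <- function(m, krow, kcol = krow) {
  # separable convolution with replicate padding
  rr <- (length(krow) - 1L) %/% 2L
  rc <- (length(kcol) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(krow)) out <- out + krow[i] * .shiftRep(m, i - rr - 1L, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kcol)) out <- out + kcol[j] * .shiftRep(m2, 0L, j - rc - 1L)
  out
}

.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gaussKernel1d(sigma)
  .convSep(m, k, k)
}

.conv2Rep <- function(m, kern) {
  # dense 2D convolution with replicate padding; kernels here are small
  # (truncated Gaussians up to ~9x9) so a shift-accumulate loop is cheap
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      w <- kern[i, j]
      if (w != 0) out <- out + w * .shiftRep(m, i - kr - 1L, j - kc - 1L)
    }
  }
  out
}

.conv2Zero <- function(m, kern) {
  # zero-padded convolution: off-image contributes nothing, i.e. the kernel
  # support is truncated to the image domain. A symmetric kernel is then
  # self-adjoint under the plain inner product, which the closed-form
  # clustering updates rely on for exact energy descent.
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      w <- kern[i, j]
      if (w == 0) next
      dr <- i - kr - 1L; dc <- j - kc - 1L
      sh <- matrix(0, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      keepR <- rs >= 1L & rs <= nr; keepC <- cs >= 1L & cs <= nc
      sh[keepR, keepC] <- m[rs[keepR], cs[keepC], drop = FALSE]
      out <- out + w * sh
    }
  }
  out
}

.gradCentral <- function(m) {
  # central differences in pixel units; replicate padding halves the
  # effective one-sided difference at the border
  list(dr = (.shiftRep(m, 1L, 0L) - .shiftRep(m, -1L, 0L)) / 2,
       dc = (.shiftRep(m, 0L, 1L) - .shiftRep(m, 0L, -1L)) / 2)
}

.gradMagnitude <- function(m) {
  g <- .gradCentral(m)
  sqrt(g$dr^2 + g$dc^2)
}

.laplacian <- function(m) {
  .shiftRep(m, 1L, 0L) + .shiftRep(m, -1L, 0L) +
    .shiftRep(m, 0L, 1L) + .shiftRep(m, 0L, -1L) - 4 * m
}

.divergence <- function(fr, fc) {
  # divergence of the vector field (fr, fc) by central differences
  (.shiftRep(fr, 1L, 0L) - .shiftRep(fr, -1L, 0L)) / 2 +
    (.shiftRep(fc, 0L, 1L) - .shiftRep(fc, 0L, -1L)) / 2
}

.diracEps <- function(x, eps) {
  # smoothed Dirac: (1/2eps)(1 + cos(pi x / eps)) on |x| <= eps, else 0
  out <- matrix(0, nrow(x), ncol(x))
  inside <- abs(x) <= eps
  out[inside] <- (1 + cos(pi * x[inside] / eps)) / (2 * eps)
  out
}

.heavisideEps <- function(x, eps) {
  # integral of .diracEps: smooth step rising over [-eps, eps]
  out <- (x > eps) * 1
  inside <- abs(x) <= eps
  xi <- x[inside]
  out[inside] <- 0.5 * (1 + xi / eps + sin(pi * xi / eps) / pi)
  out
}

.asPixels <- function(x, what = "image") {
  if (is(x, "Image2D")) return(x@pixels)
  if (is(x, "BinaryMask")) return(x@values)
  if (is(x, "LevelSetField")) return(x@phi)
  if (is.matrix(x)) return(x)
  stop("cannot interpret ", class(x)[1], " as a ", what)
}

.spacingOf <- function(x, default = c(1, 1)) {
  if (isVirtualClass(class(x)) == FALSE && .hasSlot(x, "spacing")) x@spacing else default
}

.hasSlot <- function(x, name) name %in% slotNames(class(x))
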