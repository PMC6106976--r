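.shiftZero <- function(m, dr, dc) {
  # translate with zero padding (off-image counts as background)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  keepR <- rs >= 1L & rs <= nr; keepC <- cs >= 1L & cs <= nc
  out[keepR, keepC] <- m[rs[keepR], cs[keepC], drop = FALSE]
  out
}

.boundaryPoints <- function(v, spacing) {
  # foreground pixels with at least one background 4-neighbor; the image
  # border counts as background. Returns physical coordinates (mm).
  nbMin <- pmin(.shiftZero(v, 1L, 0L), .shiftZero(v, -1L, 0L),
                .shiftZero(v, 0L, 1L), .shiftZero(v, 0L, -1L))
  idx <- which(v == 1 & nbMin == 0, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

#' Volumetric overlap error and relative volume difference
#'
#' \code{voe = 100 * (1 - |P intersect R| / |P union R|)} (percent) and the
#' signed \code{rvd = 100 * (|P| - |R|) / |R|} (percent; negative means
#' undersegmentation). Zero in both means an exact match.
#'
#' @param pred,ref \linkS4class{BinaryMask}s of equal shape; \code{ref}
#'   must be nonempty.
#' @return list with \code{voe} and \code{rvd}.
#' @export
volumeMetrics <- function(pred, ref) {
  stopifnot(is(pred, "BinaryMask"), is(ref, "BinaryMask"))
  p <- pred@values; r <- ref@values
  if (!all(dim(p) == dim(r))) stop("mask shapes differ")
  nR <- sum(r)
  if (nR == 0) stop("reference mask is empty")
  nP <- sum(p)
  inter <- sum(p * r)
  uni <- nP + nR - inter
  list(voe = 100 * (1 - inter / uni), rvd = 100 * (nP - nR) / nR)
}

#' Symmetric surface distances
#'
#' Boundary sets are the foreground pixels with at least one background
#' 4-neighbor (the image border counts as background), taken at pixel
#' centers in physical mm coordinates (anisotropic spacing respected). For
#' every boundary point of each mask the Euclidean distance to the nearest
#' boundary point of the other mask is computed; the average, root mean
#' square and maximum over the pooled symmetric set give ASD, RMSD and MSD.
#'
#' @param pred,ref nonempty \linkS4class{BinaryMask}s of equal shape.
#' @param spacing numeric(2) mm per pixel; defaults to the masks' spacing.
#' @return list with \code{asd}, \code{rmsd}, \code{msd} (mm).
#' @export
surfaceMetrics <- function(pred, ref, spacing = NULL) {
  stopifnot(is(pred, "BinaryMask"), is(ref, "BinaryMask"))
  p <- pred@values; r <- ref@values
  if (!all(dim(p) == dim(r))) stop("mask shapes differ")
  if (sum(p) == 0 || sum(r) == 0) stop("both masks must be nonempty")
  if (is.null(spacing)) spacing <- pred@spacing
  bp <- .boundaryPoints(p, spacing)
  br <- .boundaryPoints(r, spacing)
  d <- c(.nearestDistCpp(bp, br), .nearestDistCpp(br, bp))
  list(asd = mean(d), rmsd = sqrt(mean(d^2)), msd = max(d))
}

#' Full five-measure evaluation
#'
#' @param pred,ref \linkS4class{BinaryMask}s of equal shape.
#' @param spacing optional numeric(2) mm per pixel override.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' m <- BinaryMask(matrix(rep(c(0, 1), each = 50), 10, 10))
#' evaluateSegmentation(m, m)
#' @export
evaluateSegmentation <- function(pred, ref, spacing = NULL) {
  vm <- volumeMetrics(pred, ref)
  sm <- surfaceMetrics(pred, ref, spacing)
  new("MetricsReport", voe = vm$voe, rvd = vm$rvd,
      asd = sm$asd, rmsd = sm$rmsd, msd = sm$msd)
}

#' Challenge-style scoring of a metrics report
#'
#' Linear clamped per-metric score through the two anchor points: a metric
#' of 0 scores 100 (perfect segmentation) and the interobserver reference
#' value scores 75 (as good as an independent manual delineation), so
#' \code{score = max(0, 100 - 25 * |m| / m_ref)}. Reference values:
#' VOE 6.4\%, RVD 4.7\%, ASD 1.0 mm, RMSD 1.8 mm, MSD 19 mm. RVD enters by
#' absolute value. The total is the mean of the five per-metric scores.
#'
#' @param report a \linkS4class{MetricsReport}.
#' @return list with per-metric scores \code{voe}, \code{rvd}, \code{asd},
#'   \code{rmsd}, \code{msd} and their mean \code{total}, all in [0, 100].
#' @examples
#' r <- new("MetricsReport", voe = 6.4, rvd = 0, asd = 0, rmsd = 0, msd = 0)
#' sliverScore(r)$voe   # 75
#' @export
sliverScore <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  refs <- c(voe = 6.4, rvd = 4.7, asd = 1.0, rmsd = 1.8, msd = 19)
  vals <- c(voe = report@voe, rvd = report@rvd, asd = report@asd,
            rmsd = report@rmsd, msd = report@msd)
  sc <- 100 - 25 * abs(vals) / refs
  sc[sc < 0] <- 0
  out <- as.list(sc)
  out$total <- mean(sc)
  out
}

#' Convert a MetricsReport (plus optional scores) to a plain list
#'
#' The JSON report schema used by the CLI: keys \code{voe}, \code{rvd},
#' \code{asd}, \code{rmsd}, \code{msd} and, when requested, \code{scores}.
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param scores logical; attach \code{\link{sliverScore}} output.
#' @return a named list.
#' @export
reportAsList <- function(report, scores = FALSE) {
  out <- list(voe = report@voe, rvd = report@rvd, asd = report@asd,
              rmsd = report@rmsd, msd = report@msd)
  if (scores) out$scores <- sliverScore(report)
  out
}
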