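# Independent oracles and small helpers shared across the suite. These are
# deliberately naive implementations (loops, flood fills, all-pairs scans)
# kept separate from the package's code paths.

diceCoef <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  2 * sum(a * b) / (sum(a) + sum(b))
}

voeOf <- function(pred, ref) volumeMetrics(pred, ref)$voe

# flood-fill connected component count (4-connectivity), plain R
countComponents <- function(m) {
  m <- as.matrix(m) > 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  n <- 0L
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    if (!m[i, j] || seen[i, j]) next
    n <- n + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  n
}

# brute-force seeded region growing with the same FIFO/N,S,W,E order and
# incremental mean as the package documents, written independently
oracleRegionGrow <- function(img, seed, W) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  inR <- matrix(FALSE, nr, nc)
  inR[seed[1], seed[2]] <- TRUE
  total <- img[seed[1], seed[2]]; count <- 1
  q <- list()
  push <- function(p) if (p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc)
    q[[length(q) + 1L]] <<- p
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) push(seed + d)
  while (length(q)) {
    p <- q[[1]]; q <- q[-1]
    if (inR[p[1], p[2]]) next
    if (abs(img[p[1], p[2]] - total / count) < W) {
      inR[p[1], p[2]] <- TRUE
      total <- total + img[p[1], p[2]]; count <- count + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) push(p + d)
    }
  }
  inR * 1
}

# all-pairs surface distance oracle in physical units
oracleSurfaceMetrics <- function(pred, ref, spacing = c(1, 1)) {
  boundary <- function(v) {
    nr <- nrow(v); nc <- ncol(v)
    pts <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (v[i, j] != 1) next
      nb <- c(if (i > 1) v[i - 1, j] else 0, if (i < nr) v[i + 1, j] else 0,
              if (j > 1) v[i, j - 1] else 0, if (j < nc) v[i, j + 1] else 0)
      if (any(nb == 0)) pts <- rbind(pts, c(i * spacing[1], j * spacing[2]))
    }
    pts
  }
  bp <- boundary(as.matrix(pred)); br <- boundary(as.matrix(ref))
  dmat <- sqrt(outer(bp[, 1], br[, 1], `-`)^2 + outer(bp[, 2], br[, 2], `-`)^2)
  d <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  list(asd = mean(d), rmsd = sqrt(mean(d^2)), msd = max(d))
}

# pixel-count volume metric oracle
oracleVolumeMetrics <- function(pred, ref) {
  p <- as.matrix(pred); r <- as.matrix(ref)
  inter <- 0; uni <- 0
  for (k in seq_along(p)) {
    if (p[k] == 1 && r[k] == 1) inter <- inter + 1
    if (p[k] == 1 || r[k] == 1) uni <- uni + 1
  }
  list(voe = 100 * (1 - inter / uni), rvd = 100 * (sum(p) - sum(r)) / sum(r))
}

# total HMRF posterior energy, pairs counted once (independent oracle)
oracleHmrfEnergy <- function(labels, img, mu, sigma2, beta) {
  labels <- as.matrix(labels); img <- as.matrix(img)
  e <- sum((img - mu[labels + 1])^2 / (2 * sigma2[labels + 1]) +
             0.5 * log(sigma2[labels + 1]))
  nr <- nrow(labels); nc <- ncol(labels)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      q <- c(i, j) + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          labels[i, j] != labels[q[1], q[2]]) e <- e + beta
    }
  }
  e
}

randomMask <- function(nr, nc, p = 0.4) {
  BinaryMask(matrix(rbinom(nr * nc, 1, p), nr, nc))
}

# small blob mask (guaranteed nonempty, nontrivial boundary)
blobMask <- function(nr, nc, seed) {
  set.seed(seed)
  ctr <- c(sample(5:(nr - 5), 1), sample(5:(nc - 5), 1))
  r <- sample(2:4, 1)
  rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  BinaryMask(((rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2) * 1)
}
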