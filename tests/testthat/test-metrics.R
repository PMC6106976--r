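test_that("identical masks score zero on all five measures", {
  m <- blobMask(20, 20, 1)
  rep <- evaluateSegmentation(m, m)
  expect_equal(c(rep@voe, rep@rvd, rep@asd, rep@rmsd, rep@msd),
               c(0, 0, 0, 0, 0))
})

test_that("volume metrics follow the pixel-count definitions", {
  r <- matrix(0, 20, 20); r[1:10, 1:10] <- 1          # |R| = 100
  p <- matrix(0, 20, 20); p[1:10, 1:8] <- 1           # |P| = 80, nested
  vm <- volumeMetrics(BinaryMask(p), BinaryMask(r))
  expect_equal(vm$voe, 20)
  expect_equal(vm$rvd, -20)

  q <- matrix(0, 20, 20); q[15:18, 15:18] <- 1        # disjoint
  expect_equal(volumeMetrics(BinaryMask(q), BinaryMask(r))$voe, 100)
  expect_error(volumeMetrics(BinaryMask(p), BinaryMask(matrix(0, 20, 20))),
               "empty")
})

test_that("surface metrics: shifted square, spacing linearity", {
  a <- matrix(0, 20, 30); a[6:15, 6:15] <- 1
  b <- matrix(0, 20, 30); b[6:15, 9:18] <- 1          # shifted 3 columns
  sm <- surfaceMetrics(BinaryMask(a), BinaryMask(b))
  expect_equal(sm$msd, 3)
  oracle <- oracleSurfaceMetrics(a, b)
  expect_equal(sm$asd, oracle$asd, tolerance = 1e-9)
  expect_equal(sm$rmsd, oracle$rmsd, tolerance = 1e-9)

  sm2 <- surfaceMetrics(BinaryMask(a), BinaryMask(b), spacing = c(2, 2))
  expect_equal(sm2$asd, 2 * sm$asd, tolerance = 1e-12)
  expect_equal(sm2$rmsd, 2 * sm$rmsd, tolerance = 1e-12)
  expect_equal(sm2$msd, 2 * sm$msd, tolerance = 1e-12)
})

test_that("symmetries and inequalities hold on random mask pairs", {
  for (s in 1:10) {
    set.seed(100 + s)
    p <- blobMask(24, 24, 200 + s)
    r <- blobMask(24, 24, 300 + s)
    vm <- volumeMetrics(p, r); vmSwap <- volumeMetrics(r, p)
    expect_equal(vm$voe, vmSwap$voe)
    expect_equal(vm$rvd == 0, maskArea(p) == maskArea(r))
    sm <- surfaceMetrics(p, r); smSwap <- surfaceMetrics(r, p)
    expect_equal(sm$asd, smSwap$asd)
    expect_equal(sm$msd, smSwap$msd)
    expect_gte(sm$rmsd, sm$asd)      # RMS >= mean of the same sample
    expect_gte(sm$msd, sm$asd)
  }
})

test_that("metrics are translation invariant away from the border", {
  base <- matrix(0, 30, 30); base[8:14, 8:14] <- 1
  ref <- matrix(0, 30, 30); ref[9:15, 8:15] <- 1
  shift <- function(m, d) {
    out <- matrix(0, 30, 30)
    out[(1 + d):30, (1 + d):30] <- m[1:(30 - d), 1:(30 - d)]
    out
  }
  vm1 <- volumeMetrics(BinaryMask(base), BinaryMask(ref))
  vm2 <- volumeMetrics(BinaryMask(shift(base, 5)), BinaryMask(shift(ref, 5)))
  expect_equal(vm1, vm2)
  sm1 <- surfaceMetrics(BinaryMask(base), BinaryMask(ref))
  sm2 <- surfaceMetrics(BinaryMask(shift(base, 5)), BinaryMask(shift(ref, 5)))
  expect_equal(sm1, sm2)
})

test_that("challenge scoring is the clamped linear map through the anchors", {
  zero <- new("MetricsReport", voe = 0, rvd = 0, asd = 0, rmsd = 0, msd = 0)
  sc <- sliverScore(zero)
  expect_equal(unlist(sc[c("voe", "rvd", "asd", "rmsd", "msd")]),
               c(voe = 100, rvd = 100, asd = 100, rmsd = 100, msd = 100))
  expect_equal(sc$total, 100)

  ref75 <- new("MetricsReport", voe = 6.4, rvd = -4.7, asd = 1.0,
               rmsd = 1.8, msd = 19)
  sc75 <- sliverScore(ref75)
  expect_equal(unlist(sc75[c("voe", "rvd", "asd", "rmsd", "msd")]),
               c(voe = 75, rvd = 75, asd = 75, rmsd = 75, msd = 75))
  # signed RVD enters by absolute value (the -4.7 above already shows it)

  half <- new("MetricsReport", voe = 12.8, rvd = 0, asd = 0, rmsd = 0, msd = 0)
  expect_equal(sliverScore(half)$voe, 50)
  clamp <- new("MetricsReport", voe = 25.6, rvd = 0, asd = 0, rmsd = 0, msd = 0)
  expect_equal(sliverScore(clamp)$voe, 0)
})

test_that("the report list matches the JSON schema", {
  m <- blobMask(16, 16, 5)
  rep <- evaluateSegmentation(m, m)
  out <- reportAsList(rep, scores = TRUE)
  expect_named(out, c("voe", "rvd", "asd", "rmsd", "msd", "scores"))
  expect_equal(out$scores$total, 100)
})
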