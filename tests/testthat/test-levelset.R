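test_that("edge indicator: 1 on constants, dips at edges, offset-invariant", {
  expect_true(all(as.matrix(edgeIndicator(Image2D(matrix(0.7, 16, 16)))) == 1))

  half <- matrix(0, 32, 32); half[, 17:32] <- 1
  g <- as.matrix(edgeIndicator(Image2D(half)))
  expect_lt(min(g), 0.5)              # strong braking along the step
  expect_gt(min(g[, c(1:8, 25:32)]), 0.99)  # ~1 away from it
  expect_true(all(g > 0 & g <= 1))

  g2 <- as.matrix(edgeIndicator(Image2D(half + 0.2)))
  expect_equal(g, g2, tolerance = 1e-12)    # gradient kills constants
})

test_that("Chan-Vese means match a double-loop oracle and reject empty phases", {
  set.seed(6)
  I <- matrix(runif(256), 16, 16)
  phi <- matrix(rnorm(256), 16, 16)
  cc <- chanVeseMeans(Image2D(I), phi, 1.5)
  # independent loop oracle with the same smoothed Heaviside
  Hloop <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    x <- phi[i, j]
    Hloop[i, j] <- if (x > 1.5) 1 else if (x < -1.5) 0 else
      0.5 * (1 + x / 1.5 + sin(pi * x / 1.5) / pi)
  }
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (i in 1:16) for (j in 1:16) {
    num1 <- num1 + I[i, j] * Hloop[i, j]; den1 <- den1 + Hloop[i, j]
    num2 <- num2 + I[i, j] * (1 - Hloop[i, j]); den2 <- den2 + (1 - Hloop[i, j])
  }
  expect_equal(cc$c1, num1 / den1, tolerance = 1e-12)
  expect_equal(cc$c2, num2 / den2, tolerance = 1e-12)

  # sharp two-phase image: exact region constants
  phi2 <- matrix(-2, 16, 16); phi2[5:10, 5:10] <- 2
  I2 <- matrix(0, 16, 16); I2[5:10, 5:10] <- 1
  cc2 <- chanVeseMeans(Image2D(I2), phi2, 1.5)
  expect_equal(c(cc2$c1, cc2$c2), c(1, 0))

  expect_error(chanVeseMeans(Image2D(I), matrix(5, 16, 16), 1.5), "degenerate")
})

test_that("signed pressure force is normalized, signed and guarded", {
  I <- matrix(c(0, 1), 8, 8)
  spf <- as.matrix(signedPressureForce(Image2D(I), 1, 0))
  expect_true(all(spf %in% c(-1, 1)))
  expect_equal(spf[I == 1], rep(1, sum(I == 1)))
  expect_lte(max(abs(spf)), 1)
  # image equal to the midpoint: zero field
  z <- signedPressureForce(Image2D(matrix(0.5, 8, 8)), 0.6, 0.4)
  expect_true(all(as.matrix(z) == 0))
})

test_that("binary-step initialization and zero-level rasterization invert each other", {
  set.seed(7)
  m <- randomMask(12, 12)
  phi <- initLevelSet(m, 4)
  expect_true(all(as.matrix(phi) %in% c(-2, 2)))
  expect_equal(as.matrix(zeroLevelMask(phi)), as.matrix(m))
  phi2 <- initLevelSet(m, 2)
  expect_true(all(as.matrix(phi2) %in% c(-1, 1)))
  expect_error(initLevelSet(m, 1.9), "omega")
  expect_true(maskArea(zeroLevelMask(LevelSetField(matrix(-1, 8, 8)))) == 0)
})

test_that("evolution honors t = 0 and the stability bound", {
  ph <- makeLiverPhantom(liverPhantomSpec(noise_sigma = 0))
  phi0 <- initLevelSet(ph$truth)
  out <- evolveLevelSet(phi0, ph$image, iterations = 0)
  expect_identical(as.matrix(out), as.matrix(phi0))
  expect_error(evolveLevelSet(phi0, ph$image, mu = 0.3, dt = 1), "stability")
})

test_that("unified evolution recovers a bright disk from an eroded initialization", {
  rr <- matrix(1:96, 96, 96); cc <- t(rr)
  disk <- ((rr - 48)^2 + (cc - 48)^2 <= 30^2) * 1
  I <- 0.2 + 0.6 * disk
  eroded <- ((rr - 48)^2 + (cc - 48)^2 <= 25^2) * 1
  phi <- evolveLevelSet(initLevelSet(BinaryMask(eroded)), Image2D(I),
                        variant = "unified", alpha = 10, iterations = 100)
  m <- zeroLevelMask(phi)
  expect_lte(voeOf(m, BinaryMask(disk)), 2)

  # distance regularization keeps |grad phi| near 1 in the contour band
  g <- list(dr = (rbind(as.matrix(phi)[-1, ], 0) - rbind(0, as.matrix(phi)[-96, ])) / 2,
            dc = (cbind(as.matrix(phi)[, -1], 0) - cbind(0, as.matrix(phi)[, -96])) / 2)
  mag <- sqrt(g$dr^2 + g$dc^2)
  band <- abs(as.matrix(phi)) < 1.5 & rr > 5 & rr < 91 & cc > 5 & cc < 91
  expect_gt(mean(mag[band]), 0.5)
  expect_lt(mean(mag[band]), 1.5)
})

test_that("disk recovery holds across noise seeds", {
  rr <- matrix(1:96, 96, 96); cc <- t(rr)
  disk <- ((rr - 48)^2 + (cc - 48)^2 <= 30^2) * 1
  eroded <- ((rr - 48)^2 + (cc - 48)^2 <= 25^2) * 1
  for (s in 1:10) {
    set.seed(s)
    I <- 0.2 + 0.6 * disk + matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
    phi <- evolveLevelSet(initLevelSet(BinaryMask(eroded)), Image2D(I),
                          variant = "unified", alpha = 10, iterations = 100)
    m <- as.matrix(zeroLevelMask(phi))
    iou <- sum(m * disk) / sum(pmax(m, disk))
    expect_gte(iou, 0.95)
  }
})

test_that("the unified balloon term reduces to the edge balloon where SPF is +1", {
  # binary image with the contour exactly on the step: SPF is +1 inside and
  # -1 outside, so alpha*g*SPF must equal +/- alpha*g pointwise
  I <- matrix(0, 16, 16); I[, 9:16] <- 1
  img <- Image2D(I)
  cc <- chanVeseMeans(img, initLevelSet(BinaryMask(I), 4), 1.5)
  spf <- as.matrix(signedPressureForce(img, cc$c1, cc$c2))
  g <- as.matrix(edgeIndicator(img))
  unifiedB <- 10 * g * spf
  edgeB <- 10 * g
  expect_equal(unifiedB[I == 1], edgeB[I == 1], tolerance = 1e-9)
  expect_equal(unifiedB[I == 0], -edgeB[I == 0], tolerance = 1e-9)
})

test_that("liver refinement fills holes and is deterministic", {
  spec <- liverPhantomSpec(
    vessels = list(list(center = c(80, 62), radius = 5, intensity = 0.25)),
    noise_sigma = 0)
  ph <- makeLiverPhantom(spec)
  bw <- preprocessPipeline(ph$image, runConfig())
  rough <- regionGrow(Image2D(as.matrix(bw)), c(70, 50), W = 0.5)
  seg <- refineLiver(rough, ph$image, runConfig())
  # no interior holes survive
  expect_identical(as.matrix(fillHoles(seg)), as.matrix(seg))
  # the vessel hole was recovered into the envelope
  expect_equal(as.matrix(seg)[80, 62], 1)
  seg2 <- refineLiver(rough, ph$image, runConfig())
  expect_identical(as.matrix(seg), as.matrix(seg2))
  expect_error(refineLiver(BinaryMask(matrix(0, 10, 10)), ph$image), "empty")
})
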