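test_that("ROI crop and paste round-trip and validate bounds", {
  img <- Image2D(matrix(1:400 / 400, 20, 20))
  rect <- RoiRect(4, 6, 12, 16)
  roi <- cropRoi(img, rect)
  expect_equal(dim(roi), c(8L, 10L))
  ones <- BinaryMask(matrix(1, 8, 10))
  back <- pasteRoi(c(20, 20), rect, ones)
  expect_equal(sum(as.matrix(back)), 80)
  expect_equal(as.matrix(cropRoi(Image2D(as.matrix(back)), rect)),
               as.matrix(ones))
  expect_error(cropRoi(img, RoiRect(10, 10, 25, 25)), "bounds")
  expect_error(pasteRoi(c(20, 20), rect, BinaryMask(matrix(1, 5, 5))), "shape")
})

test_that("truncated Gaussian kernel has the stated support and center", {
  K <- truncatedGaussianKernel(3, 4, 1)
  expect_equal(dim(K), c(7L, 7L))
  expect_equal(K[4, 4], 1)                 # exp(0)/a with a = 1
  expect_equal(K[1, 1], 0)                 # |u| = sqrt(18) > 3: truncated
  expect_equal(K, t(K))                    # symmetric
  expect_equal(K[4, 1], exp(-9 / 32))      # |u| = 3 boundary included
  K2 <- truncatedGaussianKernel(2, 1, 2)
  expect_equal(K2[3, 3], 0.5)
})

test_that("closed-form c update: constants pass through, symmetry, guards", {
  I <- matrix(0.5, 24, 24); I[8:16, 8:16] <- 0.3
  phi <- matrix(-2, 24, 24); phi[8:16, 8:16] <- 2
  K <- truncatedGaussianKernel(3, 4, 1)
  b <- matrix(1, 24, 24)
  cs <- licUpdateC(Image2D(I), b, phi, K, 1.5)
  expect_equal(cs$c1, 0.3, tolerance = 0.05)   # kernel mixes the boundary ring
  expect_equal(cs$c2, 0.5, tolerance = 0.05)
  # swapping the partition swaps the constants
  cs2 <- licUpdateC(Image2D(I), b, -phi, K, 1.5)
  expect_equal(cs2$c1, cs$c2)
  expect_equal(cs2$c2, cs$c1)
  expect_error(licUpdateC(Image2D(I), b, matrix(3, 24, 24), K), "degenerate")
})

test_that("c and b updates are stationary points: numeric perturbation raises the energy", {
  set.seed(8)
  tp <- makeTumorPhantom(tumorPhantomSpec(shape = c(24, 24),
                                          tumor = list(center = c(12, 12), radius = 6),
                                          edge_softness = 0, noise_sigma = 0.02))
  K <- truncatedGaussianKernel(3, 4, 1)
  phi <- 4 * (as.matrix(tp$truth) - 0.5)
  b <- matrix(1, 24, 24)
  cs <- licUpdateC(tp$image, b, phi, K, 1.5)
  e0 <- licEnergy(tp$image, b, cs, phi, K, 1.5)
  for (h in c(1e-3, -1e-3)) {
    expect_gt(licEnergy(tp$image, b, list(c1 = cs$c1 + h, c2 = cs$c2), phi, K, 1.5), e0)
    expect_gt(licEnergy(tp$image, b, list(c1 = cs$c1, c2 = cs$c2 + h), phi, K, 1.5), e0)
  }
  b1 <- licUpdateBias(tp$image, cs, phi, K, 1.5)
  e1 <- licEnergy(tp$image, b1, cs, phi, K, 1.5)
  expect_lte(e1, e0 + 1e-9)
  pert <- b1; pert[10, 10] <- pert[10, 10] + 1e-3
  expect_gt(licEnergy(tp$image, pert, cs, phi, K, 1.5), e1)
})

test_that("bias self-consistency: unbiased image with exact partition gives b = 1", {
  tp <- makeTumorPhantom(tumorPhantomSpec(edge_softness = 0, noise_sigma = 0,
                                          bias = list(type = "linear", amplitude = 0)))
  K <- truncatedGaussianKernel(3, 4, 1)
  phi <- 4 * (as.matrix(tp$truth) - 0.5)
  b <- licUpdateBias(tp$image, list(c1 = 0.45, c2 = 0.55), phi, K, 1.5)
  expect_lt(max(abs(b[5:60, 5:60] - 1)), 1e-6)
})

test_that("alternating c/b updates descend the energy and recover a linear bias", {
  tp <- makeTumorPhantom(tumorPhantomSpec(edge_softness = 0, noise_sigma = 0.02))
  K <- truncatedGaussianKernel(3, 4, 1)
  phi <- 4 * (as.matrix(tp$truth) - 0.5)
  b <- matrix(1, 64, 64)
  cs <- list(c1 = 0.45, c2 = 0.55)
  ePrev <- licEnergy(tp$image, b, cs, phi, K, 1.5)
  for (k in 1:20) {
    cs <- licUpdateC(tp$image, b, phi, K, 1.5)
    e1 <- licEnergy(tp$image, b, cs, phi, K, 1.5)
    expect_lte(e1, ePrev + 1e-6)
    b <- licUpdateBias(tp$image, cs, phi, K, 1.5)
    e2 <- licEnergy(tp$image, b, cs, phi, K, 1.5)
    expect_lte(e2, e1 + 1e-6)
    ePrev <- e2
  }
  bt <- as.matrix(tp$bias_truth)
  interior <- matrix(FALSE, 64, 64); interior[5:60, 5:60] <- TRUE
  expect_gte(cor(b[interior], bt[interior]), 0.99)
})

test_that("evolveLic segments a biased two-phase ROI and is seed-reproducible", {
  # two-phase (piecewise constant) ROI: contrast 0.1, bias 0.3, noise 0.02
  tp <- makeTumorPhantom(tumorPhantomSpec(edge_softness = 0))
  fit <- evolveLic(tp$image, runConfig(seed = 1))
  expect_gte(diceCoef(fit$mask, tp$truth), 0.90)
  fit2 <- evolveLic(tp$image, runConfig(seed = 1))
  expect_identical(as.matrix(fit$mask), as.matrix(fit2$mask))
  expect_true(all(as.matrix(fit$bias) > 0))
})

test_that("the tumor phase is picked against the ROI border, hyperdense included", {
  tp <- makeTumorPhantom(tumorPhantomSpec(hypodense = FALSE, contrast = 0.2,
                                          edge_softness = 0,
                                          bias = list(type = "linear", amplitude = 0)))
  fit <- evolveLic(tp$image, runConfig(seed = 2))
  expect_gte(diceCoef(fit$mask, tp$truth), 0.9)
})

test_that("HMRF initialization takes sample statistics from the mask", {
  set.seed(9)
  I <- matrix(rnorm(900, 0.3, 0.04), 30, 30)
  blk <- matrix(0, 30, 30); blk[10:20, 10:20] <- 1
  I[blk == 1] <- rnorm(sum(blk), 0.7, 0.04)
  st <- hmrfInit(Image2D(I), BinaryMask(blk))
  expect_equal(st@mu[1], 0.3, tolerance = 0.02)
  expect_equal(st@mu[2], 0.7, tolerance = 0.02)
  expect_identical(st@labels, blk)
  # constant class hits the variance floor
  I2 <- matrix(0.5, 10, 10); I2[1:3, ] <- 0.1
  m2 <- matrix(0, 10, 10); m2[1:3, ] <- 1
  st2 <- hmrfInit(Image2D(I2), BinaryMask(m2))
  expect_equal(st2@sigma2, c(1e-6, 1e-6))
  expect_error(hmrfInit(Image2D(I2), BinaryMask(matrix(1, 10, 10))), "nonempty")
})

test_that("ICM with zero potts weight is per-pixel ML classification", {
  set.seed(10)
  I <- matrix(runif(400), 20, 20)
  st <- new("HMRFState", labels = matrix(rbinom(400, 1, 0.5), 20, 20),
            mu = c(0.25, 0.75), sigma2 = c(0.01, 0.04), pottsBeta = 0)
  lab <- hmrfMapIcm(st, Image2D(I), 5)
  ml <- ifelse((I - 0.25)^2 / 0.02 + 0.5 * log(0.01) >
               (I - 0.75)^2 / 0.08 + 0.5 * log(0.04), 1, 0)
  expect_equal(lab, ml)
})

test_that("ICM flips an isolated mislabeled pixel and descends the posterior energy", {
  set.seed(11)
  I <- matrix(rnorm(225, 0.3, 0.03), 15, 15)
  lab0 <- matrix(0, 15, 15); lab0[8, 8] <- 1   # lone wrong label
  st <- new("HMRFState", labels = lab0, mu = c(0.3, 0.8),
            sigma2 = c(0.01, 0.01), pottsBeta = 1)
  lab <- hmrfMapIcm(st, Image2D(I), 1)
  expect_equal(sum(lab), 0)

  # energy non-increasing sweep by sweep (independent oracle, pairs once)
  I2 <- matrix(runif(400, 0, 1), 20, 20)
  st2 <- new("HMRFState", labels = matrix(rbinom(400, 1, 0.5), 20, 20),
             mu = c(0.3, 0.7), sigma2 = c(0.02, 0.02), pottsBeta = 0.5)
  ePrev <- oracleHmrfEnergy(st2@labels, I2, st2@mu, st2@sigma2, 0.5)
  lab <- st2@labels
  for (s in 1:5) {
    lab <- hmrfMapIcm(new("HMRFState", labels = lab, mu = st2@mu,
                          sigma2 = st2@sigma2, pottsBeta = 0.5),
                      Image2D(I2), 1)
    e <- oracleHmrfEnergy(lab, I2, st2@mu, st2@sigma2, 0.5)
    expect_lte(e, ePrev + 1e-9)
    ePrev <- e
  }
})

test_that("HMRF-EM recovers labels and parameters from a corrupted init", {
  set.seed(42)
  truth <- matrix(0, 48, 48); truth[12:36, 12:36] <- 1
  I <- matrix(rnorm(48 * 48, 0.3, 0.05), 48, 48)
  I[truth == 1] <- rnorm(sum(truth), 0.6, 0.05)
  init <- truth
  flip <- sample(length(init), round(0.1 * length(init)))
  init[flip] <- 1 - init[flip]
  out <- hmrfEm(Image2D(I), BinaryMask(init), 15, 15, 0.5)
  expect_gte(mean(as.matrix(out) == truth), 0.95)
  st <- hmrfInit(Image2D(I), out)
  expect_lt(abs(st@mu[1] - 0.3), 0.02)
  expect_lt(abs(st@mu[2] - 0.6), 0.02)
})

test_that("HMRF-EM leaves a perfectly separated exact initialization alone", {
  I <- matrix(0.2, 20, 20); I[6:14, 6:14] <- 0.8
  init <- (I > 0.5) * 1
  out <- hmrfEm(Image2D(I), BinaryMask(init), 5, 5, 0.5)
  expect_identical(as.matrix(out), init)
})

test_that("enhanced edge indicator dominates both inputs and guards constants", {
  tp <- makeTumorPhantom(tumorPhantomSpec(shape = c(48, 48),
                                          tumor = list(center = c(24, 24), radius = 10),
                                          edge_softness = 0,
                                          contrast = 0.2, noise_sigma = 0.02,
                                          bias = list(type = "linear", amplitude = 0)))
  g <- edgeIndicator(tp$image)
  gE <- enhancedEdgeIndicator(tp$image, tp$truth)
  expect_true(all(as.matrix(gE) >= as.matrix(g) - 1e-12))
  # interior of the classified disk propagates fast, the band keeps g's value
  inner <- as.matrix(gE)[20:28, 20:28]
  expect_true(all(inner > 0.99))
  band <- as.matrix(gE)[24, 14]     # on the class boundary ring
  expect_lt(band, 0.5)
  expect_gt(band, 0)                # never exactly stops

  # constant classification contributes nothing
  flat <- BinaryMask(matrix(1, 48, 48))
  gE2 <- enhancedEdgeIndicator(tp$image, flat)
  expect_equal(as.matrix(gE2), as.matrix(g))
})

test_that("segmentTumor handles the clean phantom and validates its inputs", {
  tp <- makeTumorPhantom(tumorPhantomPreset("clean"))
  full <- matrix(0.55, 80, 80); full[9:72, 9:72] <- as.matrix(tp$image)
  truth <- matrix(0, 80, 80); truth[9:72, 9:72] <- as.matrix(tp$truth)
  img <- Image2D(full)
  roi <- RoiRect(8, 8, 72, 72); init <- RoiRect(31, 31, 49, 49)
  seg <- segmentTumor(img, roi, init, runConfig(seed = 1))
  expect_gte(diceCoef(seg, BinaryMask(truth)), 0.95)
  seg2 <- segmentTumor(img, roi, init, runConfig(seed = 1))
  expect_identical(as.matrix(seg), as.matrix(seg2))
  expect_error(segmentTumor(img, roi, RoiRect(0, 0, 40, 40), runConfig()),
               "strictly inside")
})
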