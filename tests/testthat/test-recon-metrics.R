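test_that("rSOS inverts the fully sampled acquisition and degrades monotonically with R", {
  h <- 64
  f <- pixels(sampleLumpyBackground(lumpyParams(shape = c(h, h)), seed = 1))

  # single uniform coil, R = 1, noiseless: exact recovery
  g1 <- senseForward(f, uniformCoil(h), makeCartesianMask(h, 1))
  expect_lt(max(abs(pixels(reconRSOS(g1)) - f)), 1e-9)

  # SoS-normalized 8-coil ensemble recovers |f| at R = 1
  coils8 <- simulateCoilMaps(8, c(h, h))
  g8 <- senseForward(f, coils8, makeCartesianMask(h, 1))
  r8 <- reconRSOS(g8)
  expect_lt(max(abs(pixels(r8) - abs(f))), 1e-6)
  expect_true(all(pixels(r8) >= 0))

  # aliasing: noiseless rSOS RMSE non-decreasing over the nested mask family
  for (seed in 1:3) {
    fs <- pixels(sampleLumpyBackground(lumpyParams(shape = c(h, h)), seed = seed))
    errs <- vapply(c(1, 2, 4, 8), function(R) {
      g <- senseForward(fs, coils8, makeCartesianMask(h, R))
      rmse(reconRSOS(g), fs)
    }, numeric(1))
    expect_true(all(diff(errs) >= -1e-12))
  }
})

test_that("CG-SENSE solves the regularized normal equations", {
  h <- 64
  f <- pixels(sampleLumpyBackground(lumpyParams(shape = c(h, h)), seed = 4))
  coils8 <- simulateCoilMaps(8, c(h, h))

  # full sampling, no regularization: exact recovery
  g1 <- senseForward(f, coils8, makeCartesianMask(h, 1))
  rec <- reconCgSense(g1, coils8, lambda = 0, maxIter = 30)
  expect_lt(rmse(rec, abs(f)) / sqrt(mean(f^2)), 1e-6)
  expect_true(rec@provenance$converged)

  # heavy regularization shrinks the solution toward zero
  gb <- senseForward(f, coils8, makeCartesianMask(h, 4))
  big <- reconCgSense(gb, coils8, lambda = 1e9, maxIter = 20)
  expect_lt(sqrt(sum(pixels(big)^2)),
            1e-6 * sqrt(sum(Mod(senseAdjoint(gb, coils8))^2)))

  # the quadratic objective CG minimizes decreases monotonically (the
  # residual 2-norm itself is not monotone for CG and is only reported)
  mid <- reconCgSense(gb, coils8, lambda = 0.05, maxIter = 20)
  expect_true(all(diff(mid@provenance$objective) <= 1e-9))
  expect_gt(length(mid@provenance$residuals), 1L)

  # agreement with rSOS-recoverable truth at R = 1
  rec0 <- reconCgSense(g1, coils8, lambda = 0, maxIter = 30)
  expect_lt(max(abs(pixels(rec0) - pixels(reconRSOS(g1)))), 1e-6)
})

test_that("the learned reconstructor reduces error over its rSOS input", {
  h <- 32
  coils <- simulateCoilMaps(4, c(h, h))
  sigma <- 0.6
  makePairs <- function(R, n, seed) {
    xs <- array(0, c(h, h, n)); ts <- array(0, c(h, h, n))
    mask <- makeCartesianMask(h, R)
    for (i in seq_len(n)) {
      f <- pixels(sampleLumpyBackground(lumpyParams(shape = c(h, h)),
                                        seed = seed + i))
      g <- senseForward(f, coils, mask, noiseModel(sigma), seed = seed + i)
      xs[, , i] <- pixels(reconRSOS(g))
      ts[, , i] <- f
    }
    list(x = xs, t = ts)
  }

  # R = 1 (denoising-only regime): net beats raw rSOS input on held-out data
  tr <- makePairs(1, 72, 100)
  va <- makePairs(1, 24, 900)
  net <- trainReconNet(tr$x, tr$t, width = 8, epochs = 40, seed = 2)
  rmseIn <- mean(vapply(1:24, function(i) rmse(va$x[, , i], va$t[, , i]),
                        numeric(1)))
  rmseNet <- mean(vapply(1:24, function(i)
    rmse(applyReconNet(net, va$x[, , i]), va$t[, , i]), numeric(1)))
  expect_lt(rmseNet, rmseIn)

  # R = 4: net beats rSOS on held-out pairs
  tr4 <- makePairs(4, 72, 300)
  va4 <- makePairs(4, 24, 1200)
  net4 <- trainReconNet(tr4$x, tr4$t, width = 8, epochs = 40, seed = 3)
  rmseRsos <- mean(vapply(1:24, function(i) rmse(va4$x[, , i], va4$t[, , i]),
                          numeric(1)))
  rmseNet4 <- mean(vapply(1:24, function(i)
    rmse(applyReconNet(net4, va4$x[, , i]), va4$t[, , i]), numeric(1)))
  expect_lt(rmseNet4, rmseRsos)

  # application is deterministic and training loss was recorded
  expect_identical(pixels(applyReconNet(net4, va4$x[, , 1])),
                   pixels(applyReconNet(net4, va4$x[, , 1])))
  expect_gt(length(net4@lossTrace), 0L)
  expect_error(trainReconNet(array(0, c(h, h, 0)), array(0, c(h, h, 0))),
               "empty")
})

test_that("rmse matches a direct-summation oracle", {
  set.seed(8)
  x <- matrix(rnorm(30 * 20), 30)
  y <- matrix(rnorm(30 * 20), 30)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 1.7), 1.7)
  # independent elementwise loop
  acc <- 0
  for (i in 1:30) for (j in 1:20) acc <- acc + (x[i, j] - y[i, j])^2
  expect_lt(abs(rmse(x, y) - sqrt(acc / 600)), 1e-12)
  expect_error(rmse(x, matrix(0, 10, 10)), "shape")
})

test_that("ssim matches its closed forms and a direct windowed oracle", {
  set.seed(9)
  x <- matrix(runif(20 * 16), 20)
  expect_lt(abs(ssim(x, x) - 1), 1e-9)

  y <- matrix(runif(20 * 16), 20)
  L <- diff(range(y))
  expect_lt(abs(ssim(x, y, dynamicRange = L) - ssim(y, x, dynamicRange = L)),
            1e-12)

  # constant images: closed form with zero variances
  a <- 0.4; b <- 0.9; C1 <- (0.01 * 1)^2
  expect_lt(abs(ssim(matrix(a, 8, 8), matrix(b, 8, 8), dynamicRange = 1) -
                  (2 * a * b + C1) / (a^2 + b^2 + C1)), 1e-9)

  # independent per-pixel windowed implementation (explicit loops)
  ws <- 1.5; rad <- ceiling(3 * ws)
  K1 <- 0.01; K2 <- 0.03
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- matrix(0, 20, 16)
  for (i in 1:20) for (j in 1:16) {
    wi <- max(1, i - rad):min(20, i + rad)
    wj <- max(1, j - rad):min(16, j + rad)
    wgt <- outer(exp(-(wi - i)^2 / (2 * ws^2)), exp(-(wj - j)^2 / (2 * ws^2)))
    wgt <- wgt / sum(wgt)
    mx <- sum(wgt * x[wi, wj]); my <- sum(wgt * y[wi, wj])
    vx <- sum(wgt * x[wi, wj]^2) - mx^2
    vy <- sum(wgt * y[wi, wj]^2) - my^2
    cxy <- sum(wgt * x[wi, wj] * y[wi, wj]) - mx * my
    vals[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  expect_lt(abs(ssim(x, y, dynamicRange = L) - mean(vals)), 1e-9)
})
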