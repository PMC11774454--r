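test_that("coil maps normalize and inherit the array's rotational symmetry", {
  # single normalized coil has unit magnitude everywhere
  one <- simulateCoilMaps(1, c(32, 32))
  expect_lt(max(abs(Mod(coilMaps(one)[, , 1]) - 1)), 1e-12)

  # pixelwise sum of squares is one
  coils <- simulateCoilMaps(8, c(64, 64))
  sos <- apply(abs(coilMaps(coils))^2, c(1, 2), sum)
  expect_lt(max(abs(sos - 1)), 1e-6)

  # evaluating the maps on a grid rotated by 2*pi/C about the centre
  # permutes the coils (odd-sized grid so the centre is a pixel)
  h <- 65
  c8 <- simulateCoilMaps(8, c(h, h))
  theta <- 2 * pi / 8
  r0 <- (h + 1) / 2
  rr <- matrix(seq_len(h), h, h) - r0
  cc <- matrix(seq_len(h), h, h, byrow = TRUE) - r0
  rot <- list(row = r0 + cos(theta) * rr - sin(theta) * cc,
              col = r0 + sin(theta) * rr + cos(theta) * cc)
  rotMaps <- simulateCoilMaps(8, c(h, h), coords = rot)
  for (i in 1:8)
    expect_lt(max(Mod(coilMaps(rotMaps)[, , i] -
                        coilMaps(c8)[, , (i %% 8) + 1])), 1e-6)
})

test_that("Cartesian masks select the right lines and nest across R", {
  expect_equal(sum(lineSelector(makeCartesianMask(64, 1))), 64L)

  m4 <- makeCartesianMask(64, 4)
  expect_identical(which(lineSelector(m4)), seq(1L, 61L, by = 4L))
  expect_equal(sum(lineSelector(m4)), 16L)

  # nesting with offset 0
  s2 <- lineSelector(makeCartesianMask(64, 2))
  s8 <- lineSelector(makeCartesianMask(64, 8))
  expect_true(all(!s8 | lineSelector(m4)))
  expect_true(all(!lineSelector(m4) | s2))

  # centre lines forced on
  mc <- makeCartesianMask(64, 8, centerFraction = 0.1)
  expect_true(all(lineSelector(mc)[30:36]))
  expect_error(makeCartesianMask(64, 100), "R must")

  # achieved acceleration within one line of nominal when centerFraction = 0
  for (R in c(1, 2, 4, 8)) {
    sel <- lineSelector(makeCartesianMask(64, R))
    expect_lt(abs(64 / sum(sel) - R), R / sum(sel) + 1e-9)
  }
})

test_that("forward model is unitary, masked, linear, and has an exact adjoint", {
  h <- 64
  coils1 <- uniformCoil(h)
  m1 <- makeCartesianMask(h, 1)
  f <- matrix(abs(rnorm(h * h)), h)

  # Parseval at full sampling with a uniform coil
  g <- senseForward(f, coils1, m1)
  expect_lt(abs(sqrt(sum(Mod(kspace(g))^2)) - sqrt(sum(f^2))), 1e-9)

  # unselected lines exactly zero
  m4 <- makeCartesianMask(h, 4)
  coils8 <- simulateCoilMaps(8, c(h, h))
  g4 <- senseForward(f, coils8, m4, noiseModel(2), seed = 3)
  expect_true(all(kspace(g4)[!lineSelector(m4), , ] == 0 + 0i))

  # linearity of the noiseless map
  f2 <- matrix(rnorm(h * h), h)
  sel <- lineSelector(m4)
  lhs <- senseIO:::.forwardArray(2.5 * f - 1.25 * f2, coils8, sel)
  rhs <- 2.5 * senseIO:::.forwardArray(f, coils8, sel) -
    1.25 * senseIO:::.forwardArray(f2, coils8, sel)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-10)

  # randomized adjoint identity over a grid of coils x masks
  set.seed(42)
  for (coils in list(coils1, coils8)) {
    nc <- nCoils(coils)
    for (R in c(1, 2, 4, 8)) {
      m <- makeCartesianMask(h, R)
      for (rep in 1:5) {
        x <- matrix(rnorm(h * h), h)
        y <- array(complex(real = rnorm(h * h * nc),
                           imaginary = rnorm(h * h * nc)), c(h, h, nc))
        Ax <- senseIO:::.forwardArray(x, coils, lineSelector(m))
        Aty <- senseIO:::.adjointArray(y, coils, lineSelector(m))
        lhs <- sum(Conj(y) * Ax)
        rhs <- sum(Conj(Aty) * x)
        expect_lt(Mod(lhs - rhs) /
                    (sqrt(sum(Mod(y)^2)) * sqrt(sum(x^2))), 1e-10)
      }
    }
  }

  # energy is monotone over the nested mask family
  en <- vapply(c(1, 2, 4, 8), function(R)
    sum(Mod(senseIO:::.forwardArray(f, coils8,
                                    lineSelector(makeCartesianMask(h, R))))^2),
    numeric(1))
  expect_true(all(diff(en) <= 1e-9))

  # adjoint contract cases
  g0 <- new("KspaceData", samples = array(0 + 0i, c(h, h, 8)), mask = m4,
            hypothesisLabel = "unknown", noiseSigma = 0)
  expect_true(all(senseAdjoint(g0, coils8) == 0 + 0i))
  gf <- senseForward(f, coils1, m1)
  expect_lt(max(Mod(senseAdjoint(gf, coils1) -
                      senseIO:::.ifft2c(kspace(gf)[, , 1]))), 1e-12)
})

test_that("k-space noise has the configured per-component statistics", {
  h <- 400; w <- 250  # 1e5 samples
  k <- matrix(0 + 0i, h, w)
  m <- makeCartesianMask(h, 1)
  nz <- addNoise(k, noiseModel(15), m, seed = 9)
  expect_gt(stats::sd(Re(nz)), 14.85)
  expect_lt(stats::sd(Re(nz)), 15.15)
  expect_gt(stats::sd(Im(nz)), 14.85)
  expect_lt(stats::sd(Im(nz)), 15.15)

  # sigma = 0 is the identity; same seed reproduces the noise exactly
  expect_identical(addNoise(k, noiseModel(0), m, seed = 1), k)
  expect_identical(addNoise(k, noiseModel(3), m, seed = 4),
                   addNoise(k, noiseModel(3), m, seed = 4))

  # noise only lands on selected lines
  m2 <- makeCartesianMask(h, 8)
  nz2 <- addNoise(matrix(0 + 0i, h, w), noiseModel(3), m2, seed = 5)
  expect_true(all(nz2[!lineSelector(m2), ] == 0 + 0i))
  expect_error(noiseModel(-1), "nonnegative")
})
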