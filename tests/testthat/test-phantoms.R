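test_that("lumpy background generator is seeded, truncates at edges, and matches its analytic mean", {
  # empty Poisson sum
  p0 <- lumpyParams(meanLumpCount = 0, dcOffset = 0, shape = c(32, 32))
  expect_true(all(pixels(sampleLumpyBackground(p0, seed = 1)) == 0))

  # seeded determinism, seed sensitivity
  p <- lumpyParams(shape = c(32, 32))
  expect_identical(pixels(sampleLumpyBackground(p, seed = 7)),
                   pixels(sampleLumpyBackground(p, seed = 7)))
  expect_false(identical(pixels(sampleLumpyBackground(p, seed = 7)),
                         pixels(sampleLumpyBackground(p, seed = 8))))

  # ensemble mean against the exact expectation (Campbell's theorem with
  # edge truncation), computed by an independent quadrature over uniform
  # lump centres: E[sum of one lump] = A * E_r[rowSum] * E_c[colSum].
  h <- 32
  amp <- 0.5; sig <- 2.5; count <- 20; dc <- 0.3
  p2 <- lumpyParams(meanLumpCount = count, lumpAmplitude = amp,
                    lumpSigmaMM = sig, shape = c(h, h), dcOffset = dc)
  nq <- 256
  centersQ <- 0.5 + (seq_len(nq) - 0.5) * h / nq  # midpoint rule on (0.5, h+0.5)
  oneD <- vapply(centersQ,
                 function(c0) sum(exp(-(seq_len(h) - c0)^2 / (2 * sig^2))),
                 numeric(1))
  expMean <- dc + count * amp * mean(oneD)^2 / h^2
  nrep <- 2000
  means <- vapply(seq_len(nrep),
                  function(i) mean(pixels(sampleLumpyBackground(p2, seed = 10000 + i))),
                  numeric(1))
  se <- stats::sd(means) / sqrt(nrep)
  expect_lt(abs(mean(means) - expMean), 3 * se)
})

test_that("stylized brain phantom is reproducible with a valid in-head tissue mask", {
  ph <- makeStylizedBrain(c(64, 64), seed = 3)
  ph2 <- makeStylizedBrain(c(64, 64), seed = 3)
  expect_identical(pixels(ph), pixels(ph2))
  expect_identical(tissueMask(ph), tissueMask(ph2))

  msk <- tissueMask(ph)
  expect_true(any(msk))
  # mask lies inside the head (nonzero intensity support)
  expect_true(all(pixels(ph)[msk] > 0))

  # different seeds differ in more than 1% of pixels
  ph3 <- makeStylizedBrain(c(64, 64), seed = 4)
  expect_gt(mean(pixels(ph) != pixels(ph3)), 0.01)

  expect_error(makeStylizedBrain(c(16, 64), seed = 1), "32")
})

test_that("Gaussian signal rendering matches its closed form", {
  h <- 64
  sig <- signalModel(amplitude = 0.7, sigmaMM = 2, center = c(33, 33))
  img <- pixels(renderGaussianSignal(sig, 1, c(h, h)))
  expect_equal(img[33, 33], 0.7)                      # amplitude at centre
  expect_true(all(pixels(renderGaussianSignal(
    signalModel(0, 2, c(33, 33)), 1, c(h, h))) == 0)) # zero amplitude

  # discrete sum vs analytic 2*pi*sigma^2*A for a signal far from edges
  sigPx <- 2
  expect_lt(abs(sum(img) - 0.7 * 2 * pi * sigPx^2) / (0.7 * 2 * pi * sigPx^2),
            1e-3)

  # sub-pixel widths are rejected; mm-to-pixel conversion honoured
  expect_error(renderGaussianSignal(signalModel(1, 0.4, c(33, 33)), 1,
                                    c(h, h)), "half a pixel")
  wide <- pixels(renderGaussianSignal(signalModel(1, 2, c(33, 33)), 0.5,
                                      c(h, h)))  # sigma = 4 px
  expect_lt(abs(sum(wide) - 2 * pi * 16) / (2 * pi * 16), 1e-3)
})

test_that("signal locations are uniform over the mask", {
  m <- matrix(FALSE, 16, 16)
  m[5, 9] <- TRUE
  expect_identical(unname(sampleSignalLocation(m, seed = 1)), c(5L, 9L))
  expect_error(sampleSignalLocation(matrix(FALSE, 4, 4), seed = 1),
               "eligible")

  m2 <- matrix(FALSE, 16, 16)
  m2[5:10, 3:10] <- TRUE   # 48 eligible pixels
  n <- 5000
  draws <- vapply(seq_len(n),
                  function(i) sampleSignalLocation(m2, seed = i), integer(2))
  expect_true(all(m2[t(draws)]))
  counts <- table(factor(paste(draws[1, ], draws[2, ]),
                         levels = {
                           idx <- which(m2, arr.ind = TRUE)
                           paste(idx[, 1], idx[, 2])
                         }))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("hypothesis pairs are exactly additive in the rendered signal", {
  bg <- sampleLumpyBackground(lumpyParams(shape = c(48, 48)), seed = 2)
  sig <- signalModel(amplitude = 0.7, sigmaMM = 2, center = c(20.4, 30.2))
  hp <- composeHypothesisPair(bg, sig)
  rendered <- pixels(renderGaussianSignal(sig, 1, c(48, 48)))
  expect_equal(pixels(hp@fH1) - pixels(hp@fH0), rendered)

  # peak of the difference sits at the centre rounded to the grid
  d <- pixels(hp@fH1) - pixels(hp@fH0)
  peak <- which(d == max(d), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, ]), as.integer(round(c(20.4, 30.2))))

  # zero background: H1 equals the rendered signal
  z <- objectImage(matrix(0, 48, 48))
  expect_equal(pixels(composeHypothesisPair(z, sig)@fH1), rendered)

  # additivity: amplitude a then subtracting H0 recovers the a-scaled unit signal
  a <- 3.7
  hpA <- composeHypothesisPair(bg, signalModel(a, 2, c(20.4, 30.2)))
  unit <- pixels(renderGaussianSignal(signalModel(1, 2, c(20.4, 30.2)),
                                      1, c(48, 48)))
  expect_equal(pixels(hpA@fH1) - pixels(hpA@fH0), a * unit)
})

test_that("object ensembles round-trip through NIfTI", {
  imgs <- lapply(1:3, function(i)
    sampleLumpyBackground(lumpyParams(shape = c(32, 32)), seed = i))
  f <- file.path(withr::local_tempdir(), "ens.nii.gz")
  writeEnsemble(imgs, f)
  back <- readEnsemble(f)
  expect_length(back, 3L)
  expect_equal(pixels(back[[2]]), pixels(imgs[[2]]), tolerance = 1e-6)
  expect_equal(pixelSize(back[[1]]), 1)
  expect_identical(tissueMask(back[[1]]), tissueMask(imgs[[1]]))
})
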