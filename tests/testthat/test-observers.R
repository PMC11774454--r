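test_that("the SKE/BKE statistic has its Gaussian-theory moments and invariances", {
  task <- skeTask(h = 32, dPrimeTarget = 2)
  sel <- lineSelector(task$mask)
  sv <- as.vector(task$sK); bv <- as.vector(task$bK)

  # zero signal: statistic identically zero
  g <- task$bK + 0.5i
  expect_equal(skeBkeStatistic(g, task$bK, 0 * task$sK, task$sigma), 0)

  # Monte-Carlo mean separation equals ||s||^2 / sigma^2 within 3 SE
  st <- mcSkeStatistics(task, n = 10000, seed = 77)
  sep <- mean(st$t1) - mean(st$t0)
  seSep <- sqrt(stats::var(st$t0) / 1e4 + stats::var(st$t1) / 1e4)
  expect_lt(abs(sep - sum(Mod(sv)^2) / task$sigma^2), 3 * seSep)

  # invariant to perturbations orthogonal to the signal
  set.seed(5)
  v <- complex(real = rnorm(length(sv)), imaginary = rnorm(length(sv)))
  v <- v - sv * (sum(Conj(sv) * v) / sum(Conj(sv) * sv))  # project out s
  expect_lt(abs(Re(sum(Conj(sv) * v))), 1e-8)
  gvec <- bv + complex(real = rnorm(length(sv)), imaginary = rnorm(length(sv)))
  t1 <- senseIO:::.skeStatisticMatrix(cbind(gvec), bv, sv, task$sigma)
  t2 <- senseIO:::.skeStatisticMatrix(cbind(gvec + v), bv, sv, task$sigma)
  expect_lt(abs(t1 - t2), 1e-8)
  expect_error(skeBkeStatistic(g, task$bK, task$sK, 0), "sigma")
})

test_that("analytic AUC agrees with Monte-Carlo and handles edge cases", {
  task <- skeTask(h = 32, dPrimeTarget = 2)
  expect_equal(auc(skeBkeAnalyticAuc(0 * task$sK, task$mask, 1)), 0.5)
  det <- skeBkeAnalyticAuc(task$sK, task$mask, task$sigma)
  expect_equal(dPrime(det), 2, tolerance = 1e-12)
  expect_equal(auc(det), stats::pnorm(sqrt(2)), tolerance = 1e-12)

  st <- mcSkeStatistics(task, n = 10000, seed = 123)
  emp <- auc(estimateAuc(st$t0, st$t1))
  expect_lt(abs(emp - auc(det)), 0.01)
})

test_that("location uncertainty strictly degrades the ideal observer", {
  h <- 64
  coils <- uniformCoil(h)
  mask <- makeCartesianMask(h, 1)
  sel <- lineSelector(mask)
  centers <- expand.grid(r = c(24, 32, 40), c = c(24, 32, 40))
  sks <- lapply(seq_len(nrow(centers)), function(j)
    as.vector(senseIO:::.forwardArray(
      pixels(renderGaussianSignal(
        signalModel(0.7, 2, c(centers$r[j], centers$c[j])), 1, c(h, h))),
      coils, sel)))
  sigma <- sqrt(sum(Mod(sks[[1]])^2)) / 1.8   # d' = 1.8 per location
  bg <- sampleLumpyBackground(lumpyParams(shape = c(h, h)), seed = 3)
  bv <- as.vector(senseIO:::.forwardArray(pixels(bg), coils, sel))

  # degenerate mixtures reduce to the SKE statistic
  set.seed(11)
  gv <- bv + complex(real = rnorm(length(bv), 0, sigma),
                     imaginary = rnorm(length(bv), 0, sigma))
  tSke <- skeBkeStatistic(matrix(gv, h), matrix(bv, h),
                          matrix(sks[[5]], h), sigma)
  expect_equal(sksBkeStatistic(matrix(gv, h), matrix(bv, h),
                               list(matrix(sks[[5]], h)), sigma = sigma),
               tSke, tolerance = 1e-10)
  same <- replicate(4, matrix(sks[[5]], h), simplify = FALSE)
  expect_equal(sksBkeStatistic(matrix(gv, h), matrix(bv, h), same,
                               sigma = sigma), tSke, tolerance = 1e-10)

  # MC: SKS AUC strictly below matched SKE AUC (gap > 3 combined SEs)
  n <- 10000
  Smat <- do.call(cbind, sks)
  prior <- rep(1 / 9, 9)
  drawT <- function(h1, seed) {
    tSKE <- numeric(0); tSKS <- numeric(0)
    left <- n; i <- 0L
    while (left > 0) {
      m <- min(2000L, left)
      set.seed(seed + i)
      base <- bv + if (h1) sks[[5]] else 0       # SKE truth: centre location
      G <- matrix(complex(real = rnorm(length(bv) * m, 0, sigma),
                          imaginary = rnorm(length(bv) * m, 0, sigma)),
                  length(bv), m) + base
      if (h1) {  # SKS truth: random location per draw
        pick <- sample.int(9, m, replace = TRUE)
        Gs <- matrix(complex(real = rnorm(length(bv) * m, 0, sigma),
                             imaginary = rnorm(length(bv) * m, 0, sigma)),
                     length(bv), m) + bv + Smat[, pick]
      } else Gs <- G
      tSKE <- c(tSKE, senseIO:::.skeStatisticMatrix(G, bv, sks[[5]], sigma))
      tSKS <- c(tSKS, senseIO:::.sksStatisticMatrix(Gs, bv, Smat, prior, sigma))
      left <- left - m; i <- i + 1L
    }
    list(ske = tSKE, sks = tSKS)
  }
  h0 <- drawT(FALSE, 2000); h1 <- drawT(TRUE, 4000)
  aSke <- estimateAuc(h0$ske, h1$ske)
  aSks <- estimateAuc(h0$sks, h1$sks)
  gap <- auc(aSke) - auc(aSks)
  expect_gt(gap, 3 * sqrt(aucSE(aSke)^2 + aucSE(aSks)^2))

  expect_error(sksBkeStatistic(matrix(gv, h), matrix(bv, h), list(),
                               sigma = sigma), "nonempty")
  expect_error(sksBkeStatistic(matrix(gv, h), matrix(bv, h),
                               list(matrix(sks[[1]], h)),
                               prior = c(0.5, 0.7), sigma = sigma), "prior")
})

test_that("the Hotelling template converges to the matched filter and attains the Gaussian bound", {
  # iid Gaussian features, known-signal task: optimum is the matched filter
  set.seed(21)
  p <- 100; n <- 4000; sigma <- 1
  s <- rnorm(p); s <- 3 * sigma * s / sqrt(sum(s^2))   # d' = 3
  X0 <- matrix(rnorm(n * p, 0, sigma), n, p)
  X1 <- matrix(rnorm(n * p, 0, sigma), n, p) + rep(s, each = n)
  angleTo <- function(model) {
    w <- model@parameters$w
    acos(min(1, sum(w * s) / sqrt(sum(w^2) * sum(s^2)))) * 180 / pi
  }
  hotSmall <- fitHotelling(X0[1:400, ], X1[1:400, ], shrinkage = 0.5)
  hot <- fitHotelling(X0, X1, shrinkage = 0.5)
  expect_lt(angleTo(hot), 10)
  expect_lt(angleTo(hot), angleTo(hotSmall))

  # AUC attains the analytic Gaussian value within 2 combined SEs
  nv <- 2000
  V0 <- matrix(rnorm(nv * p, 0, sigma), nv, p)
  V1 <- matrix(rnorm(nv * p, 0, sigma), nv, p) + rep(s, each = nv)
  res <- estimateAuc(applyObserver(hot, V0), applyObserver(hot, V1))
  expect_lt(abs(auc(res) - stats::pnorm(3 / sqrt(2))), 2 * aucSE(res))

  # affine invariance: scaling all inputs by 10 leaves the AUC unchanged
  hot10 <- fitHotelling(10 * X0, 10 * X1, shrinkage = 0.5)
  res10 <- estimateAuc(applyObserver(hot10, 10 * V0),
                       applyObserver(hot10, 10 * V1))
  expect_equal(auc(res10), auc(res), tolerance = 1e-12)

  expect_error(fitHotelling(X0, X1[, 1:10]), "feature")
})

test_that("observer application is deterministic and rank-preserving", {
  task <- skeTask(h = 32, dPrimeTarget = 2)
  obs <- analyticObserver(task$bK, task$sK, task$sigma, mask = task$mask)
  g <- senseForward(pixels(task$bg), task$coils, task$mask,
                    noiseModel(task$sigma), seed = 31)
  t1 <- applyObserver(obs, g)
  expect_identical(t1, applyObserver(obs, g))
  expect_equal(t1, skeBkeStatistic(g, task$bK, task$sK, task$sigma),
               tolerance = 1e-12)

  # monotone transforms of a statistic never change the AUC
  set.seed(6)
  a <- rnorm(200); b <- rnorm(200) + 0.8
  expect_equal(auc(estimateAuc(stats::plogis(a), stats::plogis(b))),
               auc(estimateAuc(a, b)), tolerance = 1e-12)
})

test_that("a label-permuted CNN observer stays at chance", {
  h <- 32
  task <- skeTask(h = h, dPrimeTarget = 2.5)
  n <- 300
  sim <- function(h1, seed) {
    set.seed(seed)
    base <- task$bK + if (h1) task$sK else 0
    arr <- array(0 + 0i, c(h, h, 1, n))
    for (i in 1:n)
      arr[, , 1, i] <- base + complex(real = rnorm(h * h, 0, task$sigma),
                                      imaginary = rnorm(h * h, 0, task$sigma))
    arr
  }
  k0 <- sim(FALSE, 51); k1 <- sim(TRUE, 52)
  x <- encodeDataSpace(array(c(k0, k1), c(h, h, 1, 2 * n)))
  yTrue <- c(rep(0, n), rep(1, n))
  set.seed(99)
  yPerm <- sample(yTrue)
  v0 <- sim(FALSE, 151); v1 <- sim(TRUE, 152)
  xv <- encodeDataSpace(array(c(v0, v1), c(h, h, 1, 2 * n)))
  cfg <- cnnIoConfig(maxStages = 1, epochs = 5, seed = 4)
  mod <- trainCnnIO(list(x = x, y = yPerm), list(x = xv, y = yTrue), cfg)
  expect_gte(mod@trainingTrace$valAuc, 0.4)
  expect_lte(mod@trainingTrace$valAuc, 0.6)
  # growth-trace contract
  expect_gte(length(mod@trainingTrace$stageAuc), 1L)
  expect_identical(length(mod@trainingTrace$stageAuc),
                   length(mod@trainingTrace$stageDepth))
  expect_error(trainCnnIO(list(x = x, y = rep(0, 2 * n)),
                          list(x = xv, y = yTrue), cfg), "classes")
})
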