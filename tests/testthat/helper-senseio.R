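# Shared fixtures: all built in code, no stored data.

# A single coil with unit sensitivity everywhere (|S| = 1, zero phase).
uniformCoil <- function(h, w = h) {
  new("CoilEnsemble", maps = array(1 + 0i, c(h, w, 1L)), nCoils = 1L,
      normalized = TRUE)
}

# Standard small SKE/BKE task on an h x h grid with a single uniform coil:
# returns the k-space background/signal (full arrays), the mask, and sigma
# chosen to hit a target detectability d'.
skeTask <- function(h = 64, R = 1, dPrimeTarget = 2, bgSeed = 5,
                    center = NULL, amplitude = 0.7, sigmaMM = 2) {
  if (is.null(center)) center <- c(h / 2, h / 2)
  coils <- uniformCoil(h)
  mask <- makeCartesianMask(h, R)
  bg <- sampleLumpyBackground(lumpyParams(shape = c(h, h)), seed = bgSeed)
  sPix <- renderGaussianSignal(signalModel(amplitude, sigmaMM, center),
                               1, c(h, h))@pixels
  sK <- senseIO:::.forwardArray(sPix, coils, lineSelector(mask))
  bK <- senseIO:::.forwardArray(pixels(bg), coils, lineSelector(mask))
  sigma <- sqrt(sum(Mod(sK)^2)) / dPrimeTarget
  list(h = h, coils = coils, mask = mask, bg = bg, sPix = sPix,
       sK = sK, bK = bK, sigma = sigma)
}

# Monte-Carlo SKE/BKE test statistics: n draws per hypothesis, computed on
# the sampled-support vectors with fully simulated complex noise.
# Returns list(t0, t1).  Chunked to bound memory.
mcSkeStatistics <- function(task, n, seed, chunk = 2000L) {
  sel <- lineSelector(task$mask)
  sv <- as.vector(task$sK[sel, , , drop = FALSE])
  bv <- as.vector(task$bK[sel, , , drop = FALSE])
  p <- length(sv)
  draw <- function(base, seedOff) {
    out <- numeric(0)
    left <- n; i <- 0L
    while (left > 0L) {
      m <- min(chunk, left)
      set.seed(seed + seedOff + i)
      G <- matrix(complex(real = rnorm(p * m, 0, task$sigma),
                          imaginary = rnorm(p * m, 0, task$sigma)),
                  p, m) + base
      out <- c(out, senseIO:::.skeStatisticMatrix(G, bv, sv, task$sigma))
      left <- left - m; i <- i + 1L
    }
    out
  }
  list(t0 = draw(bv, 0L), t1 = draw(bv + sv, 500L))
}

# Simulate n magnitude rSOS reconstructions under one hypothesis for a
# fixed (BKE) background; returns (h, w, n) array.
rsosBatch <- function(bgPix, sPix, coils, mask, sigma, n, seed, h1) {
  f <- bgPix + if (h1) sPix else 0
  h <- nrow(f)
  out <- array(0, c(dim(f), n))
  noise <- noiseModel(sigma)
  for (i in seq_len(n)) {
    g <- senseForward(f, coils, mask, noise, seed = seed + i)
    out[, , i] <- pixels(reconRSOS(g))
  }
  out
}
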