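#' Simulate stylized coil-sensitivity maps
#'
#' Places \code{nCoils} receive coils at equal angles on the circle
#' circumscribing the grid.  Each map has a Gaussian magnitude falloff with
#' distance from its coil centre and a phase linear in that distance (a
#' stylization of a physical receive array, not a Biot--Savart solution).
#' With \code{normalize = TRUE} the maps are scaled pixelwise so that
#' \eqn{\sum_i |S_i(r)|^2 = 1}.
#'
#' @param nCoils number of coils (default 8).
#' @param shape integer (H, W).
#' @param profileSigmaMM Gaussian falloff width of the coil profile (mm);
#'   default three quarters of the larger grid extent.
#' @param normalize scale to unit pixelwise sum-of-squares (default TRUE).
#' @param pixelSizeMM physical pixel size (mm), default 1.
#' @param coords optional list with matrices \code{row} and \code{col} of
#'   coordinates at which to evaluate the maps instead of the pixel grid
#'   (used e.g. to check the rotational symmetry of the array).
#' @return A \linkS4class{CoilEnsemble}.
#' @examples
#' coils <- simulateCoilMaps(8, c(64, 64))
#' @export
simulateCoilMaps <- function(nCoils = 8, shape, profileSigmaMM = NULL,
                             normalize = TRUE, pixelSizeMM = 1,
                             coords = NULL) {
  nCoils <- as.integer(nCoils)
  if (nCoils < 1L) stop("nCoils must be >= 1", call. = FALSE)
  h <- shape[1L]; w <- shape[2L]
  if (is.null(profileSigmaMM)) profileSigmaMM <- 0.75 * max(h, w) * pixelSizeMM
  sigmaPx <- profileSigmaMM / pixelSizeMM
  r0 <- (h + 1) / 2; c0 <- (w + 1) / 2
  radius <- sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)  # circumscribes the grid
  if (is.null(coords)) {
    coords <- list(row = matrix(seq_len(h), h, w),
                   col = matrix(seq_len(w), h, w, byrow = TRUE))
  }
  phaseSlope <- pi / max(h, w)
  maps <- array(0 + 0i, c(h, w, nCoils))
  for (i in seq_len(nCoils)) {
    ang <- 2 * pi * (i - 1) / nCoils
    cr <- r0 + radius * sin(ang)
    cc <- c0 + radius * cos(ang)
    d <- sqrt((coords$row - cr)^2 + (coords$col - cc)^2)
    maps[, , i] <- exp(-d^2 / (2 * sigmaPx^2)) * exp(1i * phaseSlope * d)
  }
  if (normalize) {
    sos <- sqrt(apply(abs(maps)^2, c(1L, 2L), sum))
    maps <- sweep(maps, c(1L, 2L), sos, "/")
  }
  new("CoilEnsemble", maps = maps, nCoils = nCoils, normalized = normalize)
}

#' Build a Cartesian equispaced sampling mask
#'
#' Selects every \code{R}-th phase-encode line starting at \code{offset}
#' (0-based), optionally forcing the central
#' \code{ceiling(centerFraction * nLines)} lines to be acquired.  With
#' \code{offset = 0} and \code{centerFraction = 0} the masks nest across
#' acceleration factors that divide each other.
#'
#' @param nLines number of phase-encode lines (k-space rows).
#' @param R acceleration factor, \code{1 <= R <= nLines}; R = 1 selects all
#'   lines.
#' @param offset 0-based index of the first selected line.
#' @param centerFraction fraction of central lines always acquired
#'   (default 0).
#' @return A \linkS4class{SamplingMask}.
#' @examples
#' m <- makeCartesianMask(64, 4)
#' sum(lineSelector(m))  # 16
#' @export
makeCartesianMask <- function(nLines, R, offset = 0, centerFraction = 0) {
  nLines <- as.integer(nLines)
  if (R < 1 || R > nLines)
    stop("R must satisfy 1 <= R <= nLines", call. = FALSE)
  if (centerFraction < 0 || centerFraction >= 1)
    stop("centerFraction must be in [0, 1)", call. = FALSE)
  offset <- as.integer(offset)
  sel <- rep(FALSE, nLines)
  idx <- unique(as.integer(round(seq(offset + 1, nLines, by = R))))
  idx <- idx[idx >= 1L & idx <= nLines]
  sel[idx] <- TRUE
  nc <- as.integer(ceiling(centerFraction * nLines))
  if (nc > 0L) {
    mid <- floor(nLines / 2) + 1L
    lo <- mid - floor(nc / 2)
    sel[seq.int(max(1L, lo), min(nLines, lo + nc - 1L))] <- TRUE
  }
  new("SamplingMask", lineSelector = sel, acceleration = as.numeric(R),
      offset = offset, centerFraction = as.numeric(centerFraction))
}

#' Add complex Gaussian noise on sampled lines
#'
#' Adds independent \eqn{N(0, \sigma^2)} noise to the real and to the
#' imaginary part of every k-space sample on selected lines; unselected
#' lines carry no data and stay exactly zero.
#'
#' @param k complex (H, W) matrix or (H, W, C) array of k-space samples.
#' @param noise a \linkS4class{NoiseModel}.
#' @param mask a \linkS4class{SamplingMask}.
#' @param seed integer seed (identical seeds give identical noise).
#' @return Array of the same shape as \code{k}.
#' @export
addNoise <- function(k, noise, mask, seed) {
  stopifnot(is(noise, "NoiseModel"), is(mask, "SamplingMask"))
  validObject(noise)
  if (noise@sigma == 0) return(k)
  dims <- dim(k)
  sel <- mask@lineSelector
  .withSeed(seed, {
    if (length(dims) == 2L) {
      n <- sum(sel) * dims[2L]
      k[sel, ] <- k[sel, ] + complex(real = stats::rnorm(n, 0, noise@sigma),
                                     imaginary = stats::rnorm(n, 0, noise@sigma))
    } else {
      n <- sum(sel) * dims[2L] * dims[3L]
      k[sel, , ] <- k[sel, , ] + complex(real = stats::rnorm(n, 0, noise@sigma),
                                         imaginary = stats::rnorm(n, 0, noise@sigma))
    }
    k
  })
}

# Noiseless masked SENSE forward operator on a raw pixel matrix:
# per coil, S_i * f -> unitary centered 2-D DFT -> zero unselected rows.
.forwardArray <- function(fPixels, coils, selector) {
  d <- dim(coils@maps)
  out <- array(0 + 0i, d)
  for (i in seq_len(d[3L])) {
    ki <- .fft2c(coils@maps[, , i] * fPixels)
    ki[!selector, ] <- 0 + 0i
    out[, , i] <- ki
  }
  out
}

# Exact adjoint of .forwardArray: sum_i conj(S_i) * IFFT(masked g_i).
.adjointArray <- function(g, coils, selector) {
  d <- dim(coils@maps)
  out <- matrix(0 + 0i, d[1L], d[2L])
  for (i in seq_len(d[3L])) {
    gi <- g[, , i]
    gi[!selector, ] <- 0 + 0i
    out <- out + Conj(coils@maps[, , i]) * .ifft2c(gi)
  }
  out
}

#' Simulate a multi-coil SENSE acquisition
#'
#' Computes \eqn{g_i = \Phi F S_i f + n_i} for each coil: pointwise
#' multiplication by the sensitivity map, unitary DC-centered 2-D DFT,
#' zeroing of unselected phase-encode lines, and complex Gaussian noise on
#' the selected lines only.
#'
#' @param f an \linkS4class{ObjectImage} (or numeric matrix).
#' @param coils a \linkS4class{CoilEnsemble} on the same grid.
#' @param mask a \linkS4class{SamplingMask}.
#' @param noise a \linkS4class{NoiseModel}; default noiseless.
#' @param seed integer seed for the noise (required when sigma > 0).
#' @param label hypothesis label to record ("H0", "H1" or "unknown").
#' @return A \linkS4class{KspaceData}.
#' @examples
#' f <- sampleLumpyBackground(lumpyParams(), seed = 1)
#' coils <- simulateCoilMaps(8, dim(pixels(f)))
#' mask <- makeCartesianMask(64, 4)
#' g <- senseForward(f, coils, mask, noiseModel(0.5), seed = 7)
#' @export
senseForward <- function(f, coils, mask, noise = noiseModel(0), seed = NULL,
                         label = "unknown") {
  fPix <- if (is(f, "ObjectImage")) f@pixels else f
  stopifnot(is(coils, "CoilEnsemble"), is(mask, "SamplingMask"))
  d <- dim(coils@maps)
  if (!identical(dim(fPix), d[1:2]))
    stop("object and coil maps have different shapes", call. = FALSE)
  if (length(mask@lineSelector) != d[1L])
    stop("mask length must match the number of k-space rows", call. = FALSE)
  if (noise@sigma > 0 && is.null(seed))
    stop("a seed is required when noise sigma > 0", call. = FALSE)
  g <- .forwardArray(fPix, coils, mask@lineSelector)
  g <- addNoise(g, noise, mask, seed)
  new("KspaceData", samples = g, mask = mask, hypothesisLabel = label,
      noiseSigma = noise@sigma)
}

#' Adjoint of the noiseless SENSE forward operator
#'
#' Computes \eqn{\sum_i S_i^* F^{-1}(\Phi g_i)}: the exact adjoint of the
#' masked forward map, used by iterative reconstruction.
#'
#' @param g a \linkS4class{KspaceData}.
#' @param coils the \linkS4class{CoilEnsemble} used for acquisition.
#' @return A complex H x W matrix.
#' @export
senseAdjoint <- function(g, coils) {
  stopifnot(is(g, "KspaceData"), is(coils, "CoilEnsemble"))
  if (!identical(dim(g@samples), dim(coils@maps)))
    stop("k-space data and coil maps have different shapes", call. = FALSE)
  .adjointArray(g@samples, coils, g@mask@lineSelector)
}
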