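#' Sample a lumpy stochastic background
#'
#' Draws one realization of the lumpy background model: a constant DC offset
#' plus \eqn{N \sim Poisson(\bar N)} Gaussian lumps whose centres are
#' uniform over the grid.  Lumps near the border are truncated at the grid
#' edge (no wraparound).  This parametric generator stands in for a learned
#' stochastic object model of anatomy at CPU scale.
#'
#' @param params a \linkS4class{LumpyParams}.
#' @param seed integer seed; identical seeds give bitwise-identical images.
#' @param pixelSizeMM physical pixel size (mm), default 1.
#' @return An \linkS4class{ObjectImage} whose tissue mask is the central
#'   half of the grid (the default signal-placement region for this model).
#' @examples
#' bg <- sampleLumpyBackground(lumpyParams(), seed = 1)
#' @export
sampleLumpyBackground <- function(params, seed, pixelSizeMM = 1) {
  stopifnot(is(params, "LumpyParams"))
  validObject(params)
  h <- params@shape[1L]; w <- params@shape[2L]
  sigmaPx <- params@lumpSigmaMM / pixelSizeMM
  img <- .withSeed(seed, {
    n <- stats::rpois(1L, params@meanLumpCount)
    out <- matrix(params@dcOffset, h, w)
    if (n > 0L) {
      rc <- stats::runif(n, 0.5, h + 0.5)
      cc <- stats::runif(n, 0.5, w + 0.5)
      for (k in seq_len(n)) {
        out <- out + params@lumpAmplitude *
          (exp(-(seq_len(h) - rc[k])^2 / (2 * sigmaPx^2)) %o%
             exp(-(seq_len(w) - cc[k])^2 / (2 * sigmaPx^2)))
      }
    }
    out
  })
  objectImage(img, pixelSizeMM = pixelSizeMM,
              tissueMask = centralPlacementMask(c(h, w)))
}

#' Central signal-placement mask
#'
#' Logical mask covering the central half of the grid in each dimension;
#' used as the default placement region for the lumpy background model.
#'
#' @param shape integer (H, W).
#' @return Logical H x W matrix.
#' @export
centralPlacementMask <- function(shape) {
  h <- shape[1L]; w <- shape[2L]
  m <- matrix(FALSE, h, w)
  r <- seq.int(floor(h / 4) + 1L, ceiling(3 * h / 4))
  c <- seq.int(floor(w / 4) + 1L, ceiling(3 * w / 4))
  m[r, c] <- TRUE
  m
}

#' Generate a stylized 2-D brain phantom
#'
#' Builds a piecewise-smooth head phantom: an outer skull ellipse, a brain
#' ellipse, two dark ventricles and a brighter cortical rim, with geometry
#' and intensities jittered by the seed.  The returned tissue mask marks a
#' white-matter-like annulus (inside the brain, away from ventricles and
#' rim) where signals may be placed.  It is a stylization, not an
#' anatomically validated segmentation.
#'
#' @param shape integer (H, W), both at least 32.
#' @param seed integer seed.
#' @param pixelSizeMM physical pixel size (mm), default 1.
#' @return An \linkS4class{ObjectImage} with a nonempty tissue mask.
#' @examples
#' ph <- makeStylizedBrain(c(64, 64), seed = 2)
#' @export
makeStylizedBrain <- function(shape, seed, pixelSizeMM = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("shape must be (H, W) with both dimensions >= 32", call. = FALSE)
  h <- shape[1L]; w <- shape[2L]
  .withSeed(seed, {
    jit <- function(x, frac = 0.08) x * stats::runif(1L, 1 - frac, 1 + frac)
    r0 <- h / 2 + 0.5; c0 <- w / 2 + 0.5
    rr <- matrix(seq_len(h), h, w) - r0
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - c0
    ell <- function(dr, dc, ar, ac, ang = 0) {
      ca <- cos(ang); sa <- sin(ang)
      u <- (rr - dr) * ca + (cc - dc) * sa
      v <- -(rr - dr) * sa + (cc - dc) * ca
      (u / ar)^2 + (v / ac)^2 <= 1
    }
    skullAr <- jit(0.46 * h); skullAc <- jit(0.40 * w)
    ang <- stats::runif(1L, -0.15, 0.15)
    skull <- ell(0, 0, skullAr, skullAc, ang)
    brain <- ell(0, 0, 0.88 * skullAr, 0.88 * skullAc, ang)
    vAr <- jit(0.16 * h); vAc <- jit(0.06 * w)
    vOff <- jit(0.10 * w)
    vent <- ell(jit(0.02 * h, 0.5), -vOff, vAr, vAc, ang + 0.3) |
      ell(jit(0.02 * h, 0.5), vOff, vAr, vAc, ang - 0.3)
    rim <- brain & !ell(0, 0, 0.72 * skullAr, 0.72 * skullAc, ang)
    # arbitrary units; white matter ~ 28 so unit-scale noise is the usual
    # high per-pixel SNR regime of magnitude MR images
    img <- matrix(0, h, w)
    img[skull] <- jit(10.5)              # skull / CSF shell
    img[brain] <- jit(28.5)              # white matter bulk
    img[rim] <- jit(22.5)                # cortical grey rim
    img[vent] <- jit(7.5)                # ventricles (CSF)
    # gentle intensity gradient so slices are not piecewise-constant
    img <- img * (1 + 0.05 * (cc / w) + 0.05 * (rr / h))
    mask <- brain & !vent & !rim &
      !ell(0, 0, 0.30 * vAr + vAr, 0.30 * vAc + vAc, ang) # margin around ventricles
    if (!any(mask)) mask <- brain & !vent
    objectImage(img, pixelSizeMM = pixelSizeMM, tissueMask = mask)
  })
}

#' Render a Gaussian signal on a pixel grid
#'
#' Evaluates \eqn{A \exp(-\|r - r_0\|^2/(2\sigma_{px}^2))} at every pixel,
#' with \eqn{\sigma_{px}} = \code{sigmaMM / pixelSizeMM}.  Signals narrower
#' than half a pixel are rejected as unresolvable.
#'
#' @param signal a \linkS4class{SignalModel}.
#' @param pixelSizeMM physical pixel size (mm).
#' @param shape integer (H, W).
#' @return An \linkS4class{ObjectImage} holding the rendered signal.
#' @examples
#' s <- renderGaussianSignal(signalModel(center = c(32, 32)), 1, c(64, 64))
#' @export
renderGaussianSignal <- function(signal, pixelSizeMM, shape) {
  stopifnot(is(signal, "SignalModel"))
  validObject(signal)
  h <- shape[1L]; w <- shape[2L]
  if (signal@center[1L] < 1 || signal@center[1L] > h ||
      signal@center[2L] < 1 || signal@center[2L] > w)
    stop("signal center must lie inside the grid", call. = FALSE)
  sigmaPx <- signal@sigmaMM / pixelSizeMM
  if (sigmaPx < 0.5)
    stop("signal width below half a pixel cannot be represented", call. = FALSE)
  img <- signal@amplitude *
    (exp(-(seq_len(h) - signal@center[1L])^2 / (2 * sigmaPx^2)) %o%
       exp(-(seq_len(w) - signal@center[2L])^2 / (2 * sigmaPx^2)))
  objectImage(img, pixelSizeMM = pixelSizeMM)
}

#' Sample a signal location uniformly within a tissue mask
#'
#' @param mask logical matrix with at least one \code{TRUE} pixel.
#' @param seed integer seed.
#' @return Integer (row, col) of a uniformly drawn \code{TRUE} pixel.
#' @export
sampleSignalLocation <- function(mask, seed) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask has no eligible pixels", call. = FALSE)
  pick <- .withSeed(seed, idx[sample.int(length(idx), 1L)])
  c(row = ((pick - 1L) %% nrow(mask)) + 1L,
    col = ((pick - 1L) %/% nrow(mask)) + 1L)
}

#' Compose a matched signal-absent / signal-present object pair
#'
#' Returns the pair \eqn{f_{H_0}} = background and
#' \eqn{f_{H_1}} = background + rendered signal, sharing the background's
#' pixel size and tissue mask.
#'
#' @param background an \linkS4class{ObjectImage}.
#' @param signal a \linkS4class{SignalModel}.
#' @return A \linkS4class{HypothesisPair}.
#' @examples
#' bg <- sampleLumpyBackground(lumpyParams(), seed = 1)
#' hp <- composeHypothesisPair(bg, signalModel(center = c(32, 32)))
#' @export
composeHypothesisPair <- function(background, signal) {
  stopifnot(is(background, "ObjectImage"), is(signal, "SignalModel"))
  s <- renderGaussianSignal(signal, background@pixelSizeMM,
                            dim(background@pixels))
  fH1 <- objectImage(background@pixels + s@pixels,
                     pixelSizeMM = background@pixelSizeMM,
                     tissueMask = background@tissueMask)
  new("HypothesisPair", fH0 = background, fH1 = fH1, signal = signal)
}

#' Write / read an object ensemble as NIfTI
#'
#' Stores an ensemble of 2-D objects as a single 3-D NIfTI volume (H x W x
#' N) with the physical pixel size in the header; the shared tissue mask,
#' when present, is written alongside as \code{<file>_mask.nii.gz}.
#' External 2-D ensembles (e.g. from a learned object model) can be loaded
#' the same way, which is the plug-in point for replacing the parametric
#' generators.
#'
#' @param images list of \linkS4class{ObjectImage} sharing one shape.
#' @param file output path (".nii" or ".nii.gz").
#' @return \code{writeEnsemble}: the file path, invisibly.
#'   \code{readEnsemble}: a list of \linkS4class{ObjectImage}.
#' @export
writeEnsemble <- function(images, file) {
  stopifnot(length(images) > 0L, all(vapply(images, is, TRUE, "ObjectImage")))
  px <- images[[1L]]@pixelSizeMM
  arr <- vapply(images, pixels, pixels(images[[1L]]))
  nii <- RNifti::asNifti(arr, pixdim = c(px, px, 1))
  RNifti::writeNifti(nii, file)
  mask <- images[[1L]]@tissueMask
  if (!is.null(mask))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask))),
                       sub("\\.nii(\\.gz)?$", "_mask.nii.gz", file))
  invisible(file)
}

#' @rdname writeEnsemble
#' @param file input path.
#' @export
readEnsemble <- function(file) {
  nii <- RNifti::readNifti(file)
  px <- RNifti::pixdim(nii)[1L]
  if (!is.finite(px) || px <= 0) px <- 1
  arr <- as.array(nii)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  maskFile <- sub("\\.nii(\\.gz)?$", "_mask.nii.gz", file)
  mask <- NULL
  if (file.exists(maskFile)) {
    m <- as.array(RNifti::readNifti(maskFile))
    mask <- matrix(m > 0.5, dim(m)[1L], dim(m)[2L])
  }
  lapply(seq_len(dim(arr)[3L]), function(i)
    objectImage(arr[, , i], pixelSizeMM = px, tissueMask = mask))
}
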