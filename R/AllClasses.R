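#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ObjectImage: a real-valued 2-D object on a physical pixel grid
#'
#' Container for the to-be-imaged object \eqn{f}: a real-valued pixel matrix
#' with a physical pixel size in millimetres and an optional logical tissue
#' mask marking the region where signals may be placed.
#'
#' @slot pixels numeric matrix (H x W), arbitrary intensity units.
#' @slot pixelSizeMM positive scalar, physical size of one pixel in mm.
#' @slot tissueMask logical matrix of the same shape, or \code{NULL}.
#'
#' @seealso [objectImage()], [sampleLumpyBackground()], [makeStylizedBrain()]
#' @export
setClass("ObjectImage",
  representation(pixels = "matrix", pixelSizeMM = "numeric",
                 tissueMask = "matrixOrNULL"),
  prototype(pixelSizeMM = 1, tissueMask = NULL))

setValidity("ObjectImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (!all(is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  if (length(object@pixelSizeMM) != 1L || !is.finite(object@pixelSizeMM) ||
      object@pixelSizeMM <= 0)
    msg <- c(msg, "pixelSizeMM must be a positive scalar")
  if (!is.null(object@tissueMask)) {
    if (!is.logical(object@tissueMask))
      msg <- c(msg, "tissueMask must be logical")
    if (!identical(dim(object@tissueMask), dim(object@pixels)))
      msg <- c(msg, "tissueMask must have the same shape as pixels")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ObjectImage-class Constructor.
#' @param pixels numeric matrix of object intensities.
#' @param pixelSizeMM physical pixel size in mm (default 1).
#' @param tissueMask optional logical matrix marking the signal-placement
#'   region.
#' @return An \linkS4class{ObjectImage}.
#' @export
objectImage <- function(pixels, pixelSizeMM = 1, tissueMask = NULL) {
  new("ObjectImage", pixels = pixels, pixelSizeMM = as.numeric(pixelSizeMM),
      tissueMask = tissueMask)
}

#' SignalModel: a Gaussian signal to be detected
#'
#' Parameters of the rotationally symmetric Gaussian signal
#' \eqn{f_s(r) = A \exp(-\|r - r_0\|^2 / (2\sigma^2))}: amplitude, width in
#' mm, and centre in (row, col) pixel coordinates.
#'
#' @slot amplitude real amplitude \eqn{A} at the centre.
#' @slot sigmaMM positive Gaussian standard deviation in mm.
#' @slot center numeric length-2 (row, col) pixel coordinates.
#' @export
setClass("SignalModel",
  representation(amplitude = "numeric", sigmaMM = "numeric",
                 center = "numeric"))

setValidity("SignalModel", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude))
    msg <- c(msg, "amplitude must be a finite scalar")
  if (length(object@sigmaMM) != 1L || !is.finite(object@sigmaMM) ||
      object@sigmaMM <= 0)
    msg <- c(msg, "sigmaMM must be a positive scalar")
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be finite (row, col) coordinates")
  if (length(msg)) msg else TRUE
})

#' @describeIn SignalModel-class Constructor.  Defaults follow the stylized
#'   brain-lesion task: amplitude 0.7 and a 2 mm Gaussian width.
#' @param amplitude signal amplitude (default 0.7).
#' @param sigmaMM Gaussian standard deviation in mm (default 2).
#' @param center (row, col) pixel coordinates of the signal centre.
#' @return A \linkS4class{SignalModel}.
#' @export
signalModel <- function(amplitude = 0.7, sigmaMM = 2, center) {
  new("SignalModel", amplitude = as.numeric(amplitude),
      sigmaMM = as.numeric(sigmaMM), center = as.numeric(center))
}

#' LumpyParams: parameters of the lumpy stochastic background
#'
#' The lumpy background is a DC offset plus a Poisson number of Gaussian
#' lumps with centres uniform over the grid; it is the small parametric
#' stochastic object model used in place of a learned generative model of
#' anatomy.
#'
#' @slot meanLumpCount nonnegative mean of the Poisson lump count.
#' @slot lumpAmplitude real amplitude of each lump.
#' @slot lumpSigmaMM positive lump width (mm).
#' @slot shape integer length-2 grid shape (H, W).
#' @slot dcOffset real constant offset.
#' @export
setClass("LumpyParams",
  representation(meanLumpCount = "numeric", lumpAmplitude = "numeric",
                 lumpSigmaMM = "numeric", shape = "integer",
                 dcOffset = "numeric"))

setValidity("LumpyParams", function(object) {
  msg <- character()
  if (!is.finite(object@meanLumpCount) || object@meanLumpCount < 0)
    msg <- c(msg, "meanLumpCount must be >= 0")
  if (!is.finite(object@lumpAmplitude)) msg <- c(msg, "lumpAmplitude must be finite")
  if (!is.finite(object@lumpSigmaMM) || object@lumpSigmaMM <= 0)
    msg <- c(msg, "lumpSigmaMM must be > 0")
  if (length(object@shape) != 2L || any(object@shape < 1L))
    msg <- c(msg, "shape must be two positive integers")
  if (!is.finite(object@dcOffset)) msg <- c(msg, "dcOffset must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn LumpyParams-class Constructor.  Defaults give a smooth
#'   background with mean intensity near 20 (arbitrary units) on a 64 x 64
#'   grid; against unit-scale measurement noise this is the high per-pixel
#'   SNR regime of magnitude MR images, in which the default 0.7-amplitude
#'   signal is a subtle low-contrast lesion.
#' @param meanLumpCount mean Poisson lump count (default 60).
#' @param lumpAmplitude per-lump amplitude (default 8).
#' @param lumpSigmaMM per-lump Gaussian width in mm (default 4).
#' @param shape grid shape (H, W), default \code{c(64, 64)}.
#' @param dcOffset constant offset (default 10).
#' @return A \linkS4class{LumpyParams}.
#' @export
lumpyParams <- function(meanLumpCount = 60, lumpAmplitude = 8,
                        lumpSigmaMM = 4, shape = c(64L, 64L),
                        dcOffset = 10) {
  new("LumpyParams", meanLumpCount = as.numeric(meanLumpCount),
      lumpAmplitude = as.numeric(lumpAmplitude),
      lumpSigmaMM = as.numeric(lumpSigmaMM),
      shape = as.integer(shape), dcOffset = as.numeric(dcOffset))
}

#' HypothesisPair: matched signal-absent / signal-present objects
#'
#' Holds the signal-absent object \eqn{f_{H_0}}, the signal-present object
#' \eqn{f_{H_1} = f_{H_0} + f_s}, and the signal model that was added.
#'
#' @slot fH0 \linkS4class{ObjectImage}, signal absent.
#' @slot fH1 \linkS4class{ObjectImage}, signal present.
#' @slot signal \linkS4class{SignalModel}.
#' @export
setClass("HypothesisPair",
  representation(fH0 = "ObjectImage", fH1 = "ObjectImage",
                 signal = "SignalModel"))

setValidity("HypothesisPair", function(object) {
  if (!identical(dim(object@fH0@pixels), dim(object@fH1@pixels)))
    return("fH0 and fH1 must have the same shape")
  TRUE
})

#' CoilEnsemble: simulated complex coil-sensitivity maps
#'
#' The \eqn{C} complex sensitivity maps \eqn{S_i} of a stylized multi-coil
#' receive array, stored as an H x W x C complex array.  When
#' \code{normalized}, \eqn{\sum_i |S_i(r)|^2 = 1} at every pixel.
#'
#' @slot maps complex array (H, W, C).
#' @slot nCoils positive integer.
#' @slot normalized logical.
#' @seealso [simulateCoilMaps()]
#' @export
setClass("CoilEnsemble",
  representation(maps = "array", nCoils = "integer", normalized = "logical"))

setValidity("CoilEnsemble", function(object) {
  msg <- character()
  if (length(dim(object@maps)) != 3L)
    msg <- c(msg, "maps must be an (H, W, C) array")
  else if (dim(object@maps)[3L] != object@nCoils)
    msg <- c(msg, "third dimension of maps must equal nCoils")
  if (!is.complex(object@maps)) msg <- c(msg, "maps must be complex")
  else if (!all(is.finite(Re(object@maps))) || !all(is.finite(Im(object@maps))))
    msg <- c(msg, "maps must be finite")
  if (length(msg) == 0L && isTRUE(object@normalized)) {
    sos <- apply(abs(object@maps)^2, c(1L, 2L), sum)
    if (max(abs(sos - 1)) > 1e-6)
      msg <- c(msg, "normalized ensemble must satisfy sum |S_i|^2 = 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' SamplingMask: Cartesian phase-encode line selector
#'
#' Which phase-encode lines (k-space rows) are acquired.  The equispaced
#' family with offset 0 nests across acceleration factors: the lines kept at
#' R = 8 are a subset of those kept at R = 4, and so on.
#'
#' @slot lineSelector logical vector, one entry per phase-encode row.
#' @slot acceleration nominal acceleration factor R.
#' @slot offset nonnegative integer first selected line (0-based).
#' @slot centerFraction fraction of central lines always acquired.
#' @seealso [makeCartesianMask()]
#' @export
setClass("SamplingMask",
  representation(lineSelector = "logical", acceleration = "numeric",
                 offset = "integer", centerFraction = "numeric"))

setValidity("SamplingMask", function(object) {
  msg <- character()
  if (!any(object@lineSelector)) msg <- c(msg, "at least one line must be selected")
  if (object@acceleration < 1) msg <- c(msg, "acceleration must be >= 1")
  if (object@offset < 0L) msg <- c(msg, "offset must be >= 0")
  if (object@centerFraction < 0 || object@centerFraction >= 1)
    msg <- c(msg, "centerFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: complex Gaussian measurement noise
#'
#' Independent zero-mean Gaussian noise with standard deviation
#' \code{sigma} on the real and on the imaginary part of every acquired
#' k-space sample of every coil (the common simulation convention for
#' "complex Gaussian noise with standard deviation sigma").
#'
#' @slot sigma nonnegative scalar.
#' @export
setClass("NoiseModel", representation(sigma = "numeric"))

setValidity("NoiseModel", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma < 0)
    return("sigma must be a nonnegative scalar")
  TRUE
})

#' @describeIn NoiseModel-class Constructor; default sigma = 15.
#' @param sigma noise standard deviation per real/imaginary component.
#' @return A \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(sigma = 15) new("NoiseModel", sigma = as.numeric(sigma))

#' KspaceData: per-coil k-space measurement
#'
#' The measured data \eqn{g_i = \Phi F S_i f + n_i}: a complex
#' (H, W, C) array that is exactly zero on unselected phase-encode rows,
#' together with its sampling mask, noise level and hypothesis label.
#'
#' @slot samples complex array (H, W, C).
#' @slot mask \linkS4class{SamplingMask}.
#' @slot hypothesisLabel one of "H0", "H1", "unknown".
#' @slot noiseSigma noise standard deviation used in simulation.
#' @seealso [senseForward()]
#' @export
setClass("KspaceData",
  representation(samples = "array", mask = "SamplingMask",
                 hypothesisLabel = "character", noiseSigma = "numeric"))

setValidity("KspaceData", function(object) {
  msg <- character()
  d <- dim(object@samples)
  if (length(d) != 3L) msg <- c(msg, "samples must be an (H, W, C) array")
  else {
    if (d[1L] != length(object@mask@lineSelector))
      msg <- c(msg, "mask length must match the number of k-space rows")
    else {
      off <- object@samples[!object@mask@lineSelector, , , drop = FALSE]
      if (length(off) && any(off != 0 + 0i))
        msg <- c(msg, "unselected lines must be exactly zero")
    }
  }
  if (!object@hypothesisLabel %in% c("H0", "H1", "unknown"))
    msg <- c(msg, "hypothesisLabel must be H0, H1 or unknown")
  if (length(msg)) msg else TRUE
})

#' ReconImage: a reconstructed magnitude image
#'
#' @slot pixels nonnegative numeric matrix.
#' @slot methodTag identifier of the reconstruction method.
#' @slot provenance list (acceleration, noise sigma, seed, diagnostics).
#' @export
setClass("ReconImage",
  representation(pixels = "matrix", methodTag = "character",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("ReconImage", function(object) {
  if (!all(is.finite(object@pixels))) return("pixels must be finite")
  if (any(object@pixels < 0)) return("magnitude reconstruction must be nonnegative")
  TRUE
})

#' ObserverModel: a trained or analytic observer
#'
#' Any observer exposing a scalar test statistic through
#' [applyObserver()]: the analytic SKE/BKE and SKS/BKE likelihood-ratio
#' observers, the Hotelling observer, or the depth-grown CNN observer.
#'
#' @slot kind one of "analytic_ske", "analytic_sks", "hotelling", "cnn".
#' @slot parameters list of templates / mixture components / network
#'   weights.
#' @slot inputSpace "data" (k-space measurements) or "image".
#' @slot trainingTrace list of training diagnostics (may be empty).
#' @export
setClass("ObserverModel",
  representation(kind = "character", parameters = "list",
                 inputSpace = "character", trainingTrace = "list"),
  prototype(trainingTrace = list()))

setValidity("ObserverModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("analytic_ske", "analytic_sks", "hotelling", "cnn"))
    msg <- c(msg, "unknown observer kind")
  if (!object@inputSpace %in% c("data", "image"))
    msg <- c(msg, "inputSpace must be 'data' or 'image'")
  if (length(msg)) msg else TRUE
})

#' ReconModel: a small learned image-domain reconstructor
#'
#' A shallow encoder--decoder convolutional network mapping a root
#' sum-of-squares (rSOS) reconstruction to an estimate of the true object,
#' trained by mean-squared error against fully sampled references.
#'
#' @slot arch integer matrix describing the layer stack.
#' @slot theta numeric parameter vector.
#' @slot normalization list with input/output scaling constants.
#' @slot lossTrace numeric per-epoch training loss.
#' @slot config list of training settings.
#' @seealso [trainReconNet()], [applyReconNet()]
#' @export
setClass("ReconModel",
  representation(arch = "matrix", theta = "numeric", normalization = "list",
                 lossTrace = "numeric", config = "list"))

#' AnalyticDetectability: d' and the ideal-observer AUC
#'
#' For the signal-known-exactly, background-known-exactly task in complex
#' Gaussian noise the ideal observer's detectability index is
#' \eqn{d' = \|s\|/\sigma} over the sampled k-space entries and its AUC is
#' \eqn{\Phi(d'/\sqrt{2}) = 1/2 + erf(d'/2)/2}.
#'
#' @slot dPrime nonnegative detectability index.
#' @slot auc area under the ROC curve, in [0.5, 1].
#' @seealso [skeBkeAnalyticAuc()]
#' @export
setClass("AnalyticDetectability",
  representation(dPrime = "numeric", auc = "numeric"))

setValidity("AnalyticDetectability", function(object) {
  if (object@dPrime < 0) return("dPrime must be >= 0")
  if (abs(object@auc - stats::pnorm(object@dPrime / sqrt(2))) > 1e-12)
    return("auc must equal pnorm(dPrime / sqrt(2))")
  TRUE
})

#' CnnIoConfig: settings for the depth-grown CNN observer
#'
#' The CNN approximation of the ideal observer starts from a shallow
#' convolutional classifier and adds convolutional layers stage by stage
#' until validation detection performance (AUC) stops improving.
#'
#' @slot baseDepth convolutional layers in the first stage.
#' @slot growthStep layers added per stage.
#' @slot maxStages maximum number of stages.
#' @slot convergenceTol minimum validation-AUC improvement per stage.
#' @slot patience stages without improvement tolerated before stopping.
#' @slot channels convolution width (feature channels).
#' @slot epochs training epochs per stage.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam learning rate.
#' @slot seed RNG seed for initialization and shuffling.
#' @seealso [trainCnnIO()]
#' @export
setClass("CnnIoConfig",
  representation(baseDepth = "integer", growthStep = "integer",
                 maxStages = "integer", convergenceTol = "numeric",
                 patience = "integer", channels = "integer",
                 epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer"))

setValidity("CnnIoConfig", function(object) {
  msg <- character()
  if (object@convergenceTol <= 0) msg <- c(msg, "convergenceTol must be > 0")
  if (object@maxStages < 1L) msg <- c(msg, "maxStages must be >= 1")
  if (object@baseDepth < 1L) msg <- c(msg, "baseDepth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CnnIoConfig-class Constructor with CPU-scale defaults.
#' @param baseDepth,growthStep,maxStages,convergenceTol,patience growth
#'   schedule (defaults 2, 1, 5, 0.005, 1).
#' @param channels,epochs,batchSize,learningRate optimizer settings.
#' @param seed RNG seed.
#' @return A \linkS4class{CnnIoConfig}.
#' @export
cnnIoConfig <- function(baseDepth = 2, growthStep = 1, maxStages = 5,
                        convergenceTol = 0.005, patience = 1, channels = 8,
                        epochs = 8, batchSize = 64, learningRate = 2e-3,
                        seed = 1) {
  new("CnnIoConfig", baseDepth = as.integer(baseDepth),
      growthStep = as.integer(growthStep), maxStages = as.integer(maxStages),
      convergenceTol = as.numeric(convergenceTol),
      patience = as.integer(patience), channels = as.integer(channels),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), seed = as.integer(seed))
}

#' ROCCurve: empirical receiver operating characteristic
#'
#' @slot thresholds numeric thresholds in decreasing order (with +/- Inf
#'   endpoints).
#' @slot fpf false-positive fraction at each threshold.
#' @slot tpf true-positive fraction at each threshold.
#' @seealso [rocCurve()]
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", fpf = "numeric", tpf = "numeric"))

setValidity("ROCCurve", function(object) {
  msg <- character()
  n <- length(object@thresholds)
  if (length(object@fpf) != n || length(object@tpf) != n)
    msg <- c(msg, "thresholds, fpf and tpf must have equal length")
  if (any(diff(object@fpf) < -1e-12) || any(diff(object@tpf) < -1e-12))
    msg <- c(msg, "fpf and tpf must be non-decreasing along the curve")
  if (n >= 2L && (abs(object@fpf[1L]) > 1e-12 || abs(object@tpf[1L]) > 1e-12 ||
                  abs(object@fpf[n] - 1) > 1e-12 || abs(object@tpf[n] - 1) > 1e-12))
    msg <- c(msg, "curve must run from (0,0) to (1,1)")
  if (length(msg)) msg else TRUE
})

#' AUCResult: AUC point estimate with standard error
#'
#' Mann--Whitney (rank) estimate of the area under the ROC curve with the
#' Hanley--McNeil standard error.
#'
#' @slot auc estimate in [0, 1].
#' @slot se nonnegative standard error.
#' @slot nH0,nH1 class sample sizes.
#' @seealso [estimateAuc()]
#' @export
setClass("AUCResult",
  representation(auc = "numeric", se = "numeric", nH0 = "integer",
                 nH1 = "integer"))

setValidity("AUCResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
  if (object@se < 0) msg <- c(msg, "se must be >= 0")
  if (object@nH0 < 1L || object@nH1 < 1L) msg <- c(msg, "sample sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SweepReport: results of an acceleration-factor sweep
#'
#' One row per (acceleration factor, observer, input space): AUC with SE and,
#' for image-space rows, mean RMSE/SSIM of the reconstruction method.
#'
#' @slot table data.frame with columns R, observer, space, auc, se, n0, n1,
#'   rmse_mean, ssim_mean.
#' @slot config list: the sweep configuration.
#' @slot seeds integer seeds used.
#' @seealso [runAccelerationSweep()], [compareBounds()]
#' @export
setClass("SweepReport",
  representation(table = "data.frame", config = "list", seeds = "integer"))

setValidity("SweepReport", function(object) {
  need <- c("R", "observer", "space", "auc", "se", "n0", "n1")
  if (!all(need %in% names(object@table)))
    return("table must contain columns R, observer, space, auc, se, n0, n1")
  if (is.unsorted(object@table$R)) return("rows must be sorted by R")
  TRUE
})
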