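#' Accessors for senseIO objects
#'
#' Small accessor generics used across the package: pixel matrices,
#' physical pixel size, tissue masks, coil maps, sampling-line selectors and
#' AUC summaries.
#'
#' @param object a senseIO S4 object.
#' @return The slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("coilMaps", function(object) standardGeneric("coilMaps"))
#' @rdname accessors
#' @export
setGeneric("nCoils", function(object) standardGeneric("nCoils"))
#' @rdname accessors
#' @export
setGeneric("lineSelector", function(object) standardGeneric("lineSelector"))
#' @rdname accessors
#' @export
setGeneric("acceleration", function(object) standardGeneric("acceleration"))
#' @rdname accessors
#' @export
setGeneric("kspace", function(object) standardGeneric("kspace"))
#' @rdname accessors
#' @export
setGeneric("hypothesisLabel", function(object) standardGeneric("hypothesisLabel"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("aucSE", function(object) standardGeneric("aucSE"))
#' @rdname accessors
#' @export
setGeneric("dPrime", function(object) standardGeneric("dPrime"))
#' @rdname accessors
#' @export
setGeneric("sweepTable", function(object) standardGeneric("sweepTable"))

#' Apply an observer to a measurement or image
#'
#' Computes the observer's scalar test statistic.  Deterministic: the same
#' input always yields the same value.
#'
#' @param model an \linkS4class{ObserverModel}.
#' @param x a \linkS4class{KspaceData} (data-space observers), a
#'   \linkS4class{ReconImage} or numeric matrix (image-space observers), or
#'   a list of either for vectorized evaluation.
#' @param ... passed to methods.
#' @return A numeric test statistic (one value per input).
#' @export
setGeneric("applyObserver", function(model, x, ...) standardGeneric("applyObserver"))

#' @rdname accessors
#' @export
setMethod("pixels", "ObjectImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "ReconImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ObjectImage", function(object) object@pixelSizeMM)
#' @rdname accessors
#' @export
setMethod("tissueMask", "ObjectImage", function(object) object@tissueMask)
#' @rdname accessors
#' @export
setMethod("coilMaps", "CoilEnsemble", function(object) object@maps)
#' @rdname accessors
#' @export
setMethod("nCoils", "CoilEnsemble", function(object) object@nCoils)
#' @rdname accessors
#' @export
setMethod("lineSelector", "SamplingMask", function(object) object@lineSelector)
#' @rdname accessors
#' @export
setMethod("acceleration", "SamplingMask", function(object) object@acceleration)
#' @rdname accessors
#' @export
setMethod("kspace", "KspaceData", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("hypothesisLabel", "KspaceData", function(object) object@hypothesisLabel)
#' @rdname accessors
#' @export
setMethod("auc", "AUCResult", function(object) object@auc)
#' @rdname accessors
#' @export
setMethod("auc", "AnalyticDetectability", function(object) object@auc)
#' @rdname accessors
#' @export
setMethod("aucSE", "AUCResult", function(object) object@se)
#' @rdname accessors
#' @export
setMethod("dPrime", "AnalyticDetectability", function(object) object@dPrime)
#' @rdname accessors
#' @export
setMethod("sweepTable", "SweepReport", function(object) object@table)

setMethod("show", "ObjectImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ObjectImage: %d x %d pixels (%.3g mm/px), range [%.4g, %.4g]%s\n",
              d[1L], d[2L], object@pixelSizeMM, min(object@pixels),
              max(object@pixels),
              if (is.null(object@tissueMask)) "" else
                sprintf(", tissue mask: %d px", sum(object@tissueMask))))
})

setMethod("show", "CoilEnsemble", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoilEnsemble: %d coils on a %d x %d grid (%s)\n",
              object@nCoils, d[1L], d[2L],
              if (object@normalized) "SoS-normalized" else "unnormalized"))
})

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask: %d / %d lines (R = %.3g nominal, %.3g achieved)\n",
              sum(object@lineSelector), length(object@lineSelector),
              object@acceleration,
              length(object@lineSelector) / sum(object@lineSelector)))
})

setMethod("show", "KspaceData", function(object) {
  d <- dim(object@samples)
  cat(sprintf("KspaceData: %d x %d x %d coils, %d sampled lines, sigma = %.3g, label = %s\n",
              d[1L], d[2L], d[3L], sum(object@mask@lineSelector),
              object@noiseSigma, object@hypothesisLabel))
})

setMethod("show", "ObserverModel", function(object) {
  cat(sprintf("ObserverModel: kind = %s, input space = %s\n",
              object@kind, object@inputSpace))
})

setMethod("show", "AnalyticDetectability", function(object) {
  cat(sprintf("AnalyticDetectability: d' = %.4f, AUC = %.4f\n",
              object@dPrime, object@auc))
})

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("AUC = %.4f (SE %.4f; n0 = %d, n1 = %d)\n",
              object@auc, object@se, object@nH0, object@nH1))
})

setMethod("show", "SweepReport", function(object) {
  cat(sprintf("SweepReport: %d rows over R in {%s}\n",
              nrow(object@table),
              paste(sort(unique(object@table$R)), collapse = ", ")))
  print(utils::head(object@table, 12L))
  if (nrow(object@table) > 12L) cat("...\n")
})
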