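# Hotelling (optimal linear) observer on image-domain or data-domain
# feature vectors.

# Coerce observer inputs to an n x p numeric matrix.  Accepts a numeric
# matrix (rows = samples), a list of images / ReconImage / complex
# matrices, or a 3-D array (H, W, N).  Complex inputs are real-stacked:
# (Re, Im) concatenated along the feature axis.  An optional roi
# (list(rows, cols)) crops images before vectorizing.
.observerMatrix <- function(x, roi = NULL) {
  crop <- function(m) {
    if (is.null(roi)) m else m[roi$rows, roi$cols, drop = FALSE]
  }
  flatten <- function(m) {
    if (is(m, "ReconImage")) m <- m@pixels
    if (is(m, "ObjectImage")) m <- m@pixels
    m <- crop(m)
    if (is.complex(m)) c(Re(m), Im(m)) else as.numeric(m)
  }
  if (is(x, "ReconImage") || is(x, "ObjectImage") ||
      (is.complex(x) && is.matrix(x)))
    x <- list(x)
  if (is.list(x)) return(t(vapply(x, flatten, flatten(x[[1L]]))))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(t(vapply(seq_len(dim(x)[3L]), function(i) flatten(x[, , i]),
                    flatten(x[, , 1L]))))
  }
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("cannot interpret observer training input", call. = FALSE)
}

#' Fit a Hotelling observer
#'
#' Estimates the optimal linear template
#' \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)} from labelled training samples,
#' with the pooled covariance shrunk toward its diagonal:
#' \eqn{\Sigma_\alpha = (1-\alpha)\Sigma + \alpha\, diag(\Sigma)}.
#' Shrinkage keeps the solve well posed at the sample sizes used here.
#'
#' @param trainH0,trainH1 training samples per hypothesis: numeric matrix
#'   (rows = samples), list of images, or (H, W, N) array.
#' @param shrinkage shrinkage weight in [0, 1] (default 0.01).
#' @param roi optional \code{list(rows, cols)} cropping images to a region
#'   of interest before vectorizing.
#' @param inputSpace "image" (default) or "data" (real-stacked k-space).
#' @return An \linkS4class{ObserverModel} of kind \code{"hotelling"}.
#' @seealso [applyObserver()]
#' @export
fitHotelling <- function(trainH0, trainH1, shrinkage = 0.01, roi = NULL,
                         inputSpace = "image") {
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be in [0, 1]", call. = FALSE)
  X0 <- .observerMatrix(trainH0, roi)
  X1 <- .observerMatrix(trainH1, roi)
  if (ncol(X0) != ncol(X1))
    stop("training sets must share a feature dimension", call. = FALSE)
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S0 <- stats::cov(X0)
  S1 <- stats::cov(X1)
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  Ssh <- (1 - shrinkage) * Sp + shrinkage * diag(diag(Sp), ncol(Sp))
  w <- tryCatch(solve(Ssh, mu1 - mu0), error = function(e) {
    if (shrinkage == 0)
      stop("pooled covariance is singular; increase shrinkage", call. = FALSE)
    stop(e)
  })
  new("ObserverModel", kind = "hotelling",
      parameters = list(w = as.numeric(w), roi = roi,
                        shrinkage = shrinkage,
                        muDiff = mu1 - mu0),
      inputSpace = inputSpace,
      trainingTrace = list(n0 = n0, n1 = n1, dim = ncol(X0)))
}
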