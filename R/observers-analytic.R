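# Analytic ideal observers for the complex-Gaussian (BKE) data model.
#
# Under H0 the sampled data are g = b + n and under H1 g = b + s + n, with
# n independent complex Gaussian noise of standard deviation sigma per
# real/imaginary component.  The exact log-likelihood ratio is linear in g
# (SKE) or a log-sum-exp mixture over candidate signals (SKS).

# Coerce KspaceData / complex array input to a complex vector over sampled
# entries only.
.sampledVector <- function(x, mask = NULL) {
  if (is(x, "KspaceData")) {
    sel <- x@mask@lineSelector
    return(as.vector(x@samples[sel, , , drop = FALSE]))
  }
  if (is.null(mask)) return(as.vector(x))
  sel <- if (is(mask, "SamplingMask")) mask@lineSelector else mask
  if (length(dim(x)) == 3L) as.vector(x[sel, , , drop = FALSE])
  else as.vector(x[sel, , drop = FALSE])
}

#' Exact SKE/BKE likelihood-ratio test statistic
#'
#' For the signal-known-exactly, background-known-exactly task in complex
#' Gaussian noise the log-likelihood ratio is
#' \deqn{t(g) = Re\langle s, g - b\rangle / \sigma^2 - \|s\|^2 / (2\sigma^2),}
#' with the inner product over sampled k-space entries only.
#'
#' @param g measurement: \linkS4class{KspaceData} or complex array.
#' @param b known background data (same layout as \code{g}).
#' @param s known signal data (same layout).
#' @param sigma noise standard deviation per component, \code{> 0}.
#' @param mask optional \linkS4class{SamplingMask} (taken from \code{g}
#'   when it is a \linkS4class{KspaceData}).
#' @return Scalar test statistic.
#' @seealso [skeBkeAnalyticAuc()], [sksBkeStatistic()]
#' @export
skeBkeStatistic <- function(g, b, s, sigma, mask = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is(g, "KspaceData") && is.null(mask)) mask <- g@mask
  gv <- .sampledVector(g, mask)
  bv <- .sampledVector(b, mask)
  sv <- .sampledVector(s, mask)
  Re(sum(Conj(sv) * (gv - bv))) / sigma^2 - sum(Mod(sv)^2) / (2 * sigma^2)
}

# Vectorized SKE statistic: G is a complex matrix whose columns are sampled
# measurement vectors.
.skeStatisticMatrix <- function(G, bv, sv, sigma) {
  Re(crossprod(Conj(sv), G - bv))[1L, ] / sigma^2 -
    sum(Mod(sv)^2) / (2 * sigma^2)
}

#' Analytic SKE/BKE ideal-observer performance
#'
#' Closed-form detectability of the exact likelihood-ratio observer:
#' \eqn{d'^2 = \sum_k |s_k|^2 / \sigma^2} over sampled k-space entries and
#' \eqn{AUC = \Phi(d'/\sqrt{2})} (the equal-variance normal ROC area,
#' often written \eqn{1/2 + erf(d'/2)/2}).
#'
#' @param s signal data (\linkS4class{KspaceData} or complex array).
#' @param mask optional \linkS4class{SamplingMask} restricting the sum.
#' @param sigma noise standard deviation per component, \code{> 0}.
#' @return An \linkS4class{AnalyticDetectability}.
#' @examples
#' # d' = 2 gives AUC = pnorm(sqrt(2)) ~= 0.921
#' @export
skeBkeAnalyticAuc <- function(s, mask = NULL, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  sv <- .sampledVector(s, mask)
  dp <- sqrt(sum(Mod(sv)^2)) / sigma
  new("AnalyticDetectability", dPrime = dp, auc = stats::pnorm(dp / sqrt(2)))
}

#' Exact SKS/BKE mixture likelihood-ratio statistic
#'
#' Ideal observer for a signal known statistically as a discrete mixture
#' over candidate signals \eqn{s_j} with prior \eqn{p_j}:
#' \deqn{\log\Lambda(g) = \log \sum_j \exp[\log p_j +
#'   Re\langle s_j, g-b\rangle/\sigma^2 - \|s_j\|^2/(2\sigma^2)].}
#'
#' @param g measurement (\linkS4class{KspaceData} or complex array).
#' @param b known background data.
#' @param signalSet list of candidate signal data (same layout as
#'   \code{g}).
#' @param prior numeric prior over candidates, summing to one (default
#'   uniform).
#' @param sigma noise standard deviation per component.
#' @param mask optional \linkS4class{SamplingMask}.
#' @return Scalar log mixture likelihood ratio.
#' @export
sksBkeStatistic <- function(g, b, signalSet, prior = NULL, sigma,
                            mask = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  J <- length(signalSet)
  if (J == 0L) stop("signalSet must be nonempty", call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / J, J)
  if (abs(sum(prior) - 1) > 1e-8)
    stop("prior must sum to one", call. = FALSE)
  if (is(g, "KspaceData") && is.null(mask)) mask <- g@mask
  gv <- .sampledVector(g, mask)
  bv <- .sampledVector(b, mask)
  terms <- vapply(seq_len(J), function(j) {
    sv <- .sampledVector(signalSet[[j]], mask)
    log(prior[j]) + Re(sum(Conj(sv) * (gv - bv))) / sigma^2 -
      sum(Mod(sv)^2) / (2 * sigma^2)
  }, numeric(1L))
  .logSumExp(terms)
}

# Vectorized SKS statistic over measurement columns.
.sksStatisticMatrix <- function(G, bv, Smat, prior, sigma) {
  # Smat: (nSampled x J) complex; G: (nSampled x N)
  corr <- Re(t(Conj(Smat)) %*% (G - bv)) / sigma^2            # J x N
  shift <- log(prior) - colSums(Mod(Smat)^2) / (2 * sigma^2)  # J
  Z <- corr + shift
  m <- apply(Z, 2L, max)
  m + log(colSums(exp(sweep(Z, 2L, m))))
}

#' Construct an analytic observer model
#'
#' Wraps the exact SKE or SKS likelihood-ratio statistic as an
#' \linkS4class{ObserverModel} usable with [applyObserver()].
#'
#' @param b known background data (complex array, sampled layout).
#' @param s known signal (SKE) or list of candidate signals (SKS).
#' @param sigma noise standard deviation per component.
#' @param prior SKS prior (default uniform).
#' @param mask \linkS4class{SamplingMask} defining the sampled support.
#' @return An \linkS4class{ObserverModel} of kind \code{"analytic_ske"} or
#'   \code{"analytic_sks"}.
#' @export
analyticObserver <- function(b, s, sigma, prior = NULL, mask = NULL) {
  if (is.list(s)) {
    J <- length(s)
    if (is.null(prior)) prior <- rep(1 / J, J)
    new("ObserverModel", kind = "analytic_sks",
        parameters = list(b = b, signalSet = s, prior = prior, sigma = sigma,
                          mask = mask),
        inputSpace = "data")
  } else {
    new("ObserverModel", kind = "analytic_ske",
        parameters = list(b = b, s = s, sigma = sigma, mask = mask),
        inputSpace = "data")
  }
}
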