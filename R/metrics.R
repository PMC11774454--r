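#' Root-mean-square error between two images
#'
#' @param x reconstructed image (\linkS4class{ReconImage} or numeric
#'   matrix).
#' @param ref reference image (\linkS4class{ObjectImage} or numeric
#'   matrix) of the same shape.
#' @return Scalar \eqn{\sqrt{mean((x - ref)^2)}}.
#' @export
rmse <- function(x, ref) {
  xm <- if (is(x, "ReconImage")) x@pixels else x
  rm <- if (is(ref, "ObjectImage")) ref@pixels else ref
  if (!identical(dim(xm), dim(rm)))
    stop("images must have the same shape", call. = FALSE)
  sqrt(mean((xm - rm)^2))
}

# Gaussian row/column weight matrices for local (normalized) windowing.
# Joint 2-D window weights are separable, so normalizing each factor by its
# in-bounds sum gives exactly the boundary-renormalized 2-D window.
.ssimWeights <- function(n, sigma) {
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - rad):min(n, i + rad)
    w <- exp(-(j - i)^2 / (2 * sigma^2))
    W[i, j] <- w / sum(w)
  }
  W
}

#' Structural similarity index (mean SSIM)
#'
#' Mean local SSIM with a Gaussian window (truncated at three standard
#' deviations and renormalized at image borders), using the standard
#' stabilizing constants \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}.
#'
#' @param x,ref images of the same shape (\linkS4class{ReconImage} /
#'   \linkS4class{ObjectImage} or numeric matrices).
#' @param windowSigma Gaussian window standard deviation in pixels
#'   (default 1.5).
#' @param K1,K2 stabilizing constants (defaults 0.01, 0.03).
#' @param dynamicRange intensity range \eqn{L}; default
#'   \code{max(ref) - min(ref)} (falls back to 1 for constant references).
#' @return Scalar mean SSIM.
#' @export
ssim <- function(x, ref, windowSigma = 1.5, K1 = 0.01, K2 = 0.03,
                 dynamicRange = NULL) {
  xm <- if (is(x, "ReconImage")) x@pixels else x
  rm <- if (is(ref, "ObjectImage")) ref@pixels else ref
  if (!identical(dim(xm), dim(rm)))
    stop("images must have the same shape", call. = FALSE)
  if (is.null(dynamicRange)) {
    dynamicRange <- diff(range(rm))
    if (dynamicRange <= 0) dynamicRange <- 1
  }
  if (dynamicRange <= 0) stop("dynamicRange must be > 0", call. = FALSE)
  C1 <- (K1 * dynamicRange)^2
  C2 <- (K2 * dynamicRange)^2
  Wr <- .ssimWeights(nrow(xm), windowSigma)
  Wc <- .ssimWeights(ncol(xm), windowSigma)
  loc <- function(z) Wr %*% z %*% t(Wc)
  mx <- loc(xm); my <- loc(rm)
  vx <- loc(xm^2) - mx^2
  vy <- loc(rm^2) - my^2
  cxy <- loc(xm * rm) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}
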