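#' Root sum-of-squares reconstruction
#'
#' Per-coil inverse DFT of the zero-filled k-space data followed by the
#' pixelwise square root of the sum of squared magnitudes.  With a
#' SoS-normalized coil ensemble and full sampling this recovers \eqn{|f|}
#' exactly (up to noise).
#'
#' @param g a \linkS4class{KspaceData}.
#' @return A \linkS4class{ReconImage} with method tag \code{"rsos"}.
#' @export
reconRSOS <- function(g) {
  stopifnot(is(g, "KspaceData"))
  d <- dim(g@samples)
  acc <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[3L])) acc <- acc + Mod(.ifft2c(g@samples[, , i]))^2
  new("ReconImage", pixels = sqrt(acc), methodTag = "rsos",
      provenance = list(R = g@mask@acceleration, sigma = g@noiseSigma))
}

#' Conjugate-gradient SENSE reconstruction
#'
#' Solves the Tikhonov-regularized normal equations of the noiseless
#' forward model, \eqn{(A^H A + \lambda I)\, x = A^H g}, by conjugate
#' gradients on the complex image, and returns the magnitude of the
#' solution.  Non-convergence is reported in the provenance (final
#' residual), not raised.
#'
#' @param g a \linkS4class{KspaceData}.
#' @param coils the \linkS4class{CoilEnsemble} used for acquisition.
#' @param lambda Tikhonov weight, \code{>= 0} (default 0).
#' @param maxIter maximum CG iterations (default 50).
#' @param tol relative residual tolerance (default 1e-9).
#' @return A \linkS4class{ReconImage} with method tag \code{"cgsense"};
#'   \code{provenance$residuals} holds the CG residual-norm trace,
#'   \code{provenance$objective} the quadratic-objective trace (which CG
#'   decreases monotonically, unlike the residual norm), and
#'   \code{provenance$converged} the convergence flag.
#' @export
reconCgSense <- function(g, coils, lambda = 0, maxIter = 50, tol = 1e-9) {
  stopifnot(is(g, "KspaceData"), is(coils, "CoilEnsemble"),
            lambda >= 0, maxIter >= 1)
  sel <- g@mask@lineSelector
  normalOp <- function(x) .adjointArray(.forwardArray(x, coils, sel), coils, sel) +
    lambda * x
  b <- .adjointArray(g@samples, coils, sel)
  x <- matrix(0 + 0i, nrow(b), ncol(b))
  r <- b
  p <- r
  rs <- Re(sum(Conj(r) * r))
  bNorm <- sqrt(Re(sum(Conj(b) * b)))
  residuals <- numeric(0)
  objective <- numeric(0)
  if (bNorm == 0) {
    return(new("ReconImage", pixels = Mod(x), methodTag = "cgsense",
               provenance = list(R = g@mask@acceleration, sigma = g@noiseSigma,
                                 residuals = 0, objective = 0,
                                 converged = TRUE, lambda = lambda)))
  }
  for (it in seq_len(maxIter)) {
    Ap <- normalOp(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- Re(sum(Conj(r) * r))
    residuals <- c(residuals, sqrt(rsNew) / bNorm)
    # quadratic objective 1/2 x^H N x - Re(b^H x) = -(Re(b^H x) + Re(r^H x))/2
    objective <- c(objective,
                   -(Re(sum(Conj(b) * x)) + Re(sum(Conj(r) * x))) / 2)
    if (sqrt(rsNew) / bNorm < tol) break
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  new("ReconImage", pixels = Mod(x), methodTag = "cgsense",
      provenance = list(R = g@mask@acceleration, sigma = g@noiseSigma,
                        residuals = residuals, objective = objective,
                        converged = utils::tail(residuals, 1L) < tol,
                        lambda = lambda))
}
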