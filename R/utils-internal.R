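# Internal helpers: local seeding and centered unitary FFTs.

# Evaluate expr with a temporarily fixed RNG state; the caller's stream is
# untouched.  seed = NULL leaves the current stream alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed < 0)
    stop("'seed' must be a single nonnegative number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# fftshift/ifftshift for matrices (exact inverses also for odd sizes)
.fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(ceiling(d[1L] / 2)) + floor(d[1L] / 2), seq_len(floor(d[1L] / 2)))
  j <- c(seq_len(ceiling(d[2L] / 2)) + floor(d[2L] / 2), seq_len(floor(d[2L] / 2)))
  x[i, j, drop = FALSE]
}

.ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(floor(d[1L] / 2)) + ceiling(d[1L] / 2), seq_len(ceiling(d[1L] / 2)))
  j <- c(seq_len(floor(d[2L] / 2)) + ceiling(d[2L] / 2), seq_len(ceiling(d[2L] / 2)))
  x[i, j, drop = FALSE]
}

# Unitary, DC-centered 2-D DFT and its inverse.  Row index is the
# phase-encode direction; undersampling removes whole rows of k-space.
.fft2c <- function(x) {
  .fftshift2(stats::fft(.ifftshift2(x))) / sqrt(length(x))
}

.ifft2c <- function(k) {
  .fftshift2(stats::fft(.ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}

# log(sum(exp(x))) without overflow
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
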