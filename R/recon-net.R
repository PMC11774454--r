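# Small learned image-domain reconstructor: a two-resolution-level
# encoder--decoder with a global residual connection, trained to map rSOS
# reconstructions of under-sampled data to the fully sampled reference.
# It plays the role of a deep-learning reconstruction baseline at CPU
# scale; it is an analog of such methods, not a reproduction of any
# particular published network.

.reconArch <- function(width) {
  rbind(c(1L, 1L, width),      # conv 1 -> w (full resolution)
        c(2L, 0L, 0L),         # relu
        c(3L, 0L, 0L),         # pool /2
        c(1L, width, width),   # conv w -> w (half resolution)
        c(2L, 0L, 0L),         # relu
        c(4L, 0L, 0L),         # upsample x2
        c(1L, width, 1L),      # conv w -> 1
        c(6L, 0L, 0L))         # residual: add input image
}

#' Train the small learned reconstructor
#'
#' Fits the encoder--decoder to minimize mean-squared error between its
#' output on under-sampled rSOS inputs and fully sampled reference images.
#' Inputs and targets are scaled by a single constant (the mean absolute
#' reference intensity) stored on the model, so application is exactly
#' deterministic given fixed parameters.
#'
#' @param inputs list of \linkS4class{ReconImage} / numeric matrices (the
#'   under-sampled rSOS reconstructions), or an (H, W, N) array.
#' @param targets matching list or array of reference images.
#' @param width convolution width (default 12; about 3k parameters).
#' @param epochs training epochs (default 60).
#' @param batchSize minibatch size (default 16).
#' @param learningRate Adam step size (default 2e-3).
#' @param seed RNG seed for initialization and shuffling.
#' @return A \linkS4class{ReconModel}.
#' @seealso [applyReconNet()]
#' @export
trainReconNet <- function(inputs, targets, width = 12, epochs = 60,
                          batchSize = 16, learningRate = 2e-3, seed = 1) {
  x <- .asNetInput(inputs)
  tArr <- .asNetInput(targets)
  n <- dim(x)[4L]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (!identical(dim(tArr)[4L], dim(x)[4L]))
    stop("inputs and targets must match in number", call. = FALSE)
  scale <- mean(abs(tArr))
  if (!is.finite(scale) || scale < 1e-12) scale <- 1
  x <- x / scale
  y <- as.numeric(tArr / scale)          # (H, W, 1, N) values in order
  arch <- .reconArch(as.integer(width))
  storage.mode(arch) <- "integer"
  theta <- cpp_net_init(arch, as.integer(seed))
  # zero the last convolution so the residual net starts exactly at the
  # identity and learns corrections from there
  npar <- function(row) if (row[1] == 1L) row[3] * row[2] * 9L + row[3] else
    if (row[1] == 5L) row[2] + 1L else 0L
  offs <- cumsum(c(0L, apply(arch, 1L, npar)))
  lastConv <- max(which(arch[, 1L] == 1L))
  theta[(offs[lastConv] + 1L):offs[lastConv + 1L]] <- 0
  fit <- cpp_net_train(arch, theta, x, y, "mse", as.integer(epochs),
                       as.integer(batchSize), learningRate,
                       as.integer(seed) + 17L)
  new("ReconModel", arch = arch, theta = as.numeric(fit$theta),
      normalization = list(scale = scale),
      lossTrace = as.numeric(fit$loss),
      config = list(width = as.integer(width), epochs = as.integer(epochs),
                    batchSize = as.integer(batchSize),
                    learningRate = learningRate, seed = as.integer(seed)))
}

#' Apply the learned reconstructor
#'
#' Deterministic for a fixed model.  Negative outputs are clipped at zero
#' (the model reconstructs magnitude images).
#'
#' @param model a \linkS4class{ReconModel}.
#' @param g a \linkS4class{KspaceData} (rSOS is applied first), a
#'   \linkS4class{ReconImage}, or a numeric matrix.
#' @return A \linkS4class{ReconImage} with method tag \code{"net"}.
#' @export
applyReconNet <- function(model, g) {
  stopifnot(is(model, "ReconModel"))
  prov <- list()
  if (is(g, "KspaceData")) {
    prov <- list(R = g@mask@acceleration, sigma = g@noiseSigma)
    g <- reconRSOS(g)
  }
  x <- .asNetInput(g) / model@normalization$scale
  out <- cpp_net_predict(model@arch, model@theta, x, "mse")
  img <- matrix(out, dim(x)[1L], dim(x)[2L]) * model@normalization$scale
  img[img < 0] <- 0
  new("ReconImage", pixels = img, methodTag = "net", provenance = prov)
}
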