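#' Encode k-space measurements as real network channels
#'
#' Maps per-coil complex k-space data to real-valued network input
#' channels.  Each coil's zero-filled k-space is taken back to the image
#' domain by the unitary inverse DFT (an invertible, information-preserving
#' re-indexing of the raw measurement data) and split into real and
#' imaginary channels, ordered coil-major: (coil 1 Re, coil 1 Im, coil 2
#' Re, ...).  The unitary transform keeps the noise white, so observers on
#' this representation see exactly the raw-data task.
#'
#' @param g a \linkS4class{KspaceData}, a list of them, or a complex
#'   (H, W, C, N) array of k-space samples.
#' @return Numeric array (H, W, 2C, N).
#' @seealso [trainCnnIO()]
#' @export
encodeDataSpace <- function(g) {
  if (is(g, "KspaceData")) g <- list(g)
  if (is.list(g)) {
    d <- dim(g[[1L]]@samples)
    arr <- array(0 + 0i, c(d, length(g)))
    for (i in seq_along(g)) arr[, , , i] <- g[[i]]@samples
    g <- arr
  }
  d <- dim(g)
  if (length(d) != 4L) stop("expected (H, W, C, N) k-space", call. = FALSE)
  out <- array(0, c(d[1L], d[2L], 2L * d[3L], d[4L]))
  for (n in seq_len(d[4L])) {
    for (c in seq_len(d[3L])) {
      img <- .ifft2c(g[, , c, n])
      out[, , 2L * c - 1L, n] <- Re(img)
      out[, , 2L * c, n] <- Im(img)
    }
  }
  out
}

# Coerce network input to (H, W, C, N): accepts an encoded 4-D array, an
# (H, W, N) image stack, a single matrix, or a list of matrices/ReconImages.
.asNetInput <- function(x) {
  if (is.list(x) && !is(x, "KspaceData")) {
    mats <- lapply(x, function(m) {
      if (is(m, "ReconImage") || is(m, "ObjectImage")) m <- pixels(m)
      m
    })
    d <- dim(mats[[1L]])
    arr <- array(0, c(d[1L], d[2L], 1L, length(mats)))
    for (i in seq_along(mats)) arr[, , 1L, i] <- mats[[i]]
    return(arr)
  }
  if (is(x, "ReconImage") || is(x, "ObjectImage")) x <- pixels(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  d <- dim(x)
  if (length(d) == 3L) return(array(x, c(d[1L], d[2L], 1L, d[3L])))
  if (length(d) == 4L) return(x)
  stop("cannot interpret network input", call. = FALSE)
}

# Classifier layer stack: `depth` 3x3 convolutions (width `channels`) with
# ReLU, average-pooling after each convolution while the spatial size stays
# above 8, then a dense sigmoid readout.
.classifierArch <- function(h, w, cin, depth, channels) {
  rows <- list()
  ch <- cin
  for (d in seq_len(depth)) {
    rows[[length(rows) + 1L]] <- c(1L, ch, channels)   # conv
    rows[[length(rows) + 1L]] <- c(2L, 0L, 0L)         # relu
    ch <- channels
    if (min(h, w) > 8L && h %% 2L == 0L && w %% 2L == 0L) {
      rows[[length(rows) + 1L]] <- c(3L, 0L, 0L)       # pool
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  rows[[length(rows) + 1L]] <- c(5L, h * w * ch, 1L)   # dense logit
  do.call(rbind, rows)
}

# Input standardization from a training array: subtract the per-pixel
# training-mean image (removing any static background pattern, which would
# otherwise dominate the dynamic range) and divide by a per-channel scale.
.channelNorm <- function(x) {
  d <- dim(x)
  mu <- array(0, d[1:3])
  sd <- numeric(d[3L])
  for (c in seq_len(d[3L])) {
    v <- x[, , c, , drop = FALSE]
    mu[, , c] <- apply(v, c(1L, 2L), mean)
    sd[c] <- stats::sd(sweep(v[, , 1L, ], c(1L, 2L), mu[, , c]))
    if (!is.finite(sd[c]) || sd[c] < 1e-12) sd[c] <- 1
  }
  list(mu = mu, sd = sd)
}

.applyChannelNorm <- function(x, norm) {
  for (c in seq_len(dim(x)[3L]))
    x[, , c, ] <- (x[, , c, ] - as.vector(norm$mu[, , c])) / norm$sd[c]
  x
}

#' Train the depth-grown CNN approximation of the ideal observer
#'
#' Trains a convolutional classifier with a sigmoid readout and binary
#' cross-entropy loss, whose output is a monotone transform of the
#' likelihood ratio at the optimum.  Convolutional layers are added stage
#' by stage (starting from \code{baseDepth}, adding \code{growthStep} per
#' stage) and training repeats until the validation AUC improves by less
#' than \code{convergenceTol} for \code{patience} consecutive stages, or
#' \code{maxStages} is reached.  The best stage's model is returned.
#'
#' @param train,val lists with elements \code{x} (input array: encoded
#'   data-space channels from [encodeDataSpace()], or an (H, W, N) image
#'   stack) and \code{y} (0/1 labels).
#' @param config a \linkS4class{CnnIoConfig}.
#' @param inputSpace "data" or "image" (recorded on the model).
#' @return An \linkS4class{ObserverModel} of kind \code{"cnn"} whose
#'   \code{trainingTrace} holds the per-stage validation AUC and the depth
#'   at which the growth rule stopped.
#' @export
trainCnnIO <- function(train, val, config = cnnIoConfig(),
                       inputSpace = "data") {
  stopifnot(is(config, "CnnIoConfig"))
  validObject(config)
  x <- .asNetInput(train$x)
  y <- as.numeric(train$y)
  if (length(y) != dim(x)[4L]) stop("labels do not match inputs", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  if (length(y) == 0L) stop("empty training set", call. = FALSE)
  xv <- .asNetInput(val$x)
  yv <- as.numeric(val$y)
  norm <- .channelNorm(x)
  x <- .applyChannelNorm(x, norm)
  xv <- .applyChannelNorm(xv, norm)
  d <- dim(x)

  stageAuc <- numeric(0)
  stageDepth <- integer(0)
  best <- list(auc = -Inf)
  noImprove <- 0L
  for (stage in seq_len(config@maxStages)) {
    depth <- config@baseDepth + (stage - 1L) * config@growthStep
    arch <- .classifierArch(d[1L], d[2L], d[3L], depth, config@channels)
    storage.mode(arch) <- "integer"
    theta <- cpp_net_init(arch, config@seed + stage)
    # epoch-level early stopping on validation AUC: these small networks
    # overfit quickly, so the best-epoch weights are kept per stage
    epochBest <- -Inf; stale <- 0L; lossTrace <- numeric(0)
    fitTheta <- theta
    for (ep in seq_len(config@epochs)) {
      fit <- cpp_net_train(arch, theta, x, y, "bce", 1L,
                           config@batchSize, config@learningRate,
                           config@seed + 1000L * stage + ep)
      theta <- fit$theta
      lossTrace <- c(lossTrace, fit$loss)
      sc <- cpp_net_predict(arch, theta, xv, "bce")
      aucEp <- auc(estimateAuc(sc[yv == 0], sc[yv == 1]))
      if (aucEp > epochBest) {
        epochBest <- aucEp; fitTheta <- theta; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= 3L) break
      }
    }
    fit <- list(theta = fitTheta, loss = lossTrace)
    aucStage <- epochBest
    stageAuc <- c(stageAuc, aucStage)
    stageDepth <- c(stageDepth, depth)
    if (aucStage > best$auc + config@convergenceTol) {
      best <- list(auc = aucStage, arch = arch, theta = fit$theta,
                   depth = depth, loss = fit$loss)
      noImprove <- 0L
    } else {
      if (aucStage > best$auc)
        best <- list(auc = aucStage, arch = arch, theta = fit$theta,
                     depth = depth, loss = fit$loss)
      noImprove <- noImprove + 1L
      if (noImprove >= config@patience) break
    }
  }
  new("ObserverModel", kind = "cnn",
      parameters = list(arch = best$arch, theta = best$theta, norm = norm,
                        config = config),
      inputSpace = inputSpace,
      trainingTrace = list(stageAuc = stageAuc, stageDepth = stageDepth,
                           chosenDepth = best$depth, valAuc = best$auc,
                           finalLoss = utils::tail(best$loss, 1L)))
}

#' @describeIn applyObserver Test statistic of any observer model:
#'   delegates to the exact SKE/SKS likelihood-ratio formulas, the
#'   Hotelling template, or the trained network (returning the logit, a
#'   monotone transform of the estimated likelihood ratio).
#' @export
setMethod("applyObserver", signature("ObserverModel", "ANY"),
  function(model, x, ...) {
    p <- model@parameters
    switch(model@kind,
      analytic_ske = {
        xs <- if (is.list(x) && !is(x, "KspaceData")) x else list(x)
        vapply(xs, function(g)
          skeBkeStatistic(g, p$b, p$s, p$sigma, mask = p$mask), numeric(1L))
      },
      analytic_sks = {
        xs <- if (is.list(x) && !is(x, "KspaceData")) x else list(x)
        vapply(xs, function(g)
          sksBkeStatistic(g, p$b, p$signalSet, p$prior, p$sigma,
                          mask = p$mask), numeric(1L))
      },
      hotelling = {
        as.numeric(.observerMatrix(x, p$roi) %*% p$w)
      },
      cnn = {
        xin <- if (model@inputSpace == "data" &&
                   (is(x, "KspaceData") ||
                    (is.list(x) && is(x[[1L]], "KspaceData")) ||
                    is.complex(x)))
          encodeDataSpace(x) else .asNetInput(x)
        xin <- .applyChannelNorm(xin, p$norm)
        as.numeric(cpp_net_predict(p$arch, p$theta, xin, "bce"))
      },
      stop("unknown observer kind", call. = FALSE))
  })
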