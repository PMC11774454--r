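#' Configuration for an acceleration-factor sweep
#'
#' Assembles the full study configuration: phantom model, coils, noise,
#' detection task, acceleration grid, observers, reconstruction methods
#' and sample sizes.  Defaults describe the package's reference experiment:
#' a 64 x 64 grid, 8 SoS-normalized coils, a 0.7-amplitude / 2 mm Gaussian
#' signal, and noise chosen so the full-sampling ideal-observer AUC is
#' about 0.95 (sigma = 1; the physical intensity scale of the object
#' model is arbitrary, so the noise level is what fixes task difficulty).
#'
#' @param shape grid shape (H, W).
#' @param nCoils number of simulated coils.
#' @param sigma k-space noise standard deviation per component.
#' @param Rlist acceleration factors, ascending (default 1, 2, 4, 8, 12).
#' @param nTrain,nEval training/evaluation samples per hypothesis per R.
#' @param nReconTrain image pairs for training the learned reconstructor.
#' @param task "ske" (fixed signal location) or "sks" (random location
#'   among \code{sksLocations} disjoint candidates).
#' @param sksLocations number of candidate locations for "sks".
#' @param background "lumpy" or "brain".
#' @param backgroundKnown if TRUE every draw reuses one fixed background
#'   (BKE); if FALSE each draw gets a fresh background realization (BKS).
#' @param recon reconstruction methods to evaluate ("rsos", "net",
#'   "cgsense").
#' @param signalAmplitude,signalSigmaMM signal parameters.
#' @param roiHalf half-width (pixels) of the region of interest handed to
#'   image-space Hotelling observers.
#' @param shrinkage Hotelling covariance shrinkage.
#' @param netWidth,netEpochs learned-reconstructor settings.
#' @param seed master seed; the sweep is fully determined by the
#'   configuration and this seed.
#' @return A named list (class \code{"senseIOSweepConfig"}).
#' @seealso [runAccelerationSweep()]
#' @export
sweepConfig <- function(shape = c(64L, 64L), nCoils = 8, sigma = 1,
                        Rlist = c(1, 2, 4, 8, 12), nTrain = 2000,
                        nEval = 2000, nReconTrain = 96, task = "ske",
                        sksLocations = 9, background = "lumpy",
                        backgroundKnown = FALSE,
                        recon = c("rsos", "net"),
                        signalAmplitude = 0.7, signalSigmaMM = 2,
                        roiHalf = 12, shrinkage = 0.05,
                        netWidth = 12, netEpochs = 40, seed = 1) {
  cfg <- list(shape = as.integer(shape), nCoils = as.integer(nCoils),
              sigma = sigma, Rlist = sort(as.numeric(Rlist)),
              nTrain = as.integer(nTrain), nEval = as.integer(nEval),
              nReconTrain = as.integer(nReconTrain),
              task = match.arg(task, c("ske", "sks")),
              sksLocations = as.integer(sksLocations),
              background = match.arg(background, c("lumpy", "brain")),
              backgroundKnown = isTRUE(backgroundKnown),
              recon = recon, signalAmplitude = signalAmplitude,
              signalSigmaMM = signalSigmaMM, roiHalf = as.integer(roiHalf),
              shrinkage = shrinkage, netWidth = as.integer(netWidth),
              netEpochs = as.integer(netEpochs), seed = as.integer(seed))
  class(cfg) <- c("senseIOSweepConfig", "list")
  cfg
}

# Background generator closure for a configuration.
.backgroundSampler <- function(cfg) {
  if (cfg$background == "lumpy") {
    params <- lumpyParams(shape = cfg$shape)
    function(seed) sampleLumpyBackground(params, seed)
  } else {
    function(seed) makeStylizedBrain(cfg$shape, seed)
  }
}

# Candidate signal centres: the fixed SKE centre, or a 3 x 3 grid of
# disjoint locations (spacing > 6 sigma) inside the placement mask.
.signalCenters <- function(cfg, mask) {
  ctr <- sampleSignalLocation(mask, seed = cfg$seed)
  if (cfg$task == "ske") return(list(as.numeric(ctr)))
  k <- as.integer(round(sqrt(cfg$sksLocations)))
  sp <- max(8, ceiling(6 * cfg$signalSigmaMM))
  offs <- (seq_len(k) - (k + 1) / 2) * sp
  centers <- list()
  for (dr in offs) for (dc in offs)
    centers[[length(centers) + 1L]] <- as.numeric(ctr) + c(dr, dc)
  centers[seq_len(cfg$sksLocations)]
}

# Simulate n draws under one hypothesis, reconstruct with every requested
# method, and (optionally) collect per-draw truths for metrics.
.simulateReconBatch <- function(cfg, coils, mask, centers, n, hyp, seedBase,
                                bgSampler, fixedBg, netModel = NULL,
                                wantTruth = FALSE) {
  h <- cfg$shape[1L]; w <- cfg$shape[2L]
  methods <- cfg$recon
  out <- lapply(methods, function(m) array(0, c(h, w, n)))
  names(out) <- methods
  truths <- if (wantTruth) array(0, c(h, w, n)) else NULL
  noise <- noiseModel(cfg$sigma)
  for (i in seq_len(n)) {
    bg <- if (cfg$backgroundKnown) fixedBg else bgSampler(seedBase + i)
    f <- bg@pixels
    if (hyp == "H1") {
      ctr <- if (length(centers) == 1L) centers[[1L]] else
        centers[[.withSeed(seedBase + 600000L + i,
                           sample.int(length(centers), 1L))]]
      sig <- signalModel(cfg$signalAmplitude, cfg$signalSigmaMM, ctr)
      f <- f + renderGaussianSignal(sig, bg@pixelSizeMM, c(h, w))@pixels
    }
    g <- senseForward(f, coils, mask, noise, seed = seedBase + 300000L + i,
                      label = hyp)
    rs <- NULL
    for (m in methods) {
      img <- switch(m,
        rsos = { rs <- reconRSOS(g); rs },
        net = {
          if (is.null(rs)) rs <- reconRSOS(g)
          applyReconNet(netModel, rs)
        },
        cgsense = reconCgSense(g, coils, lambda = 0.01, maxIter = 15),
        stop("unknown reconstruction method: ", m))
      out[[m]][, , i] <- img@pixels
    }
    if (wantTruth) truths[, , i] <- f
  }
  list(recon = out, truth = truths)
}

#' Run an acceleration-factor sweep
#'
#' For every acceleration factor R: builds the nested equispaced mask,
#' computes the analytic data-space ideal-observer bound for the
#' signal-known-exactly task, simulates training and evaluation ensembles,
#' trains the learned reconstructor (when requested) and a Hotelling
#' observer on each reconstruction method, and estimates every observer's
#' AUC together with mean RMSE/SSIM of the reconstructions.  The whole
#' sweep is a deterministic function of the configuration.
#'
#' @param cfg a configuration from [sweepConfig()].
#' @return A \linkS4class{SweepReport}.
#' @export
runAccelerationSweep <- function(cfg) {
  stopifnot(inherits(cfg, "senseIOSweepConfig"))
  h <- cfg$shape[1L]; w <- cfg$shape[2L]
  coils <- simulateCoilMaps(cfg$nCoils, cfg$shape)
  bgSampler <- .backgroundSampler(cfg)
  fixedBg <- bgSampler(cfg$seed + 11L)
  centers <- .signalCenters(cfg, fixedBg@tissueMask)
  sigPix <- lapply(centers, function(ctr)
    renderGaussianSignal(signalModel(cfg$signalAmplitude, cfg$signalSigmaMM,
                                     ctr), 1, c(h, w))@pixels)
  roi <- {
    ctr <- round(centers[[1L]])
    list(rows = max(1, ctr[1L] - cfg$roiHalf):min(h, ctr[1L] + cfg$roiHalf),
         cols = max(1, ctr[2L] - cfg$roiHalf):min(w, ctr[2L] + cfg$roiHalf))
  }
  rows <- list()
  for (ri in seq_along(cfg$Rlist)) {
    R <- cfg$Rlist[ri]
    mask <- makeCartesianMask(h, R)
    sBase <- cfg$seed + 7919L * ri

    # analytic data-space bound (SKE/BKE ideal observer; an upper bound for
    # every observer and task variant with less knowledge)
    sK <- .forwardArray(sigPix[[1L]], coils, mask@lineSelector)
    det <- skeBkeAnalyticAuc(sK, mask = mask, sigma = cfg$sigma)
    rows[[length(rows) + 1L]] <- data.frame(
      R = R, observer = "io_bound", space = "data", auc = det@auc, se = 0,
      n0 = NA_integer_, n1 = NA_integer_, rmse_mean = NA_real_,
      ssim_mean = NA_real_)

    # learned reconstructor for this R (trained on mixed H0/H1 draws)
    netModel <- NULL
    if ("net" %in% cfg$recon) {
      nr <- cfg$nReconTrain
      cfgNoNet <- cfg; cfgNoNet$recon <- "rsos"
      b0 <- .simulateReconBatch(cfgNoNet, coils, mask, centers,
                                ceiling(nr / 2), "H0", sBase + 400000L,
                                bgSampler, fixedBg, wantTruth = TRUE)
      b1 <- .simulateReconBatch(cfgNoNet, coils, mask, centers,
                                floor(nr / 2), "H1", sBase + 450000L,
                                bgSampler, fixedBg, wantTruth = TRUE)
      xArr <- array(c(b0$recon$rsos, b1$recon$rsos), c(h, w, nr))
      tArr <- array(c(b0$truth, b1$truth), c(h, w, nr))
      netModel <- trainReconNet(xArr, tArr, width = cfg$netWidth,
                                epochs = cfg$netEpochs,
                                seed = cfg$seed + 91L * ri)
    }

    trH0 <- .simulateReconBatch(cfg, coils, mask, centers, cfg$nTrain, "H0",
                                sBase, bgSampler, fixedBg, netModel)
    trH1 <- .simulateReconBatch(cfg, coils, mask, centers, cfg$nTrain, "H1",
                                sBase + 100000L, bgSampler, fixedBg, netModel)
    evH0 <- .simulateReconBatch(cfg, coils, mask, centers, cfg$nEval, "H0",
                                sBase + 200000L, bgSampler, fixedBg, netModel)
    evH1 <- .simulateReconBatch(cfg, coils, mask, centers, cfg$nEval, "H1",
                                sBase + 250000L, bgSampler, fixedBg, netModel,
                                wantTruth = TRUE)

    for (m in cfg$recon) {
      hot <- fitHotelling(trH0$recon[[m]], trH1$recon[[m]],
                          shrinkage = cfg$shrinkage, roi = roi)
      t0 <- applyObserver(hot, evH0$recon[[m]])
      t1 <- applyObserver(hot, evH1$recon[[m]])
      res <- estimateAuc(t0, t1)
      mets <- vapply(seq_len(cfg$nEval), function(i) {
        ref <- evH1$truth[, , i]
        img <- evH1$recon[[m]][, , i]
        c(rmse(img, ref), ssim(img, ref))
      }, numeric(2L))
      rows[[length(rows) + 1L]] <- data.frame(
        R = R, observer = paste0("hotelling_", m), space = "image",
        auc = res@auc, se = res@se, n0 = res@nH0, n1 = res@nH1,
        rmse_mean = mean(mets[1L, ]), ssim_mean = mean(mets[2L, ]))
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$R), ]
  rownames(tab) <- NULL
  new("SweepReport", table = tab, config = unclass(cfg),
      seeds = cfg$seed)
}

#' Compare image-space observer performance against the data-space bound
#'
#' For every acceleration factor: the gap between the analytic data-space
#' bound and each image-space observer's AUC, with the combined standard
#' error; gaps below \code{-nSE} standard errors are flagged as bound
#' violations.  Also juxtaposes the RMSE/SSIM ordering of reconstruction
#' methods against their AUC ordering and flags discordances (a method
#' better on traditional metrics but not on the detection task).
#'
#' @param report a \linkS4class{SweepReport} containing an
#'   \code{io_bound} row per R.
#' @param nSE violation threshold in combined standard errors (default 2).
#' @return A list with elements \code{gaps} (data.frame: R, observer, gap,
#'   se, violation) and \code{ordering} (data.frame per R comparing
#'   methods on rmse/ssim/auc, with a \code{discordant} flag).
#' @export
compareBounds <- function(report, nSE = 2) {
  stopifnot(is(report, "SweepReport"))
  tab <- report@table
  gaps <- NULL
  ordering <- NULL
  for (R in sort(unique(tab$R))) {
    sub <- tab[tab$R == R, ]
    bnd <- sub[sub$observer == "io_bound", ]
    if (nrow(bnd) != 1L)
      stop("report lacks a data-space bound row at R = ", R, call. = FALSE)
    img <- sub[sub$space == "image", ]
    if (nrow(img)) {
      gaps <- rbind(gaps, data.frame(
        R = R, observer = img$observer,
        gap = bnd$auc - img$auc,
        se = img$se,
        violation = (bnd$auc - img$auc) < -nSE * img$se))
    }
    if (nrow(img) >= 2L) {
      for (a in seq_len(nrow(img) - 1L)) for (b in (a + 1L):nrow(img)) {
        better_rmse <- img$rmse_mean[b] < img$rmse_mean[a]
        better_ssim <- img$ssim_mean[b] > img$ssim_mean[a]
        seAB <- sqrt(img$se[a]^2 + img$se[b]^2)
        better_auc <- img$auc[b] > img$auc[a] + nSE * seAB
        ordering <- rbind(ordering, data.frame(
          R = R, reference = img$observer[a], method = img$observer[b],
          better_rmse = better_rmse, better_ssim = better_ssim,
          better_auc = better_auc,
          discordant = (better_rmse || better_ssim) && !better_auc))
      }
    }
  }
  list(gaps = gaps, ordering = ordering)
}

#' Write a sweep report to CSV / JSON
#'
#' @param report a \linkS4class{SweepReport}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.  Writes \code{sweep_report.csv} and a
#'   structured \code{sweep_log.json} with the configuration and seeds.
#' @export
writeSweepReport <- function(report, dir) {
  stopifnot(is(report, "SweepReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report@table, file.path(dir, "sweep_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = report@config, seeds = report@seeds,
         rVersion = as.character(getRversion()),
         package = as.character(utils::packageVersion("senseIO"))),
    file.path(dir, "sweep_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
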