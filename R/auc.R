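#' Mann--Whitney AUC estimate with standard error
#'
#' Two-sample rank estimator of the area under the ROC curve (ties counted
#' one half), with the Hanley--McNeil standard error computed from the rank
#' statistic.  The estimate is invariant under any strictly monotone
#' transform of the statistics.
#'
#' @param tH0 test statistics under the signal-absent hypothesis.
#' @param tH1 test statistics under the signal-present hypothesis.
#' @return An \linkS4class{AUCResult}.
#' @examples
#' estimateAuc(c(0, 1), c(2, 3))  # AUC = 1
#' @export
estimateAuc <- function(tH0, tH1) {
  n0 <- length(tH0); n1 <- length(tH1)
  if (n0 == 0L || n1 == 0L)
    stop("both hypothesis samples must be nonempty", call. = FALSE)
  r <- rank(c(tH0, tH1))  # midranks handle ties at one half
  a <- (sum(r[(n0 + 1L):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
    (n0 * n1)
  new("AUCResult", auc = a, se = sqrt(max(v, 0)), nH0 = as.integer(n0),
      nH1 = as.integer(n1))
}

#' Empirical ROC curve
#'
#' FPF/TPF at every distinct statistic value, swept from high thresholds
#' (nothing called positive) to low, with infinite-threshold endpoints so
#' the curve runs from (0, 0) to (1, 1).  Its trapezoidal area equals the
#' Mann--Whitney estimate.
#'
#' @inheritParams estimateAuc
#' @return A \linkS4class{ROCCurve}.
#' @export
rocCurve <- function(tH0, tH1) {
  if (length(tH0) == 0L || length(tH1) == 0L)
    stop("both hypothesis samples must be nonempty", call. = FALSE)
  thr <- c(Inf, sort(unique(c(tH0, tH1)), decreasing = TRUE), -Inf)
  fpf <- vapply(thr, function(t) mean(tH0 >= t), numeric(1L))
  tpf <- vapply(thr, function(t) mean(tH1 >= t), numeric(1L))
  new("ROCCurve", thresholds = thr, fpf = fpf, tpf = tpf)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve an \linkS4class{ROCCurve}.
#' @return Scalar area.
#' @export
trapezoidAuc <- function(curve) {
  stopifnot(is(curve, "ROCCurve"))
  sum(diff(curve@fpf) * (utils::head(curve@tpf, -1L) +
                           utils::tail(curve@tpf, -1L)) / 2)
}

#' Bootstrap cross-check of the AUC standard error
#'
#' Seeded nonparametric bootstrap over both samples; provided as an
#' optional check on the closed-form rank-based standard error.
#'
#' @inheritParams estimateAuc
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return Bootstrap standard error of the AUC.
#' @export
bootstrapAucSE <- function(tH0, tH1, nBoot = 1000, seed = 1) {
  .withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      b0 <- sample(tH0, replace = TRUE)
      b1 <- sample(tH1, replace = TRUE)
      auc(estimateAuc(b0, b1))
    }, numeric(1L))
    stats::sd(reps)
  })
}
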