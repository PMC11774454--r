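#' @useDynLib senseIO, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm rnorm runif rpois sd cov
#' @importFrom utils head tail write.csv
NULL
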