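#' @useDynLib ramanscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois mad runmed approx quantile sd predict
#' @importFrom utils head tail combn
NULL

utils::globalVariables(c("fpr", "tpr", "lo", "hi", "pc", "evf", "auroc"))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoid area under a sampled curve
#'
#' @param x ordinate (strictly increasing).
#' @param y sampled values, same length as `x`.
#' @return The trapezoid-rule integral of `y` over `x`.
#' @keywords internal
trapz_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Deterministic 32-bit sub-seed so stages / lesions / replicates each get an
# independent, reproducible stream derived from one root seed.
child_seed <- function(seed, index, stream = 0L) {
  s <- ((as.numeric(seed) %% 65521) * 30011 +
          as.numeric(index) * 127 + as.numeric(stream) * 7919) %% 2147483647
  as.integer(s)
}

stop_rs <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ramanscreen_error")))
}
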