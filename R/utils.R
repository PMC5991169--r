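#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif fft pt sd quantile median convolve
#' @importFrom utils head tail
NULL

# Derive a reproducible 31-bit sub-seed from a master seed and an index.
# Keeps every seed handed to set.seed() inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_painlep <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
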