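#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif cor quantile ecdf predict sd
#' @importFrom utils head tail
NULL

# sample() misbehaves on length-1 numeric x; always index-sample.
resample <- function(x, size, replace = FALSE) {
  if (length(x) == 0L && size == 0L) return(x[0])
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_po2go <- function(msg, class) {
  abort(msg, class = c(class, "po2go_error"))
}

# Deterministic evaluation under a local RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
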