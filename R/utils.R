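#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats quantile rnorm runif var
#' @importFrom utils head tail
NULL

# Run code under a temporary RNG state; restores the caller's state afterwards.
# All stochastic operations in the package funnel through this so that no
# global random state leaks between calls.
withSeed <- function(seed, code) {
  if (!is.null(get0(".Random.seed", envir = globalenv()))) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty detection table with canonical column types
emptyDetDF <- function() {
  data.frame(frame_index = integer(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0), confidence = numeric(0))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
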