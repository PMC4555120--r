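#' @useDynLib vkorcp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize rgamma runif rnorm qgamma pgamma setNames
#' @importFrom utils write.table head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset) * 131L) %% 2147483587L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
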