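#' @keywords internal
#' @importFrom stats median sd var cor lm coef residuals fitted p.adjust
#'   rnorm runif wilcox.test nls nls.control
#' @importFrom utils read.delim write.table combn
#' @importFrom graphics abline lines text
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points funnel through this so that a single integer
# seed reproduces a study bit-for-bit (Mersenne-Twister, R default stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ss <- function(...) stop(..., call. = FALSE)

# sample coefficient of variation, n-1 denominator
cv <- function(x) stats::sd(x) / mean(x)
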