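# Internal helpers shared across modules.

#' @importFrom stats rnorm qnorm sd var dgamma rgamma pt fft mvfft
#' @importFrom utils read.csv write.csv
NULL

MAX_SEED <- 2147483646L

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  All randomness in the package flows through
# this so that independent seed streams never interfere.
with_seed <- function(seed, expr) {
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

# Deterministically derive `n` sub-seeds from a master seed.  Sub-seeds are
# drawn without replacement from 1..MAX_SEED so every derived seed fits in a
# 32-bit integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(MAX_SEED, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
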