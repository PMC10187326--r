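#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor fft median pnorm qnorm quantile rnorm runif sd var
#' @importFrom utils head modifyList tail
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stage-specific 31-bit seed from a global seed and a stage label,
# so stages re-run in isolation reproduce their in-pipeline draws.
derive_seed <- function(seed, stage) {
  bytes <- utf8ToInt(paste0(stage, ":", as.integer(seed)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
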