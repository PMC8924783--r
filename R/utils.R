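#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif rbinom rlnorm rpois sd quantile setNames
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 69069 + 12345 * as.double(k)) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
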