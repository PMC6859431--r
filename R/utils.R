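# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input.
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf, or an Inf dominates
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b. Used by the injective-placement sums,
# where positivity of the underlying quantity is guaranteed analytically.
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a == -Inf || b > a) {
    # only reachable through catastrophic cancellation; treat as log(0)
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

# Two-sided normal p-value; kept > 0 by clamping at the smallest
# representable double so downstream (0, 1] validation holds.
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Two-sided normal p-value on the log10 scale, finite far below the
# double-precision underflow point.
log10_two_sided_p <- function(z) {
  pmin((stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10), 0)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL evaluates the code against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
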