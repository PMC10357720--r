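# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
softplus <- function(x) {
  # numerically stable log(1 + exp(x)); keeps simulated expression positive
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

log2p1 <- function(x) log2(x + 1)

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG state is untouched.  All stochastic functions in the package route
# through this so that a single explicit seed argument gives bit-identical
# results regardless of what the session did before.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Counter-based seed derivation: child streams (per cohort, per member, per
# stage) come from fixed arithmetic on the master seed, so adding streams never
# perturbs existing ones and results do not depend on execution order.
derive_seed <- function(master, index, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid 32-bit integers
  s <- (abs(master) %% m) + 104729 * (stream %% 1000L) + 7919 * (index %% 100000L)
  as.integer(s %% m) + 1L
}

# sample() helper immune to the length-1 "convenience" behaviour
sample_exact <- function(x, size) {
  if (length(x) == 1L) {
    if (size == 1L) return(x)
    stop("cannot sample ", size, " items from a pool of 1")
  }
  sample(x, size)
}

stop_pu <- function(...) stop(..., call. = FALSE)
warn_pu <- function(...) warning(..., call. = FALSE)
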