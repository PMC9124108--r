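#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans predict rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic package internals go
# through this so that a run never perturbs (or depends on) the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Each pipeline stage (feature selection, model initialization, parameter
#' tuning, resampling) consumes its own RNG stream whose seed is a pure
#' function of the master seed and the stage name.  Stages therefore never
#' consume each other's random numbers, and any stage can be re-run in
#' isolation.
#'
#' @param master single integer master seed.
#' @param stage character stage label, e.g. `"fs"` or `"tune"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "fs")
#' derive_seed(42, "tune")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master),
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(master) %% 1048576) * 2039 + h) %% 2147483646L
}

# Clip a numeric vector/matrix to [lo, hi] elementwise (recycled bounds).
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half-up to `digits` decimals (display convention for percent metrics;
# base round() rounds half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Minimum-norm least-squares solution of X b = y (handles rank deficiency).
lsq_minnorm <- function(X, y) {
  drop(MASS::ginv(X) %*% y)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
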