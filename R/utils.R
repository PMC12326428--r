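#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#' A `NULL` seed evaluates `code` with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent per-stage seeds from one master seed
#'
#' Deterministically spawns `n` sub-seeds so pipeline stages draw from
#' decoupled streams; all spawned seeds fit in a 32-bit signed integer.
#'
#' @param seed Master integer seed (or `NULL`, which propagates `NULL`s).
#' @param n Number of seeds to spawn.
#' @return Integer vector of length `n` (or list of `NULL`s).
#' @export
#' @examples
#' spawn_seeds(1, 3)
spawn_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Running mean with window `width` samples, truncated at the edges.
# For even widths the window is centred-left: floor((width-1)/2) samples
# before, the rest at and after the index.
running_mean <- function(x, width) {
  stopifnot(width >= 1)
  n <- length(x)
  left <- floor((width - 1) / 2)
  right <- width - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Equal-tailed quantile interval using type-5 (midpoint) interpolation,
# matching h = n*p + 0.5 linear-interpolation quantiles.
eqtail_interval <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, type = 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
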