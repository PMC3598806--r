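# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees to the interval (-180, 180]
#' @param x numeric vector of angles, degrees.
#' @return wrapped angles, degrees.
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream; all stochastic generators route through this so that they are
# pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
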