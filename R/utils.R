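# Internal helpers shared across the package.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so library internals never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Half-up rounding to integer (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_point2 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stopf("'%s' must be a finite numeric 2-vector", name)
  as.numeric(x)
}

# Coerce points to an n x 2 numeric matrix (x, y in visual-field degrees).
as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L)
      stopf("points must be a 2-vector or an n x 2 matrix")
    points <- matrix(as.numeric(points), 1L, 2L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("points must have two columns (x, y)")
  storage.mode(points) <- "double"
  points
}
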