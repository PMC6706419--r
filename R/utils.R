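## Internal helpers shared across modules.

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Normalise rows of an n x 3 matrix to unit length.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite scalar in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

## Uniformly random 3x3 rotation matrix (uses current RNG stream).
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-12) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
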