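# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without clobbering the
# session stream.
with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed as
#' `exp(mean(log(x)))`. Used to pool replicate regulatory LD50 point
#' estimates, which vary multiplicatively.
#'
#' @param x Numeric vector of strictly positive values.
#' @return A single numeric value.
#' @examples
#' geometric_mean(c(1, 4)) # 2
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    abort("geometric_mean() requires a non-empty vector of positive finite values")
  }
  exp(mean(log(x)))
}

# TRUE if x is a single finite number.
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
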