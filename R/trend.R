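# Mann-Kendall monotonic trend test (tie-corrected, normal approximation
# with continuity correction) and response-ratio fold changes.

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in an annual series.
#' `S` is the sum of signs of all pairwise differences taken forward in
#' time; its variance carries the standard tie correction
#' `var(S) = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18` over tie groups of
#' size `t`. The reported `tau` is the tie-corrected rank correlation
#' (tau-b). The two-sided p-value uses the normal approximation with a
#' continuity correction (`S` shrunk toward zero by one).
#'
#' A constant series has no defined trend direction: `tau` and `p_value`
#' are `NA` and the result is flagged `undefined`.
#'
#' @param x Numeric series in time order, length >= 4, finite values.
#' @return One-row tibble `n`, `S`, `var_S`, `tau`, `p_value`,
#'   `undefined`.
#' @export
mann_kendall <- function(x) {
  if (!is.numeric(x) || length(x) < 4) {
    abort("mann_kendall() needs a numeric series of length >= 4")
  }
  if (any(!is.finite(x))) abort("series values must be finite")
  n <- length(x)
  d <- sign(outer(x, x, `-`)) # d[j, i] = sign(x_j - x_i)
  S <- sum(d[lower.tri(d)]) # over pairs i < j: sign(x_j - x_i)
  ties <- table(x)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
    sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  D0 <- n * (n - 1) / 2
  Tx <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((D0 - Tx) * D0)
  if (denom == 0 || var_S == 0) {
    return(tibble(
      n = n, S = S, var_S = var_S, tau = NA_real_, p_value = NA_real_,
      undefined = TRUE
    ))
  }
  tau <- S / denom
  z <- if (S == 0) 0 else (S - sign(S)) / sqrt(var_S)
  p <- min(1, 2 * pnorm(-abs(z)))
  tibble(n = n, S = S, var_S = var_S, tau = tau, p_value = p, undefined = FALSE)
}

#' Response-ratio fold change
#'
#' `fold_change(v0, v1)` returns `v1 / v0`, the response ratio between an
#' end and a start value: 1 means no change, 3 a tripling, 0.3 a 70%
#' decline. A non-positive or missing baseline yields `NA` (undefined),
#' never infinity. Vectorized.
#'
#' @param v0 Baseline value(s), expected > 0.
#' @param v1 End value(s).
#' @return Numeric vector of ratios with `NA` where undefined.
#' @export
fold_change <- function(v0, v1) {
  out <- ifelse(!is.na(v0) & v0 > 0, v1 / v0, NA_real_)
  as.numeric(out)
}
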