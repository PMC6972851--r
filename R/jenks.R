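# Fisher-Jenks natural-breaks classification: exact dynamic program over
# the sorted distinct values (weighted by multiplicity, so tied values can
# never be split across classes), plus a zero-centered variant for change
# maps.

# Weighted within-block sum of squared deviations for distinct values
# v[i..j] with counts w[i..j], via prefix sums.
block_ssd_fun <- function(v, w) {
  cw <- cumsum(w)
  cwv <- cumsum(w * v)
  cwv2 <- cumsum(w * v^2)
  p <- function(x, i) if (i == 0) 0 else x[i]
  function(i, j) {
    sw <- p(cw, j) - p(cw, i - 1)
    swv <- p(cwv, j) - p(cwv, i - 1)
    swv2 <- p(cwv2, j) - p(cwv2, i - 1)
    swv2 - swv^2 / sw
  }
}

# Optimal contiguous partition of m distinct values into k classes.
# Returns the class index of each distinct value and the minimal SSD.
jenks_partition <- function(v, w, k) {
  m <- length(v)
  ssd <- block_ssd_fun(v, w)
  cost <- matrix(Inf, m, k) # cost[j, kk]: best SSD for v[1..j] in kk classes
  back <- matrix(0L, m, k)
  for (j in seq_len(m)) cost[j, 1] <- ssd(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:m) {
        for (s in (kk - 1):(j - 1)) { # last class is v[(s+1)..j]
          cand <- cost[s, kk - 1] + ssd(s + 1, j)
          if (cand < cost[j, kk]) {
            cost[j, kk] <- cand
            back[j, kk] <- s
          }
        }
      }
    }
  }
  bounds <- integer(k) # upper index of each class
  j <- m
  for (kk in k:1) {
    bounds[kk] <- j
    j <- if (kk > 1) back[j, kk] else 0L
  }
  classes <- rep(seq_len(k), times = diff(c(0L, bounds)))
  list(classes = classes, ssd = cost[m, k], bounds = bounds)
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher-Jenks optimization: partitions the sorted values into `k`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations from the class means. The dynamic program runs over distinct
#' values weighted by multiplicity, so equal values always land in the
#' same class. Deterministic.
#'
#' @param values Finite numeric vector.
#' @param k Number of classes, `1 <= k <=` number of distinct values.
#' @return Object of class `jenks_breaks`: list with `k`, `breaks`
#'   (length `k + 1`: minimum, the class maxima), `assignment` (class
#'   index per input value, input order), `gvf` (goodness of variance
#'   fit, `1 - SSD_within / SSD_total`) and `ssd`.
#' @export
jenks_breaks <- function(values, k) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric")
  }
  if (!is_scalar_number(k) || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer")
  }
  k <- as.integer(k)
  tab <- sort(unique(values))
  if (k > length(tab)) {
    abort("`k` exceeds the number of distinct values")
  }
  w <- as.numeric(table(factor(values, levels = tab)))
  part <- jenks_partition(tab, w, k)
  total <- block_ssd_fun(tab, w)(1, length(tab))
  assignment <- part$classes[match(values, tab)]
  structure(
    list(
      k = k,
      breaks = c(tab[1], tab[part$bounds]),
      assignment = assignment,
      ssd = part$ssd,
      gvf = if (total > 0) 1 - part$ssd / total else 0
    ),
    class = "jenks_breaks"
  )
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(
    "<jenks_breaks> k = ", x$k, ", gvf = ", signif(x$gvf, 4),
    "\n  breaks: ", paste(signif(x$breaks, 5), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Zero-centered natural breaks for change values
#'
#' Variant used for change maps: negative and non-negative values are
#' classified separately with a forced class boundary at zero, with the
#' class budget split between the two sides in proportion to their share
#' of the values (at least one class per side). If the input is
#' one-signed the function falls back to plain [jenks_breaks()] with a
#' warning.
#'
#' @param values Finite numeric vector containing (ordinarily) both
#'   negative and non-negative entries.
#' @param k Total number of classes, `k >= 2`.
#' @return A `jenks_breaks` object whose `breaks` include zero; class
#'   indices run from the most negative class upward.
#' @export
zero_centered_breaks <- function(values, k) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric")
  }
  if (!is_scalar_number(k) || k < 2 || k != round(k)) {
    abort("`k` must be an integer >= 2")
  }
  neg <- values[values < 0]
  pos <- values[values >= 0]
  if (length(neg) == 0 || length(pos) == 0) {
    warn("values are one-signed; falling back to plain jenks_breaks()")
    return(jenks_breaks(values, k))
  }
  k_neg <- round(k * length(neg) / length(values))
  k_neg <- max(1L, min(k - 1L, as.integer(k_neg)))
  k_neg <- min(k_neg, length(unique(neg)))
  k_pos <- min(k - k_neg, length(unique(pos)))
  bn <- jenks_breaks(neg, k_neg)
  bp <- jenks_breaks(pos, k_pos)
  assignment <- integer(length(values))
  assignment[values < 0] <- bn$assignment
  assignment[values >= 0] <- bp$assignment + k_neg
  breaks <- unique(c(
    bn$breaks[1], head(bn$breaks[-1], -1), 0, bp$breaks[-1]
  ))
  ssd <- bn$ssd + bp$ssd
  tab <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = tab)))
  total <- block_ssd_fun(tab, w)(1, length(tab))
  structure(
    list(
      k = k_neg + k_pos, breaks = breaks, assignment = assignment,
      ssd = ssd, gvf = if (total > 0) 1 - ssd / total else 0
    ),
    class = "jenks_breaks"
  )
}
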