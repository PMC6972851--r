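# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: enumeration and first-principles formulas only.

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Mann-Kendall S statistic by direct pair counting.
mk_S <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) s <- s + sign(x[j] - x[i])
  }
  s
}

# Exact two-sided permutation p-value of the Mann-Kendall test: the
# probability under random ordering of the observed multiset that |S| is
# at least as large as observed.
mk_exact_p <- function(x) {
  perms <- all_perms(length(x))
  s_obs <- abs(mk_S(x))
  s_all <- apply(perms, 1, function(idx) abs(mk_S(x[idx])))
  mean(s_all >= s_obs)
}

# Exhaustive Fisher-Jenks: enumerate every contiguous partition of the
# sorted distinct values into k classes and return the minimal total
# within-class SSD (ties in values weighted by multiplicity).
jenks_oracle <- function(values, k) {
  v <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = v)))
  m <- length(v)
  ssd_block <- function(i, j) {
    x <- rep(v[i:j], times = w[i:j])
    sum((x - mean(x))^2)
  }
  best <- NULL
  cuts <- if (k == 1) matrix(integer(0), 1, 0) else t(utils::combn(m - 1, k - 1))
  for (r in seq_len(nrow(cuts))) {
    bounds <- c(cuts[r, ], m)
    starts <- c(1, head(bounds, -1) + 1)
    ssd <- sum(mapply(ssd_block, starts, bounds))
    if (is.null(best) || ssd < best$ssd - 1e-12) {
      best <- list(ssd = ssd, breaks = c(v[1], v[bounds]))
    }
  }
  best
}

# Brute-force Ward agglomeration: at every step evaluate the true
# increase in within-cluster sum of squares for every cluster pair from
# the raw members and merge the minimum (first minimal pair in order).
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) i)
  ids <- -seq_len(n)
  merges <- list()
  delta_sse <- function(a, b) {
    xa <- x[a, , drop = FALSE]
    xb <- x[b, , drop = FALSE]
    sse <- function(m) {
      if (nrow(m) == 1) return(0)
      sum(sweep(m, 2, colMeans(m))^2)
    }
    sse(rbind(xa, xb)) - sse(xa) - sse(xb)
  }
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- delta_sse(clusters[[i]], clusters[[j]])
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    merges[[step]] <- list(
      left = ids[best$i], right = ids[best$j],
      height = sqrt(2 * best$d)
    )
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  merges
}
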