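# Hierarchical clustering of regional toxic-load trajectories:
# fold-change normalization, Ward agglomeration (Euclidean distance,
# Lance-Williams recurrence on squared distances) with a deterministic tie
# rule, and Newick export.

#' Normalize a series to fold change relative to its first value
#'
#' Divides every value by the first one, so series that differ by orders
#' of magnitude in absolute level become comparable trajectories (the
#' first value is always 1). Idempotent.
#'
#' @param x Numeric series; `x[1]` must be > 0.
#' @return Numeric series of the same length starting at 1.
#' @export
normalize_series <- function(x) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    abort("`x` must be a finite numeric series")
  }
  if (x[1] <= 0) abort("first-year value must be > 0 to normalize")
  x / x[1]
}

#' Ward hierarchical clustering of time series
#'
#' Agglomerative clustering of the rows of `x` using Euclidean distances
#' and Ward's minimum-variance criterion, implemented via the
#' Lance-Williams recurrence on squared distances (the ward.D2
#' convention: the height of a merge of two singletons equals their
#' Euclidean distance). Ties in the minimum merge cost are broken by the
#' lexicographically smallest (left, right) pair in input order, making
#' the tree deterministic. The result is `hclust`-compatible, so
#' [stats::cutree()] and [merge_table()] / [tree_newick()] apply.
#'
#' @param x Numeric matrix, one series per row, rownames as labels;
#'   at least two rows, no missing values.
#' @return An object of classes `ward_tree` and `hclust`.
#' @export
ward_cluster <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || nrow(x) < 2) {
    abort("`x` must be a matrix with at least two series (rows)")
  }
  if (any(!is.finite(x))) abort("series must be finite and of equal length")
  n <- nrow(x)
  labels <- rownames(x) %||% paste0("S", seq_len(n))
  D2 <- as.matrix(dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1L, n)
  node_id <- -seq_len(n) # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        cost <- D2[active[i], active[j]]
        # strict '<' keeps the first (lexicographically smallest) pair on ties
        if (is.null(best) || cost < best$cost) {
          best <- list(i = i, j = j, cost = cost)
        }
      }
    }
    i <- best$i
    j <- best$j
    ai <- active[i]
    aj <- active[j]
    merge[step, ] <- c(node_id[ai], node_id[aj])
    height[step] <- sqrt(best$cost)
    ni <- sizes[ai]
    nj <- sizes[aj]
    for (k in active[-c(i, j)]) {
      nk <- sizes[k]
      D2[ai, k] <- D2[k, ai] <-
        ((ni + nk) * D2[k, ai] + (nj + nk) * D2[k, aj] - nk * D2[ai, aj]) /
          (ni + nj + nk)
    }
    sizes[ai] <- ni + nj
    node_id[ai] <- step
    active <- active[-j]
  }
  obj <- structure(
    list(
      merge = merge, height = height, order = tree_leaf_order(merge),
      labels = labels, method = "ward.D2", dist.method = "euclidean",
      call = match.call()
    ),
    class = c("ward_tree", "hclust")
  )
  obj
}

# Left-to-right leaf order implied by the merge matrix.
tree_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Merge list of a clustering tree
#'
#' Tabulates the agglomeration schedule: one row per merge with its two
#' children (leaves named, internal nodes numbered), the merge height and
#' the size of the merged cluster.
#'
#' @param tree A `ward_tree` / `hclust` object.
#' @return Tibble `step`, `left`, `right`, `height`, `size`.
#' @export
merge_table <- function(tree) {
  name_of <- function(id, labels) {
    if (id < 0) labels[-id] else paste0("node_", id)
  }
  sizes <- integer(nrow(tree$merge))
  size_of <- function(id) if (id < 0) 1L else sizes[id]
  out <- lapply(seq_len(nrow(tree$merge)), function(s) {
    l <- tree$merge[s, 1]
    r <- tree$merge[s, 2]
    sizes[s] <<- size_of(l) + size_of(r)
    tibble(
      step = s, left = name_of(l, tree$labels),
      right = name_of(r, tree$labels), height = tree$height[s],
      size = sizes[s]
    )
  })
  bind_rows(out)
}

#' Newick representation of a clustering tree
#'
#' Exports the tree as a Newick string with branch lengths derived from
#' the merge heights, for inspection in standard tree viewers.
#'
#' @param tree A `ward_tree` / `hclust` object.
#' @return A single Newick string.
#' @export
tree_newick <- function(tree) {
  class(tree) <- "hclust"
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}

#' Membership of the top split of a clustering tree
#'
#' The two groups created by cutting the tree below its final (highest)
#' merge - the split that captures the largest share of between-cluster
#' variation under Ward's criterion.
#'
#' @param tree A `ward_tree` / `hclust` object.
#' @return List of two character vectors of leaf labels, the larger-height
#'   side first ordering by the merge order.
#' @export
top_split <- function(tree) {
  k2 <- stats::cutree(tree, k = 2)
  split(names(k2), unname(k2))
}
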