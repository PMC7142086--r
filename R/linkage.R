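#' Complete-linkage agglomerative clustering
#'
#' Agglomerates the rows of a distance matrix with the maximum-linkage update
#' `D(A+B, C) = max(D(A, C), D(B, C))`. Complete linkage is monotone, so merge
#' heights are non-decreasing. Exact distance ties during agglomeration are
#' broken by the smallest node-index pair (leaves are numbered in input order,
#' internal nodes in creation order), which makes the tree deterministic
#' across platforms and input permutations.
#'
#' @param d A `stats::dist` object or a symmetric numeric matrix with zero
#'   diagonal and values in \[0, 1\].
#' @return An object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`), compatible with [stats::cophenetic()], [stats::cutree()] and
#'   plotting.
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    D <- as.matrix(d)
  } else if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
      abort("Distance matrix must be square and symmetric.",
            class = "msdendro_validation_error")
    }
    labels <- rownames(d)
    D <- d
  } else {
    abort("`d` must be a dist object or a symmetric matrix.",
          class = "msdendro_validation_error")
  }
  n <- nrow(D)
  if (n < 1L) {
    abort("Distance matrix must have at least one row.",
          class = "msdendro_validation_error")
  }
  if (any(D < -1e-12) || any(D > 1 + 1e-12)) {
    abort("Distances must lie in [0, 1].", class = "msdendro_validation_error")
  }
  if (is.null(labels)) labels <- as.character(seq_len(n))

  merge <- matrix(0L, nrow = max(n - 1L, 0L), ncol = 2L)
  height <- numeric(max(n - 1L, 0L))

  if (n > 1L) {
    # active cluster bookkeeping: hclust merge codes and age indices for
    # tie-breaking (leaf i -> i, internal node k -> n + k)
    code <- -seq_len(n)
    age <- seq_len(n)
    active <- rep(TRUE, n)
    W <- D
    diag(W) <- Inf
    W[!active, ] <- Inf

    for (step in seq_len(n - 1L)) {
      idx <- which(active)
      sub <- W[idx, idx, drop = FALSE]
      dmin <- min(sub)
      hits <- which(sub == dmin, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      # tie-break: smallest (node_a, node_b) age pair, lexicographically
      a_age <- pmin(age[idx[hits[, 1]]], age[idx[hits[, 2]]])
      b_age <- pmax(age[idx[hits[, 1]]], age[idx[hits[, 2]]])
      pick <- order(a_age, b_age)[1]
      i <- idx[min(hits[pick, ])]
      j <- idx[max(hits[pick, ])]

      merge[step, ] <- order_merge_codes(code[i], code[j])
      height[step] <- dmin

      # fold j into i with the max-linkage update
      W[i, ] <- pmax(W[i, ], W[j, ])
      W[, i] <- W[i, ]
      W[i, i] <- Inf
      active[j] <- FALSE
      W[j, ] <- Inf
      W[, j] <- Inf
      code[i] <- step
      age[i] <- n + step
    }
  }

  structure(
    list(
      merge = merge, height = height,
      order = if (n == 1L) 1L else dendrogram_leaf_order(merge),
      labels = labels, method = "complete",
      call = match.call(), dist.method = "binary"
    ),
    class = "hclust"
  )
}

# hclust convention: singleton codes (negative) before internal codes, else
# ascending
order_merge_codes <- function(a, b) {
  if (a < 0 && b > 0) c(a, b)
  else if (a > 0 && b < 0) c(b, a)
  else if (a < 0) c(max(a, b), min(a, b))  # both leaves: smaller leaf id first
  else c(min(a, b), max(a, b))
}

# left-to-right leaf order implied by the merge matrix (standard recursive
# expansion of the final merge)
dendrogram_leaf_order <- function(merge) {
  expand <- function(code) {
    if (code < 0) -code
    else c(expand(merge[code, 1]), expand(merge[code, 2]))
  }
  as.integer(expand(nrow(merge)))
}

#' Cut a dendrogram into flat clusters at a distance threshold
#'
#' Joins every merge whose height is less than or equal to `threshold`
#' (inclusive) and reads off the resulting connected subtrees as flat
#' clusters. Cluster labels are assigned by the position of each cluster's
#' leftmost leaf in the dendrogram leaf order, so label 1 is the leftmost
#' cluster in a plotted tree. The partition is invariant to permutations of
#' the input leaves.
#'
#' @param tree An `hclust` tree from [complete_linkage()].
#' @param threshold Cut distance, >= 0. `0` yields all singletons (when all
#'   positive-height merges are above 0); a threshold at or above the last
#'   merge height yields a single cluster.
#' @return A tibble with `feature_id` (leaf label) and integer `cluster`,
#'   with the threshold recorded in the `threshold` attribute.
#' @export
cut_clusters <- function(tree, threshold) {
  stopifnot(inherits(tree, "hclust"), is.numeric(threshold), threshold >= 0)
  n <- length(tree$labels)
  if (n == 1L) {
    out <- tibble(feature_id = tree$labels, cluster = 1L)
    attr(out, "threshold") <- threshold
    return(out)
  }
  m_cut <- sum(tree$height <= threshold)  # heights are non-decreasing
  members <- c(as.list(seq_len(n)), vector("list", nrow(tree$merge)))
  consumed <- rep(FALSE, n + nrow(tree$merge))
  for (k in seq_len(m_cut)) {
    childs <- tree$merge[k, ]
    ids <- ifelse(childs < 0, -childs, n + childs)
    members[[n + k]] <- c(members[[ids[1]]], members[[ids[2]]])
    consumed[ids] <- TRUE
  }
  roots <- setdiff(which(!consumed), n + seq(m_cut + 1L, length.out = nrow(tree$merge) - m_cut))
  leaf_pos <- match(seq_len(n), tree$order)
  first_pos <- vapply(roots, function(r) min(leaf_pos[members[[r]]]), numeric(1))
  roots <- roots[order(first_pos)]
  cluster <- integer(n)
  for (lab in seq_along(roots)) cluster[members[[roots[lab]]]] <- lab
  out <- tibble(feature_id = tree$labels, cluster = cluster)
  attr(out, "threshold") <- threshold
  out
}
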