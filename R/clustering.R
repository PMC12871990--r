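# Agglomerative hierarchical clustering from a precomputed distance matrix
# with four linkages (average, single, complete, and a medoid-based Ward),
# dendrogram cutting, and a purity score of a cluster against another
# linkage's tree.

linkage_value <- function(m, A, B, linkage) {
  block <- m[A, B, drop = FALSE]
  switch(linkage,
    average  = mean(block),
    single   = min(block),
    complete = max(block),
    ward     = {
      sse <- function(S) {
        if (length(S) == 1L) return(0)
        tot <- rowSums(m[S, S, drop = FALSE])
        med <- S[which.min(tot)]  # ties: smallest index wins via which.min
        sum(m[S, med]^2)
      }
      sse(c(A, B)) - (sse(A) + sse(B))
    }
  )
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Bottom-up merging: every object starts as its own cluster and the pair
#' of clusters with the smallest inter-cluster distance is merged at that
#' distance until one cluster remains. Inter-cluster distances are
#' recomputed from the pairwise matrix at every step per the chosen
#' linkage:
#' * `average` - mean of all cross-pair distances (UPGMA);
#' * `single` - smallest cross-pair distance;
#' * `complete` - largest cross-pair distance;
#' * `ward` - `SSE(A u B) - SSE(A) - SSE(B)` where
#'   `SSE(S) = sum of squared distances to the medoid of S` (the member
#'   with least total distance to the others). Only pairwise distances are
#'   available, so the medoid stands in for the centroid; merge heights
#'   under this linkage may be non-monotone and are reported as computed.
#'
#' Ties are broken deterministically: candidate pairs compare
#' lexicographically by (smaller cluster id, larger cluster id), where
#' leaves carry ids 1..n in input order and the cluster created at step s
#' has id n+s; medoid ties resolve to the smallest index.
#'
#' @param m Symmetric distance matrix with zero diagonal; dimnames give the
#'   leaf labels.
#' @param linkage `"average"` (default), `"single"`, `"complete"` or
#'   `"ward"`.
#' @return A `cellph_dendrogram`: list with `merges` (tibble `a`, `b`,
#'   `height`, `id`; `a`, `b` refer to leaf ids 1..n or merge ids > n),
#'   `labels`, `linkage`, `n`.
#' @export
hca <- function(m, linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  check_distance_matrix(m)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 objects")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  members <- as.list(seq_len(n))       # cluster id -> leaf indices
  active <- seq_len(n)                 # currently open cluster ids
  merges <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    best_d <- Inf
    k <- length(active)
    for (ii in seq_len(k - 1L)) {
      for (jj in seq.int(ii + 1L, k)) {
        a <- active[ii]; b <- active[jj]
        d <- linkage_value(m, members[[a]], members[[b]], linkage)
        lo <- min(a, b); hi <- max(a, b)
        if (d < best_d ||
            (d == best_d && (lo < best[1L] ||
                             (lo == best[1L] && hi < best[2L])))) {
          best_d <- d
          best <- c(lo, hi)
        }
      }
    }
    newid <- n + step
    members[[newid]] <- sort(c(members[[best[1L]]], members[[best[2L]]]))
    active <- c(setdiff(active, best), newid)
    merges[[step]] <- tibble(a = best[1L], b = best[2L], height = best_d,
                             id = newid)
  }

  structure(
    list(merges = dplyr::bind_rows(merges), labels = labels,
         linkage = linkage, n = n),
    class = "cellph_dendrogram"
  )
}

# leaf indices under each node id (leaf ids 1..n, merge ids n+1..2n-1)
dendro_members <- function(tree) {
  n <- tree$n
  out <- vector("list", 2L * n - 1L)
  out[seq_len(n)] <- as.list(seq_len(n))
  for (s in seq_len(n - 1L)) {
    a <- tree$merges$a[s]; b <- tree$merges$b[s]
    out[[n + s]] <- sort(c(out[[a]], out[[b]]))
  }
  out
}

#' Cut a dendrogram into k clusters
#'
#' Removes the final k-1 merges of the tree (for the monotone linkages
#' these are exactly the k-1 highest merges); the maximal remaining
#' subtrees are the clusters, so every cluster is a subtree of the
#' dendrogram even when Ward heights invert. Cluster names are assigned in
#' decreasing cluster size, ties broken by smallest leaf index, as letters
#' A, B, C, ...
#'
#' @param tree A `cellph_dendrogram`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `cellph_clusters`: tibble with columns `id` (leaf label) and
#'   `cluster` (name), plus attribute `k`.
#' @export
cut_clusters <- function(tree, k) {
  n <- tree$n
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    abort("k must be between 1 and the number of leaves",
          class = "cellph_parameter_error")
  }
  k <- as.integer(k)
  assign <- seq_len(n)                     # cluster root id per leaf
  node_of <- seq_len(2L * n - 1L)          # current root of each node id
  keep <- seq_len(n - k)                   # merges retained
  for (s in keep) {
    a <- tree$merges$a[s]; b <- tree$merges$b[s]
    id <- tree$merges$id[s]
    node_of[node_of == node_of[a] | node_of == node_of[b]] <- id
  }
  roots <- node_of[seq_len(n)]
  groups <- split(seq_len(n), roots)
  sizes <- lengths(groups)
  minleaf <- vapply(groups, min, integer(1))
  ord <- order(-sizes, minleaf)
  nm <- if (k <= 26L) LETTERS[seq_len(k)] else paste0("C", seq_len(k))
  cl <- character(n)
  for (i in seq_along(ord)) cl[groups[[ord[i]]]] <- nm[i]
  out <- tibble(id = tree$labels, cluster = cl)
  attr(out, "k") <- k
  class(out) <- c("cellph_clusters", class(out))
  out
}

#' Purity of a cluster with respect to a dendrogram
#'
#' How well a group of objects `c1` (found by one linkage) is preserved in
#' a tree built with another linkage: starting from any member of `c1` and
#' walking up the tree, collecting the leaves of ever-larger subtrees until
#' all of `c1` is covered, reaches exactly the subtree rooted at the lowest
#' common ancestor of `c1`. With `O` the leaf set of that subtree and `N`
#' the total number of leaves, the purity is
#' `P = (N - |O|) / (N - |c1|)`, clipped to `[0, 1]`: 1 when `c1` is a
#' subtree of its own, 0 when only the whole tree contains it.
#'
#' @param c1 Character vector of leaf labels (a proper non-empty subset of
#'   the tree's leaves).
#' @param tree A `cellph_dendrogram`.
#' @return Purity score in `[0, 1]`.
#' @export
purity <- function(c1, tree) {
  n <- tree$n
  idx <- match(c1, tree$labels)
  if (length(idx) == 0L || anyNA(idx)) {
    abort("c1 must be a non-empty set of leaf labels")
  }
  idx <- sort(unique(idx))
  if (length(idx) == n) {
    abort("purity is undefined when c1 contains all leaves",
          class = "cellph_domain_error")
  }
  if (length(idx) == 1L) return(1)
  mem <- dendro_members(tree)
  # first (lowest) merge whose subtree contains all of c1
  for (s in seq_len(n - 1L)) {
    O <- mem[[n + s]]
    if (all(idx %in% O)) {
      p <- (n - length(O)) / (n - length(idx))
      return(min(max(p, 0), 1))
    }
  }
  0
}

#' Purity table of a reference clustering against several linkages
#'
#' Cuts the tree built with `ref_linkage` into `k` clusters and scores
#' every cluster's purity against the trees of all requested linkages.
#'
#' @param m Distance matrix.
#' @param k Number of clusters from the reference tree.
#' @param ref_linkage Linkage defining the clusters (default `"average"`).
#' @param linkages Linkages to score against (default all four).
#' @return A tibble with columns `linkage`, one column per cluster name,
#'   and attribute `sizes` (named cluster sizes).
#' @export
purity_table <- function(m, k = 4L, ref_linkage = "average",
                         linkages = c("average", "single", "complete",
                                      "ward")) {
  ref_tree <- hca(m, ref_linkage)
  cl <- cut_clusters(ref_tree, k)
  trees <- lapply(linkages, function(l) {
    if (l == ref_linkage) ref_tree else hca(m, l)
  })
  names(trees) <- linkages
  cl_names <- sort(unique(cl$cluster))
  rows <- lapply(linkages, function(l) {
    scores <- vapply(cl_names, function(cn) {
      purity(cl$id[cl$cluster == cn], trees[[l]])
    }, numeric(1))
    tibble(linkage = l, !!!as.list(scores))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sizes") <- table(cl$cluster)
  out
}

#' Convert a dendrogram to a base hclust object
#'
#' @param x A `cellph_dendrogram`.
#' @param ... Unused.
#' @return A `stats::hclust` object.
#' @export
as.hclust.cellph_dendrogram <- function(x, ...) {
  n <- x$n
  to_hc <- function(id) if (id <= n) -id else id - n
  merge <- cbind(vapply(x$merges$a, to_hc, numeric(1)),
                 vapply(x$merges$b, to_hc, numeric(1)))
  # leaf ordering by recursive traversal
  ord <- integer(0)
  walk <- function(id) {
    if (id <= n) {
      ord <<- c(ord, id)
    } else {
      s <- id - n
      walk(x$merges$a[s])
      walk(x$merges$b[s])
    }
  }
  walk(2L * n - 1L)
  structure(
    list(merge = merge, height = x$merges$height, order = ord,
         labels = x$labels, method = x$linkage,
         call = match.call(), dist.method = "precomputed"),
    class = "hclust"
  )
}

#' Serialise a dendrogram as a Newick string
#'
#' Branch lengths are height differences between a node and its parent
#' merge (leaves descend from their first merge at its full height).
#'
#' @param tree A `cellph_dendrogram`.
#' @return A Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(tree) {
  n <- tree$n
  height_of <- c(rep(0, n), tree$merges$height)
  build <- function(id) {
    if (id <= n) return(tree$labels[id])
    s <- id - n
    a <- tree$merges$a[s]; b <- tree$merges$b[s]
    h <- tree$merges$height[s]
    sprintf("(%s:%g,%s:%g)", build(a), h - height_of[a],
            build(b), h - height_of[b])
  }
  paste0(build(2L * n - 1L), ";")
}

#' @export
print.cellph_dendrogram <- function(x, ...) {
  cat(sprintf("<cellph_dendrogram> %d leaves, %s linkage\n", x$n,
              x$linkage))
  invisible(x)
}
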