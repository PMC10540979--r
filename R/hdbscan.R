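#' Hierarchical density-based clustering with noise
#'
#' A complete implementation of hierarchical density-based clustering:
#' mutual-reachability distances from k-nearest-neighbor core distances, a
#' minimum spanning tree (Prim), the single-linkage hierarchy condensed by
#' minimum cluster size, and cluster extraction by excess-of-mass stability.
#' Points in no selected cluster are labeled noise (`-1`).
#'
#' @name hdbscan
NULL

# Prim's MST over mutual-reachability distances, with distance rows
# computed on the fly (O(n^2) time, O(n) memory).
mutual_reachability_mst <- function(x, core_dist) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n)
  parent <- rep(0L, n)
  cur <- 1L
  in_tree[1L] <- TRUE
  edges <- matrix(0, n - 1L, 3L)   # from, to, weight
  for (step in seq_len(n - 1L)) {
    d2 <- sq + sq[cur] - 2 * as.numeric(x %*% x[cur, ])
    d <- sqrt(pmax(d2, 0))
    mr <- pmax(d, core_dist, core_dist[cur])
    upd <- !in_tree & mr < best
    best[upd] <- mr[upd]
    parent[upd] <- cur
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    edges[step, ] <- c(parent[nxt], nxt, best[nxt])
    in_tree[nxt] <- TRUE
    cur <- nxt
  }
  edges[order(edges[, 3L]), , drop = FALSE]
}

# Single-linkage hierarchy from sorted MST edges (union-find).
# Internal nodes are numbered n+1 .. 2n-1 in merge order.
slink_hierarchy <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_of <- seq_len(n)            # representative -> current node id
  size <- c(rep(1L, n), rep(0L, n - 1L))
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    na <- node_of[a]; nb <- node_of[b]
    new <- n + e
    merges[e, ] <- c(na, nb)
    heights[e] <- edges[e, 3L]
    size[new] <- size[na] + size[nb]
    parent[a] <- b
    node_of[b] <- new
  }
  list(merges = merges, heights = heights, size = size)
}

# Condense the hierarchy: clusters persist only while both split children
# have >= min_cluster_size points; smaller children "fall out" as points at
# lambda = 1 / height. Returns per-point fall-out lambdas and cluster-tree
# bookkeeping for stability computation.
condense_tree <- function(hier, n, min_cluster_size) {
  n_nodes <- 2L * n - 1L
  root <- n_nodes
  kids <- vector("list", n_nodes)    # children in the raw hierarchy
  for (e in seq_len(n - 1L)) kids[[n + e]] <- hier$merges[e, ]
  hgt <- c(rep(0, n), hier$heights)
  size <- hier$size

  # condensed clusters: id, parent, lambda_birth
  cl_parent <- integer(0); cl_birth <- numeric(0)
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    length(cl_parent)
  }
  pt_cluster <- integer(n)           # condensed cluster each point falls from
  pt_lambda <- numeric(n)            # lambda at which it falls out
  # stability accumulators
  stab <- numeric(0)

  # keep lambdas finite even for duplicate points (zero merge heights)
  pos <- hgt[hgt > 0]
  h_floor <- if (length(pos)) min(pos) / 2 else 1e-12
  lam <- function(h) 1 / max(h, h_floor)

  root_cl <- new_cluster(0L, lam(hgt[root]))
  stab <- numeric(1L)

  # iterative walk: stack of (raw node, condensed cluster)
  stack <- list(c(root, root_cl))
  # collect all leaf points of a raw subtree
  subtree_points <- function(node) {
    out <- integer(0); st <- node
    while (length(st)) {
      v <- st[length(st)]; st <- st[-length(st)]
      if (v <= n) out <- c(out, v) else st <- c(st, kids[[v]])
    }
    out
  }
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1L]; cl <- top[2L]
    # descend chains where one child is too small (those points fall out)
    repeat {
      if (node <= n) {               # singleton reached
        pt_cluster[node] <- cl
        pt_lambda[node] <- lam(0)
        break
      }
      ch <- kids[[node]]
      l_here <- lam(hgt[node])
      big <- ch[size[ch] >= min_cluster_size]
      if (length(big) == 2L) {
        # true split: two new condensed clusters are born here; every point
        # still in `cl` (exactly the points under `node`) leaves it now
        for (c2 in ch) {
          ncl <- new_cluster(cl, l_here)
          stab[ncl] <- 0
          stack[[length(stack) + 1L]] <- c(c2, ncl)
        }
        # contribution of the split to the parent's stability
        stab[cl] <- stab[cl] + size[node] * (l_here - cl_birth[cl])
        break
      } else {
        # points of the small child(ren) fall out of cl at l_here
        small <- ch[size[ch] < min_cluster_size]
        for (c2 in small) {
          pts <- subtree_points(c2)
          pt_cluster[pts] <- cl
          pt_lambda[pts] <- l_here
          stab[cl] <- stab[cl] + length(pts) * (l_here - cl_birth[cl])
        }
        if (length(big) == 0L) break
        node <- big[1L]
      }
    }
  }
  list(parent = cl_parent, birth = cl_birth, stability = stab,
       pt_cluster = pt_cluster, pt_lambda = pt_lambda)
}

#' Density-based cluster extraction in an embedded space
#'
#' @param embedding numeric matrix (rows = observations), typically the 2-D
#'   output of [embed_conformations].
#' @param min_cluster_size smallest cluster to report; default
#'   `max(25, 1%)` of the rows.
#' @param min_samples neighborhood size for core distances (defaults to
#'   `min_cluster_size`).
#' @param allow_single_cluster permit the hierarchy root to be returned as
#'   one cluster when no stable substructure exists.
#' @return object of class `hdbscan_result`: `labels` (1..k, noise = -1),
#'   `n_clusters`, `noise_fraction`, `cluster_sizes`, parameters.
#' @export
cluster_conformations <- function(embedding, min_cluster_size = NULL,
                                  min_samples = NULL,
                                  allow_single_cluster = FALSE) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  min_cluster_size <- min_cluster_size %||% max(25L, ceiling(0.01 * n))
  min_samples <- min_samples %||% min_cluster_size
  if (n < min_cluster_size)
    stop(sprintf("%d rows < min_cluster_size = %d", n, min_cluster_size),
         call. = FALSE)

  knn <- knn_euclidean(x, min(min_samples, n - 1L))
  core <- knn$dist[, ncol(knn$dist)]
  mst <- mutual_reachability_mst(x, core)
  hier <- slink_hierarchy(mst, n)
  cond <- condense_tree(hier, n, min_cluster_size)

  # excess-of-mass selection, bottom-up
  n_cl <- length(cond$parent)
  children <- split(seq_len(n_cl), factor(cond$parent, levels = 0:n_cl))
  selected <- rep(FALSE, n_cl)
  subtree_stab <- cond$stability
  # children are always created after their parent, so reverse creation
  # order is a valid bottom-up traversal
  for (cl in rev(seq_len(n_cl))) {
    ch <- children[[as.character(cl)]]
    if (length(ch) == 0L) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- cond$stability[cl]
    } else {
      child_sum <- sum(subtree_stab[ch])
      if (child_sum >= cond$stability[cl]) {
        subtree_stab[cl] <- child_sum
      } else {
        selected[cl] <- TRUE
        # deselect all descendants
        st <- ch
        while (length(st)) {
          v <- st[length(st)]; st <- st[-length(st)]
          selected[v] <- FALSE
          st <- c(st, children[[as.character(v)]])
        }
        subtree_stab[cl] <- cond$stability[cl]
      }
    }
  }
  if (!allow_single_cluster) selected[1L] <- FALSE
  if (!any(selected) && allow_single_cluster) selected[1L] <- TRUE

  # each point belongs to the nearest selected ancestor of its fall-out cluster
  sel_of <- integer(n_cl)
  for (cl in seq_len(n_cl)) {
    v <- cl
    while (v != 0L && !selected[v]) v <- cond$parent[v]
    sel_of[cl] <- v
  }
  raw <- sel_of[cond$pt_cluster]
  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  for (k in seq_along(sel_ids)) labels[raw == sel_ids[k]] <- k
  # renumber by decreasing size for stable, readable output
  if (length(sel_ids)) {
    sz <- tabulate(labels[labels > 0], nbins = length(sel_ids))
    remap <- order(order(sz, decreasing = TRUE))
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  sizes <- if (any(labels > 0)) tabulate(labels[labels > 0]) else integer(0)
  noise_fraction <- mean(labels == -1L)
  if (all(labels == -1L))
    warning(paste("all points labeled noise; consider lowering",
                  "min_cluster_size or sweeping hyperparameters"))
  structure(list(
    labels = labels, n_clusters = length(sizes),
    cluster_sizes = sizes, noise_fraction = noise_fraction,
    min_cluster_size = min_cluster_size, min_samples = min_samples,
    allow_single_cluster = allow_single_cluster
  ), class = "hdbscan_result")
}

#' @export
print.hdbscan_result <- function(x, ...) {
  cat(sprintf("<hdbscan_result> %d cluster(s), noise %.1f%%\n",
              x$n_clusters, 100 * x$noise_fraction))
  if (x$n_clusters)
    cat("  sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}
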