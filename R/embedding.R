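#' Neighbor-graph nonlinear embedding
#'
#' A two-dimensional embedding that preserves local topology, built the way
#' modern manifold-learning embeddings are: a fuzzy k-nearest-neighbor graph
#' with locally adaptive kernel widths, symmetrized into edge weights, laid
#' out by spectral initialization on the normalized graph Laplacian and
#' refined by a seeded attraction-repulsion optimization with a Cauchy
#' low-dimensional kernel. Deterministic for a fixed seed.
#'
#' @name embedding
NULL

# k nearest neighbors by squared Euclidean distance, chunked to bound memory.
knn_euclidean <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  stopifnot(k < n)
  sq <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(x[s:e, , drop = FALSE], x)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf   # exclude self
    for (i in seq_len(e - s + 1L)) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(pmax(d2[i, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

# Locally-adaptive fuzzy weights: per point, rho = nearest-neighbor
# distance and sigma solved so the smoothed neighbor cardinality is
# log2(k); then symmetrize by probabilistic union w + w' - w w'.
fuzzy_graph <- function(knn) {
  n <- nrow(knn$index); k <- ncol(knn$index)
  target <- log2(k)
  rho <- knn$dist[, 1L]
  sigma <- vapply(seq_len(n), function(i) {
    d <- pmax(knn$dist[i, ] - rho[i], 0)
    lo <- 1e-6; hi <- max(d[d > 0], 1)
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  w <- exp(-pmax(knn$dist - rho, 0) / sigma)
  i <- rep(seq_len(n), k)
  j <- as.vector(knn$index)
  A <- Matrix::sparseMatrix(i = i, j = j, x = as.vector(w), dims = c(n, n))
  A <- A + Matrix::t(A) - A * Matrix::t(A)
  A
}

# Leading eigenvectors of the normalized adjacency D^-1/2 W D^-1/2 via
# igraph's ARPACK with a fixed deterministic start vector; dense eigen
# fallback for small problems.
spectral_coords <- function(W, n_dim = 2L) {
  n <- nrow(W)
  deg <- pmax(Matrix::rowSums(W), 1e-12)
  Dhalf <- 1 / sqrt(deg)
  M <- W * tcrossprod(Dhalf)          # D^-1/2 W D^-1/2, sparse
  nev <- n_dim + 1L
  if (n <= 600L) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    vec <- e$vectors[, seq_len(nev), drop = FALSE]
  } else {
    f <- function(x, extra) as.numeric(M %*% x)
    a <- igraph::arpack(f, options = list(
      n = n, nev = nev, ncv = max(2L * nev + 8L, 20L), which = "LA",
      maxiter = 3000L, start = sin(seq_len(n))), sym = TRUE)
    vec <- a$vectors[, seq_len(nev), drop = FALSE]
  }
  # drop the Perron-like leading vector; fix signs deterministically
  coords <- vec[, 2L:(n_dim + 1L), drop = FALSE]
  for (d in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, d])), d])
    if (s < 0) coords[, d] <- -coords[, d]
  }
  coords
}

#' Embed feature vectors into two dimensions
#'
#' Standardizes feature columns, reduces to at most 50 principal
#' components, builds the fuzzy k-nearest-neighbor graph, and lays it out
#' in 2-D (spectral initialization + seeded force refinement). Identical
#' input, hyperparameters and seed give identical coordinates.
#'
#' @param features numeric matrix, one row per observation.
#' @param n_neighbors neighborhood size of the kNN graph.
#' @param min_dist minimum spread distance in the layout; smaller values
#'   pack clusters more tightly.
#' @param n_epochs refinement epochs.
#' @param n_pca maximal number of principal components kept before the
#'   neighbor search.
#' @param seed integer seed.
#' @return n x 2 coordinate matrix with attributes `n_neighbors`,
#'   `min_dist`, `seed`.
#' @export
embed_conformations <- function(features, n_neighbors = 15L, min_dist = 0.1,
                                n_epochs = 150L, n_pca = 50L, seed = 42L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < n_neighbors + 1L)
    stop(sprintf("need at least n_neighbors + 1 = %d rows, got %d",
                 n_neighbors + 1L, n), call. = FALSE)
  sds <- apply(features, 2L, stats::sd)
  keep <- which(sds > 0)
  x <- scale(features[, keep, drop = FALSE])
  if (ncol(x) > n_pca) {
    pc <- stats::prcomp(x, center = FALSE, rank. = n_pca)
    x <- pc$x
  }

  local_seed(derive_seed(seed, "embed"), {
    knn <- knn_euclidean(x, n_neighbors)
    W <- fuzzy_graph(knn)
    init <- spectral_coords(W, 2L)
    init <- init / max(stats::sd(init[, 1L]), 1e-12) * 10
    init <- init + matrix(stats::rnorm(2L * n, sd = 1e-3), ncol = 2L)
    coords <- refine_layout(W, init, n_epochs = n_epochs,
                            min_dist = min_dist)
  })
  structure(coords, n_neighbors = n_neighbors, min_dist = min_dist,
            seed = seed)
}

# Vectorized attraction-repulsion refinement of a graph layout. Attraction
# acts along graph edges with the Cauchy kernel gradient; repulsion against
# per-epoch resampled negatives. Learning rate decays linearly.
refine_layout <- function(W, coords, n_epochs = 150L, min_dist = 0.1,
                          neg_per_point = 5L, lr0 = 1.5) {
  n <- nrow(coords)
  tri <- Matrix::which(W != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1L] < tri[, 2L], , drop = FALSE]
  wij <- W[tri]
  i <- tri[, 1L]; j <- tri[, 2L]
  eps <- max(min_dist, 1e-3)
  for (ep in seq_len(n_epochs)) {
    lr <- lr0 * (1 - (ep - 1) / n_epochs)
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    d2 <- rowSums(d^2)
    ga <- (2 * wij / (1 + d2)) * d          # attraction along edges
    upd <- rbind(-ga, ga)
    ids <- c(i, j)
    # negative sampling: each point repels one random partner per round
    for (r in seq_len(neg_per_point)) {
      neg <- sample.int(n, n, replace = TRUE)
      dn <- coords - coords[neg, , drop = FALSE]
      dn2 <- rowSums(dn^2)
      gr <- (2 / ((eps + dn2) * (1 + dn2))) * dn
      upd <- rbind(upd, gr)
      ids <- c(ids, seq_len(n))
    }
    delta <- rowsum(upd, ids)
    coords <- coords + lr * pmin(pmax(delta[order(as.integer(rownames(delta))), ,
                                            drop = FALSE], -4), 4)
  }
  unname(coords)
}
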