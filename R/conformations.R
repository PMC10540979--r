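#' Conformational landscape of polymers within micelles
#'
#' The two-step protocol: every (polymer, frame) observation is featurized
#' by rotation/translation-invariant internal geometry, embedded into two
#' dimensions ([embed_conformations]), and clustered by hierarchical
#' density-based clustering ([cluster_conformations]). Cluster occupancy,
#' medoid representatives and intrinsic localization summarize the result.
#'
#' @name conformation_landscape
NULL

#' Rotation/translation-invariant conformational features
#'
#' Per (polymer, frame): the upper triangle of the monomer center-of-mass
#' pairwise distance matrix (Angstrom), optionally augmented with per-block
#' radii of gyration and end-to-end distances. Invariant to rigid motion of
#' the polymer by construction. All polymers must share one topology.
#'
#' @param ens a [frame_ensemble].
#' @param stationary_range frames to featurize (default: all).
#' @param include_blocks append per-block R_G and end-to-end distances.
#' @return numeric matrix, one row per (polymer, frame); attribute
#'   `row_index` is a data.frame with columns `polymer_id`, `frame`.
#' @export
featurize <- function(ens, stationary_range = NULL, include_blocks = FALSE) {
  frames <- stationary_range %||% seq_len(n_frames(ens))
  ids <- ens$polymer_ids
  specs <- ens$polymer_specs
  nm <- vapply(specs, function(s) s$n_monomers, integer(1))
  if (length(unique(nm)) != 1L)
    stop("featurize requires all polymers to share one topology", call. = FALSE)
  sp <- specs[[1L]]

  rows <- vector("list", length(ids) * length(frames))
  ridx <- data.frame(polymer_id = integer(0), frame = integer(0))
  r <- 0L
  for (f in frames) {
    for (id in ids) {
      mc <- monomer_coms(ens, f, id)
      feat <- as.numeric(stats::dist(mc))
      if (include_blocks) {
        extra <- unlist(lapply(seq_len(nrow(sp$blocks)), function(b) {
          bm <- mc[sp$monomer_block == b, , drop = FALSE]
          rg <- sqrt(sum(sweep(bm, 2L, colMeans(bm))^2) / nrow(bm))
          e2e <- sqrt(sum((bm[nrow(bm), ] - bm[1L, ])^2))
          c(rg, e2e)
        }))
        feat <- c(feat, extra)
      }
      r <- r + 1L
      rows[[r]] <- feat
    }
  }
  ridx <- data.frame(
    polymer_id = rep(ids, times = length(frames)),
    frame = rep(frames, each = length(ids)))
  out <- do.call(rbind, rows)
  attr(out, "row_index") <- ridx
  out
}

#' Run the full conformational-landscape protocol
#'
#' Featurizes, embeds, clusters, and summarizes occupancy. Noise rows are
#' included in the occupancy denominator (reported as their own gray bar).
#'
#' @param ens a [frame_ensemble].
#' @param stationary_range frames to analyse.
#' @param n_neighbors,min_dist,seed embedding hyperparameters
#'   ([embed_conformations]).
#' @param min_cluster_size,min_samples clustering hyperparameters
#'   ([cluster_conformations]).
#' @param include_blocks pass-through to [featurize].
#' @return object of class `conformation_landscape` with `features`,
#'   `embedding`, `labels`, `fractions` (%, named, noise under `"noise"`),
#'   `medoids`, `row_index`, hyperparameters and seed.
#' @export
conformation_landscape <- function(ens, stationary_range = NULL,
                                   n_neighbors = 15L, min_dist = 0.1,
                                   min_cluster_size = NULL,
                                   min_samples = NULL,
                                   include_blocks = FALSE, seed = 42L) {
  feats <- featurize(ens, stationary_range, include_blocks)
  emb <- embed_conformations(feats, n_neighbors = n_neighbors,
                             min_dist = min_dist, seed = seed)
  cl <- cluster_conformations(emb, min_cluster_size = min_cluster_size,
                              min_samples = min_samples)
  land <- structure(list(
    features = feats, embedding = emb, labels = cl$labels,
    n_clusters = cl$n_clusters, noise_fraction = cl$noise_fraction,
    row_index = attr(feats, "row_index"),
    hyperparameters = list(
      n_neighbors = n_neighbors, min_dist = min_dist,
      min_cluster_size = cl$min_cluster_size,
      min_samples = cl$min_samples),
    seed = seed
  ), class = "conformation_landscape")
  s <- summarize_clusters(land)
  land$fractions <- s$fractions
  land$medoids <- s$medoids
  if (land$noise_fraction > 0.08)
    warning(sprintf("noise fraction %.1f%% exceeds 8%%",
                    100 * land$noise_fraction))
  land
}

#' Cluster occupancy and medoid representatives
#'
#' Occupancy percentages include noise in the denominator. The medoid of a
#' cluster is the row minimizing the summed feature-space distance to the
#' cluster's other rows; noise rows never enter medoid computations.
#'
#' @param landscape a [conformation_landscape] (or compatible list with
#'   `features`, `labels`, `row_index`).
#' @return list with `fractions` (named percentages summing to 100) and
#'   `medoids` (data.frame: cluster, row, polymer_id, frame).
#' @export
summarize_clusters <- function(landscape) {
  labels <- landscape$labels
  n <- length(labels)
  ks <- sort(unique(labels[labels > 0]))
  fr <- c(vapply(ks, function(k) 100 * sum(labels == k) / n, numeric(1)),
          100 * sum(labels == -1L) / n)
  names(fr) <- c(sprintf("cluster%d", ks), "noise")
  med <- do.call(rbind, lapply(ks, function(k) {
    rows <- which(labels == k)
    x <- landscape$features[rows, , drop = FALSE]
    if (length(rows) == 1L) {
      best <- 1L
    } else {
      dm <- as.matrix(stats::dist(x))
      best <- which.min(rowSums(dm))
    }
    data.frame(cluster = k, row = rows[best],
               polymer_id = landscape$row_index$polymer_id[rows[best]],
               frame = landscape$row_index$frame[rows[best]])
  }))
  list(fractions = fr, medoids = med)
}

#' @export
print.conformation_landscape <- function(x, ...) {
  cat(sprintf("<conformation_landscape> %d rows, %d cluster(s), noise %.1f%%\n",
              nrow(x$features), x$n_clusters, 100 * x$noise_fraction))
  cat("  occupancy (%):\n")
  print(round(x$fractions, 1))
  invisible(x)
}

#' @export
plot.conformation_landscape <- function(x, ...) {
  cols <- c("grey60", grDevices::hcl.colors(max(1, x$n_clusters), "Dark 3"))
  ci <- ifelse(x$labels == -1L, 1L, x$labels + 1L)
  graphics::plot(x$embedding[, 1L], x$embedding[, 2L], col = cols[ci],
                 pch = 16, cex = 0.5, xlab = "embedding 1",
                 ylab = "embedding 2", ...)
  invisible(x)
}

#' Export medoid structures
#'
#' Writes each cluster medoid's polymer, at its frame, as a PDB file.
#'
#' @param landscape a [conformation_landscape].
#' @param ens the [frame_ensemble] it was computed from.
#' @param dir output directory.
#' @return character vector of file paths, invisibly.
#' @export
write_medoids <- function(landscape, ens, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(nrow(landscape$medoids))) {
    m <- landscape$medoids[i, ]
    id <- as.character(m$polymer_id)
    sp <- ens$polymer_specs[[id]]
    xyz <- polymer_coords(ens, m$frame, m$polymer_id)
    sub <- frame_ensemble(
      list(list(positions = xyz, box = frame_box(ens, m$frame))),
      data.frame(name = sp$atom_name, element = sp$atom_element,
                 mass = sp$atom_mass, molecule_id = 1L, role = "polymer",
                 stringsAsFactors = FALSE),
      stats::setNames(list(sp), "1"))
    p <- file.path(dir, sprintf("medoid_cluster%d.pdb", m$cluster))
    write_pdb(sub, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Intrinsic localization of conformation clusters
#'
#' Assigns every polymer's atoms, per frame, to that row's cluster and
#' computes per-cluster intrinsic density profiles against the frame's
#' core-shell interface — where in the micelle each conformational family
#' lives.
#'
#' @param landscape a [conformation_landscape].
#' @param ens the [frame_ensemble] it was computed from.
#' @param frames frames to profile (default: the landscape's frames).
#' @param bin_width,d_range,grid_resolution,cutoff,n_mc,seed see
#'   [intrinsic_density].
#' @return the [intrinsic_density] result, with one group per cluster
#'   (`"noise"` for unclustered rows) and an extra `mean_d` element: the
#'   mass-weighted mean intrinsic distance per cluster.
#' @export
localize_clusters <- function(landscape, ens, frames = NULL, bin_width = 1,
                              d_range = c(-25, 15), grid_resolution = 512L,
                              cutoff = 4.5, n_mc = 1e5, seed = 1) {
  ri <- landscape$row_index
  frames <- frames %||% sort(unique(ri$frame))
  if (!all(frames %in% ri$frame))
    stop("requested frames were not part of the landscape", call. = FALSE)

  profs <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    ga <- rep(NA_character_, nrow(ens$atoms))
    sel <- ri$frame == f
    for (r in which(sel)) {
      lab <- landscape$labels[r]
      gname <- if (lab == -1L) "noise" else sprintf("cluster%d", lab)
      ga[ens$molecule_atoms[[as.character(ri$polymer_id[r])]]] <- gname
    }
    profs[[k]] <- intrinsic_density(
      ens, group_assignments = ga, bin_width = bin_width, d_range = d_range,
      cutoff = cutoff, stationary_range = f,
      grid_resolution = grid_resolution, n_mc = n_mc, seed = seed + k)
  }
  # average the per-frame profiles group-wise
  groups <- sort(unique(unlist(lapply(profs, `[[`, "groups"))))
  base <- profs[[1L]]$profile[, c("d_lo", "d_hi", "d_mid")]
  base <- base[!duplicated(base$d_mid), ]
  prof <- do.call(rbind, lapply(groups, function(g) {
    mats <- vapply(profs, function(p) {
      v <- p$profile$density[p$profile$group == g]
      if (length(v) == 0L) rep(0, nrow(base)) else v
    }, numeric(nrow(base)))
    mats <- matrix(mats, nrow = nrow(base))
    data.frame(base, group = g, density = rowMeans(mats),
               density_sd = apply(mats, 1L, stats::sd),
               stringsAsFactors = FALSE)
  }))
  # mass-weighted mean intrinsic distance per group
  mh <- Reduce(`+`, lapply(profs, function(p) {
    m <- matrix(0, nrow(base), length(groups), dimnames = list(NULL, groups))
    m[, p$groups] <- apply(p$mass_hist, c(1, 2), sum)
    m
  }))
  mean_d <- vapply(groups, function(g) {
    w <- mh[, g]
    if (sum(w) == 0) NA_real_ else sum(base$d_mid * w) / sum(w)
  }, numeric(1))
  single <- names(which(vapply(groups, function(g)
    sum(vapply(profs, function(p)
      sum(p$mass_in_range[, colnames(p$mass_in_range) == g]), numeric(1))) > 0 &&
      sum(landscape$labels[ri$frame %in% frames] ==
            ifelse(g == "noise", -1L, as.integer(sub("cluster", "", g)))) == 1L,
    logical(1))))
  if (length(single))
    warning(sprintf("cluster(s) %s have a single member in the profiled frames; high variance",
                    paste(single, collapse = ", ")))
  structure(list(profile = prof, groups = groups, mean_d = mean_d,
                 frames = frames, per_frame = profs),
            class = "intrinsic_profile")
}
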