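test_that("features are invariant to rigid motion and have the right length", {
  gm <- tiny_micelle(n_polymers = 3, seed = 41)
  ens <- gm$ensemble
  f1 <- featurize(ens)
  sp <- ens$polymer_specs[["1"]]
  nm <- sp$n_monomers
  expect_equal(ncol(f1), nm * (nm - 1) / 2)
  expect_equal(nrow(f1), 3)
  # rotate + translate the whole frame rigidly
  R <- micelletools:::random_rotation()
  ens2 <- ens
  ens2$frames[[1]]$positions <- ens$frames[[1]]$positions %*% t(R) + 5
  ens2$frames[[1]]$box <- ens$frames[[1]]$box * 10  # avoid rewrap effects
  ens2 <- frame_ensemble(ens2$frames, ens2$atoms, ens2$polymer_specs)
  f2 <- featurize(ens2)
  expect_lt(max(abs(f1 - f2)), 1e-6)
  # block-augmented variant appends 2 values per block
  fb <- featurize(ens, include_blocks = TRUE)
  expect_equal(ncol(fb), ncol(f1) + 2 * nrow(sp$blocks))
})

test_that("extended chains have larger mean pairwise distance than collapsed", {
  sp <- build_polymer_spec("diblock")
  ge <- generate_micelle(sp, 1, family_mix = c(extended_MA = 1),
                         noise_sigma = 0, seed = 42)
  gc <- generate_micelle(sp, 1, family_mix = c(collapsed_MA = 1),
                         noise_sigma = 0, seed = 42)
  # extended MA + collapsed EO vs collapsed MA + extended EO: compare MA
  # block internal spread, the defining axis of the families
  fe <- featurize(ge$ensemble, include_blocks = TRUE)
  fc <- featurize(gc$ensemble, include_blocks = TRUE)
  nb <- ncol(fe)
  # MA block R_G is the first appended block statistic
  expect_gt(fe[1, nb - 3], fc[1, nb - 3])
})

test_that("embedding separates planted blobs and is deterministic", {
  set.seed(43)
  X <- rbind(matrix(rnorm(200 * 8, 0), ncol = 8),
             matrix(rnorm(150 * 8, 7), ncol = 8),
             matrix(rnorm(100 * 8, -7), ncol = 8))
  lab <- rep(1:3, c(200, 150, 100))
  emb <- embed_conformations(X, seed = 1)
  ctrs <- t(sapply(1:3, function(k) colMeans(emb[lab == k, ])))
  spread <- sapply(1:3, function(k) {
    e <- emb[lab == k, ]
    mean(sqrt(rowSums(sweep(e, 2, colMeans(e))^2)))
  })
  expect_gt(min(dist(ctrs)), 3 * mean(spread))
  # determinism
  emb2 <- embed_conformations(X, seed = 1)
  expect_identical(unclass(emb), unclass(emb2))
  # duplicated rows land together
  Xd <- rbind(X, X[1, , drop = FALSE])
  embd <- embed_conformations(Xd, seed = 1)
  d_dup <- sqrt(sum((embd[nrow(Xd), ] - embd[1, ])^2))
  expect_lt(d_dup, mean(spread))
  # too few rows errors
  expect_error(embed_conformations(X[1:10, ], n_neighbors = 15), "at least")
})

test_that("clustering recovers planted blobs with noise labeling", {
  set.seed(44)
  emb <- rbind(matrix(rnorm(300 * 2, 0, 0.5), ncol = 2),
               matrix(rnorm(200 * 2, 8, 0.5), ncol = 2),
               cbind(rnorm(100, 4, 0.5), rnorm(100, 8, 0.5)))
  truth <- rep(1:3, c(300, 200, 100))
  cl <- cluster_conformations(emb, min_cluster_size = 30)
  expect_equal(cl$n_clusters, 3)
  expect_gte(ari(cl$labels, truth), 0.9)
  expect_lt(cl$noise_fraction, 0.08)
  # single tight blob: one cluster when the root may stand alone
  one <- matrix(rnorm(400, 0, 0.3), ncol = 2)
  c1 <- cluster_conformations(one, min_cluster_size = 30,
                              allow_single_cluster = TRUE)
  expect_equal(c1$n_clusters, 1)
  expect_lt(c1$noise_fraction, 0.05)
  # sparse uniform points: mostly noise, warned
  set.seed(45)
  un <- matrix(runif(120, 0, 400), ncol = 2)
  expect_warning(cu <- cluster_conformations(un, min_cluster_size = 25,
                                             min_samples = 10),
                 "noise")
  expect_gt(cu$noise_fraction, 0.5)
})

test_that("labels are deterministic for identical input", {
  set.seed(46)
  emb <- matrix(rnorm(500 * 2), ncol = 2)
  a <- suppressWarnings(cluster_conformations(emb, min_cluster_size = 25))
  b <- suppressWarnings(cluster_conformations(emb, min_cluster_size = 25))
  expect_identical(a$labels, b$labels)
})

test_that("landscape recovers the planted three-family mixture", {
  dm <- demo_micelle_trajectory(n_frames = 60, seed = 47)
  land <- conformation_landscape(dm$ensemble, seed = 42)
  expect_equal(land$n_clusters, 3)
  truth <- planted_family_labels(dm$ground_truth, land$row_index)
  expect_gte(ari(land$labels, truth), 0.9)
  expect_lt(land$noise_fraction, 0.08)
  occ <- sort(land$fractions[names(land$fractions) != "noise"],
              decreasing = TRUE)
  expect_true(all(abs(occ - c(50, 30, 20)) <= 3))
  expect_equal(sum(land$fractions), 100, tolerance = 1e-6)
  # determinism of labels for the same seed
  land2 <- conformation_landscape(dm$ensemble, seed = 42)
  expect_identical(land$labels, land2$labels)
})

test_that("medoids minimize within-cluster summed feature distance", {
  dm <- demo_micelle_trajectory(n_frames = 20, seed = 48)
  land <- conformation_landscape(dm$ensemble, seed = 42)
  for (i in seq_len(nrow(land$medoids))) {
    k <- land$medoids$cluster[i]
    rows <- which(land$labels == k)
    dm_k <- as.matrix(stats::dist(land$features[rows, , drop = FALSE]))
    best <- rows[which.min(rowSums(dm_k))]
    expect_equal(land$medoids$row[i], best)
    expect_false(land$medoids$row[i] %in% which(land$labels == -1L))
  }
  # medoid structures are written as PDB files
  dir <- withr::local_tempdir()
  paths <- write_medoids(land, dm$ensemble, dir)
  expect_true(all(file.exists(file.path(
    dir, sprintf("medoid_cluster%d.pdb", land$medoids$cluster)))))
})

test_that("cluster localization orders planted depths correctly", {
  # families differ in MA extension: extended-MA chains reach deepest, so
  # their mass-weighted mean intrinsic distance is the most negative
  dm <- demo_micelle_trajectory(n_frames = 30, seed = 49)
  land <- conformation_landscape(dm$ensemble, seed = 42)
  loc <- localize_clusters(land, dm$ensemble,
                           frames = sort(unique(land$row_index$frame))[1:2],
                           grid_resolution = 128, n_mc = 2e4)
  truth <- planted_family_labels(dm$ground_truth, land$row_index)
  # map each cluster to its dominant planted family
  fam_of_cluster <- sapply(sort(unique(land$labels[land$labels > 0])),
                           function(k) {
    names(which.max(table(truth[land$labels == k])))
  })
  g_ext <- paste0("cluster", which(fam_of_cluster == "3"))
  g_col <- paste0("cluster", which(fam_of_cluster == "1"))
  # fraction of a cluster's mass found deep in the core (d_I <= -6 A):
  # extended-MA chains span the core, collapsed-MA chains hug the interface
  deep_frac <- function(g) {
    tot <- 0; deep <- 0
    for (p in loc$per_frame) {
      gi <- match(g, p$groups)
      if (is.na(gi)) next
      h <- p$mass_hist[, gi, 1]
      tot <- tot + sum(h)
      deep <- deep + sum(h[p$profile$d_hi[p$profile$group == g] <= -6])
    }
    deep / tot
  }
  expect_gt(deep_frac(g_ext), deep_frac(g_col) + 0.05)
  # partition identity: single grouping equals the union profile
  expect_true(all(c("d_mid", "group", "density") %in% names(loc$profile)))
})
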