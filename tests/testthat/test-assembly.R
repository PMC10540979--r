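two_bead_ensemble <- function(gap, box = c(60, 60, 60)) {
  # two 1-monomer-like polymers built from full diblock chains collapsed to
  # a controlled closest-approach distance along x
  sp <- build_polymer_spec("diblock")
  gm <- generate_micelle(sp, n_polymers = 2, R_core = 10, corona_span = 8,
                         noise_sigma = 0, seed = 1, box = box)
  ens <- gm$ensemble
  # translate polymer 2 so the pair's closest heavy atoms sit exactly `gap`
  # apart along the line between them
  p1 <- ens$frames[[1]]$positions[ens$molecule_atoms[["1"]], ]
  p2 <- ens$frames[[1]]$positions[ens$molecule_atoms[["2"]], ]
  dm <- as.matrix(stats::dist(rbind(p1, p2)))[seq_len(nrow(p1)),
                                              nrow(p1) + seq_len(nrow(p2))]
  w <- arrayInd(which.min(dm), dim(dm))
  v <- p2[w[2], ] - p1[w[1], ]
  shift <- v / sqrt(sum(v^2)) * (gap - min(dm))
  ens$frames[[1]]$positions[ens$molecule_atoms[["2"]], ] <-
    sweep(p2, 2, shift, "+")
  frame_ensemble(ens$frames, ens$atoms, ens$polymer_specs)
}

test_that("contact edges follow the cutoff threshold exactly", {
  ens <- two_bead_ensemble(gap = 4.0)
  expect_true(polymer_contact_graph(ens, 1, cutoff = 4.5)["1", "2"])
  expect_false(polymer_contact_graph(ens, 1, cutoff = 3.5)["1", "2"])
})

test_that("contact graph equals the all-pairs brute-force oracle", {
  for (seed in 1:3) {
    mm <- generate_multi_micelle(build_polymer_spec("diblock"),
                                 sizes = c(4, 3, 3), seed = seed)
    got <- polymer_contact_graph(mm$ensemble, 1, 4.5)
    oracle <- bf_contact_adjacency(mm$ensemble, 1, 4.5)
    expect_identical(unname(got == TRUE), unname(oracle), info = seed)
  }
})

test_that("aggregates are connected components and respect transitivity", {
  # chain A-B-C where only A-B and B-C touch: one component
  sp <- build_polymer_spec("diblock")
  gm <- generate_micelle(sp, n_polymers = 3, seed = 2)
  agg <- identify_aggregates(gm$ensemble, 1, 4.5)
  g <- agg$graph
  expect_equal(max(agg$labels), 1L)
  # partition: sizes sum to the polymer count
  expect_equal(sum(agg$sizes), 3L)
})

test_that("aggregate identification is invariant to periodic wrapping", {
  mm <- generate_multi_micelle(build_polymer_spec("diblock"),
                               sizes = c(6, 4), seed = 3)
  ens <- mm$ensemble
  ref <- identify_aggregates(ens, 1, 4.5)
  box <- ens$frames[[1]]$box
  shifted <- ens
  shifted$frames[[1]]$positions <-
    (sweep(ens$frames[[1]]$positions, 2, box / 2, "+")) %% box[1]
  shifted <- frame_ensemble(shifted$frames, shifted$atoms,
                            shifted$polymer_specs)
  got <- identify_aggregates(shifted, 1, 4.5)
  # identical partition up to label permutation
  expect_equal(ari(unname(ref$labels), unname(got$labels)), 1)
  expect_equal(sort(got$sizes), sort(ref$sizes))
})

test_that("planted micelle sizes {14,6} are recovered and unwrapped geometry is whole", {
  mm <- generate_multi_micelle(build_polymer_spec("diblock"),
                               sizes = c(14, 6), seed = 4)
  agg <- identify_aggregates(mm$ensemble, 1, 4.5)
  expect_equal(sort(agg$sizes, decreasing = TRUE), c(14L, 6L))
  ac <- aggregate_coords(mm$ensemble, 1, agg, agg$largest)
  # unwrapped aggregate spans far less than the box: no split images
  expect_lt(max(apply(ac$positions, 2, function(x) diff(range(x)))),
            mm$ensemble$frames[[1]]$box[1] / 2)
})

test_that("polymer-weighted N_agg distribution matches hand-computed weights", {
  # frames alternating one 20-mer and a {14,6} split:
  # P(20) = 0.5, P(14) = 14/20/2 = 0.35, P(6) = 0.15
  sp <- build_polymer_spec("diblock")
  one <- generate_micelle(sp, n_polymers = 20, seed = 5, box = rep(240, 3),
                          center = rep(120, 3))$ensemble
  two <- generate_multi_micelle(sp, sizes = c(14, 6), separation = 120,
                                seed = 5)$ensemble
  frames <- list(one$frames[[1]], two$frames[[1]],
                 one$frames[[1]], two$frames[[1]])
  ens <- frame_ensemble(frames, one$atoms, one$polymer_specs)
  nd <- nagg_distribution(ens, 4.5)
  expect_equal(nd$prob[["20"]], 0.5)
  expect_equal(nd$prob[["14"]], 0.35)
  expect_equal(nd$prob[["6"]], 0.15)
  expect_equal(sum(nd$prob), 1, tolerance = 1e-9)
  expect_equal(sum(nd$prob_unweighted), 1, tolerance = 1e-9)
  # largest-aggregate statistics over the alternating frames
  expect_equal(nd$largest_mean, mean(c(20, 14, 20, 14)))
  # empty frame selection errors
  expect_error(nagg_distribution(ens, 4.5, integer(0)), "empty")
})

test_that("single stable micelle gives a delta distribution", {
  gm <- tiny_micelle(n_polymers = 8, seed = 6)
  tr <- make_trajectory(gm$ensemble, n_frames = 10, seed = 7)$ensemble
  nd <- nagg_distribution(tr, 4.5)
  expect_equal(names(nd$prob), "8")
  expect_equal(nd$largest_mean, 8)
  expect_equal(nd$largest_sd, 0)
})

test_that("burn-in estimation recovers a planted changepoint", {
  # constant series: already stationary
  expect_equal(estimate_burn_in(rep(20, 80), window = 10), 0L)
  # planted step at frame 50 of 200
  s <- c(rep(17, 50), rep(20, 150))
  b <- estimate_burn_in(s, window = 20, tolerance = 0.5)
  expect_lte(abs(b - 50), 20)
  # strictly increasing series: flagged fallback
  expect_warning(b2 <- estimate_burn_in(as.numeric(1:100), window = 10),
                 "fallback|plateau")
  expect_true(isTRUE(attr(b2, "fallback")))
  # series shorter than two windows is refused
  expect_error(estimate_burn_in(rep(1, 10), window = 8), "shorter")
})

test_that("partition and count conservation hold on every frame of a trajectory", {
  dm <- demo_micelle_trajectory(n_frames = 15, seed = 8)
  nd <- nagg_distribution(dm$ensemble, 4.5)
  npol <- length(dm$ensemble$polymer_ids)
  for (i in seq_along(nd$frames)) {
    expect_equal(sum(nd$nagg[[i]]), npol)
    expect_equal(sort(unique(nd$labels[[i]])), seq_along(nd$nagg[[i]]))
  }
})
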