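test_that("R_G and eccentricity match closed forms for a uniform ball", {
  set.seed(101)
  pts <- matrix(rnorm(3e5), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * 12 * runif(1e5)^(1 / 3)
  gm <- gyration_metrics(pts)
  expect_equal(gm$rg, 12 * sqrt(3 / 5), tolerance = 0.01)
  expect_lt(gm$eccentricity, 0.02)
  # exact identity: R_G^2 = sum of gyration eigenvalues
  expect_equal(gm$rg^2, sum(gm$eigenvalues), tolerance = 1e-10)
})

test_that("eccentricity of a uniform prolate ellipsoid matches analytic moments", {
  set.seed(102)
  pts <- matrix(rnorm(3e5), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(1e5)^(1 / 3)
  pts[, 3] <- pts[, 3] * 2                     # semi-axes (1, 1, 2)
  gm <- gyration_metrics(pts)
  expect_equal(gm$eccentricity, ellipsoid_eccentricity(1, 1, 2),
               tolerance = 0.01)
})

test_that("eccentricity is invariant under rigid rotation", {
  set.seed(103)
  pts <- matrix(rnorm(600), ncol = 3) %*% diag(c(1, 2, 3))
  m <- runif(200, 1, 20)
  g1 <- gyration_metrics(pts, m)
  R <- micelletools:::random_rotation()
  g2 <- gyration_metrics(pts %*% t(R), m)
  expect_equal(g1$eccentricity, g2$eccentricity, tolerance = 1e-8)
  expect_equal(g1$rg, g2$rg, tolerance = 1e-8)
})

test_that("shape_of_aggregate summarizes per-frame metrics of the largest micelle", {
  dm <- demo_micelle_trajectory(n_frames = 6, seed = 21)
  sh <- shape_of_aggregate(dm$ensemble)
  expect_equal(nrow(sh$per_frame), 6)
  expect_true(all(sh$per_frame$rg > 0))
  expect_true(all(sh$per_frame$eccentricity >= 0 &
                    sh$per_frame$eccentricity <= 1))
  expect_true(all(diff(t(as.matrix(sh$per_frame[, c("ev1", "ev2", "ev3")]))) <= 0))
  expect_error(shape_of_aggregate(dm$ensemble, stationary_range = integer(0)),
               "empty")
})

test_that("radial density: single-particle bookkeeping is exact", {
  # one water at 10.5 A from a tiny micelle would be awkward; instead place
  # a single off-center atom and check its bin and density value directly
  gm <- tiny_micelle(n_polymers = 3, seed = 22, noise_sigma = 0)
  ens <- gm$ensemble
  com0 <- colMeans(ens$frames[[1]]$positions)
  # add one water oxygen exactly 10.5 A from the aggregate COM... the COM
  # shifts by adding mass-weighted positions only for polymer atoms, so the
  # water does not move the aggregate COM used for binning
  wxyz <- matrix(0, 1, 3)
  rd0 <- radial_density(ens, components = "MA", bin_width = 1)
  agg <- identify_aggregates(ens, 1, 4.5)
  ac <- aggregate_coords(ens, 1, agg, 1)
  m <- ens$atoms$mass[ac$atom_index]
  com <- colSums(ac$positions * m) / sum(m)
  wxyz[1, ] <- com + c(10.5, 0, 0)
  ens2 <- frame_ensemble(
    list(list(positions = rbind(ens$frames[[1]]$positions, wxyz),
              box = ens$frames[[1]]$box)),
    rbind(ens$atoms[, c("name", "element", "mass", "molecule_id", "role")],
          data.frame(name = "OW", element = "O", mass = 18.015,
                     molecule_id = max(ens$atoms$molecule_id) + 1L,
                     role = "water")),
    ens$polymer_specs)
  rd <- radial_density(ens2, components = "water", bin_width = 1)
  p <- rd$profile
  hit <- p[p$density > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$r_lo, 10)
  expect_equal(hit$density,
               18.015 * micelletools:::AMU_PER_A3_TO_G_CM3 / hit$shell_volume)
})

test_that("density conservation: sum(density * shell volume) recovers the mass", {
  dm <- demo_micelle_trajectory(n_frames = 4, water = TRUE, seed = 23)
  rd <- radial_density(dm$ensemble, bin_width = 2)
  p <- rd$profile
  for (comp in unique(p$component)) {
    tot <- sum(p$density[p$component == comp] *
                 p$shell_volume[p$component == comp]) /
      micelletools:::AMU_PER_A3_TO_G_CM3
    expect_equal(tot, unname(rd$mean_mass_in_range[comp]),
                 tolerance = 1e-6, info = comp)
  }
})

test_that("radial profile of a uniformly filled ball is flat", {
  gm <- tiny_micelle(n_polymers = 1, seed = 24)
  ens <- gm$ensemble
  agg <- identify_aggregates(ens, 1, 4.5)
  ac <- aggregate_coords(ens, 1, agg, 1)
  m <- ens$atoms$mass[ac$atom_index]
  com <- colSums(ac$positions * m) / sum(m)
  set.seed(24)
  n <- 2e5
  ball <- sweep(micelletools:::runif_ball(n, 15), 2, com, "+")
  ens2 <- frame_ensemble(
    list(list(positions = rbind(ens$frames[[1]]$positions, ball),
              box = ens$frames[[1]]$box)),
    rbind(ens$atoms[, c("name", "element", "mass", "molecule_id", "role")],
          data.frame(name = "OW", element = "O", mass = 18.015,
                     molecule_id = max(ens$atoms$molecule_id) + seq_len(n),
                     role = "water")),
    ens$polymer_specs)
  rd <- radial_density(ens2, components = "water", bin_width = 2,
                       r_max = 15, mode = "number")
  p <- rd$profile
  rho0 <- n / (4 / 3 * pi * 15^3)
  inner <- p[p$r_lo >= 4 & p$r_hi <= 14, ]
  expect_true(all(abs(inner$density - rho0) / rho0 < 0.03))
})

test_that("planted micelle profile orders MA inside, EO in the corona, water outside", {
  gm <- tiny_micelle(n_polymers = 12, seed = 24)
  ens <- add_water(gm$ensemble, shell_thickness = 8, density = 0.003,
                   seed = 25)
  rd <- radial_density(ens, bin_width = 2)
  p <- rd$profile
  mean_r <- sapply(c("MA", "EO", "water"), function(comp) {
    q <- p[p$component == comp, ]
    sum(q$r_mid * q$density) / sum(q$density)
  })
  expect_lt(mean_r["MA"], mean_r["EO"])
  expect_lt(mean_r["EO"], mean_r["water"])
})

test_that("core report recovers planted end-out fraction and core counts", {
  sp <- build_polymer_spec("triblock_MA_terminated")
  gm <- generate_micelle(sp, n_polymers = 20, end_out_fraction = 0.2,
                         noise_sigma = 0, seed = 25)
  cr <- core_report(gm$ensemble)
  expect_equal(cr$end_out_fraction, 0.2, tolerance = 1e-12)
  # noisy fixture: within 5 percentage points
  gm2 <- generate_micelle(sp, n_polymers = 20, end_out_fraction = 0.2,
                          noise_sigma = 0.6, seed = 26)
  cr2 <- core_report(gm2$ensemble)
  expect_lt(abs(cr2$end_out_fraction - 0.2), 0.05)
  # no waters: hydration metrics are zero
  expect_equal(unname(cr$MA_H2O["mean"]), 0)
  expect_equal(unname(cr$EO_H2O["mean"]), 0)
})

test_that("planted core waters appear in core hydration counts", {
  gm <- tiny_micelle(n_polymers = 10, seed = 27)
  ens <- add_water(gm$ensemble, density = 0, core_waters = 30, seed = 2)
  cr <- core_report(ens)
  expect_gt(unname(cr$MA_H2O["mean"]), 0)
})

test_that("class contacts match the brute-force oracle and normalize to 1", {
  gm <- tiny_micelle("ring", n_polymers = 4, seed = 28)
  cc <- class_contacts(gm$ensemble, 4.5)
  oracle <- bf_ma_contacts(gm$ensemble, 1, 4.5)
  o_means <- tapply(oracle$count, oracle$class, mean)
  got <- setNames(cc$classes$raw, cc$classes$class)
  expect_equal(unname(got[names(o_means)]), as.numeric(o_means), tolerance = 1e-12)
  expect_equal(max(cc$classes$normalized), 1)
  # intermolecular-only: a single isolated polymer has zero contacts
  g1 <- tiny_micelle(n_polymers = 1, seed = 29)
  cc1 <- class_contacts(g1$ensemble, 4.5)
  expect_true(all(cc1$classes$raw == 0))
})

test_that("deepest MA class registers the most contacts in symmetric topologies", {
  for (topo in c("triblock_EO_terminated", "ring")) {
    gm <- tiny_micelle(topo, n_polymers = 12, seed = 30)
    cc <- class_contacts(gm$ensemble, 4.5)
    expect_equal(cc$classes$class[which.max(cc$classes$raw)], "MA6",
                 info = topo)
  }
})

test_that("carbonyl hydration matches brute force, honors the closed boundary", {
  gm <- tiny_micelle(n_polymers = 3, seed = 31)
  plan <- data.frame(polymer_id = c(1, 2), monomer = c(2, 7), count = c(3, 1))
  ens <- add_water(gm$ensemble, density = 0.001, shell_thickness = 6,
                   hydration_counts = plan, seed = 3)
  ch <- carbonyl_hydration(ens, 3.5)
  oracle <- bf_carbonyl_coordination(ens, 1, 3.5)
  o_means <- tapply(oracle$count, oracle$class, mean)
  got <- setNames(ch$classes$raw, ch$classes$class)
  expect_equal(unname(got[names(o_means)]), as.numeric(o_means), tolerance = 1e-12)
  # closed boundary: water exactly at the cutoff is included
  pos <- ens$frames[[1]]$positions
  sp1 <- ens$polymer_specs[["1"]]
  oc_atom <- ens$molecule_atoms[["1"]][sp1$carbonyl_oxygen_map[1]]
  far <- pos[oc_atom, ] + c(3.5, 0, 0)
  ens2 <- frame_ensemble(
    list(list(positions = rbind(pos, matrix(far, 1)),
              box = ens$frames[[1]]$box)),
    rbind(ens$atoms[, c("name", "element", "mass", "molecule_id", "role")],
          data.frame(name = "OW", element = "O", mass = 18.015,
                     molecule_id = max(ens$atoms$molecule_id) + 1L,
                     role = "water")),
    ens$polymer_specs)
  before <- bf_carbonyl_coordination(ens, 1, 3.5)
  after <- carbonyl_hydration(ens2, 3.5)
  cls1 <- sp1$equivalence_classes[1]
  b <- mean(before$count[before$class == cls1])
  a <- after$classes$raw[after$classes$class == cls1]
  n_in_class <- sum(before$class == cls1)
  expect_equal(a, b + 1 / n_in_class, tolerance = 1e-12)
  # planted most-hydrated class normalizes to 1
  most <- ch$classes$class[which.max(ch$classes$raw)]
  expect_equal(ch$classes$normalized[ch$classes$class == most], 1)
})

test_that("a spec without carbonyl map is refused for hydration analysis", {
  gm <- tiny_micelle(n_polymers = 2, seed = 32)
  ens <- gm$ensemble
  ens$polymer_specs[["1"]]$carbonyl_oxygen_map[] <- NA_integer_
  expect_error(carbonyl_hydration(ens), "carbonyl")
})
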