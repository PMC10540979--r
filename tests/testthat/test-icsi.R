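# Fabricate an ensemble whose largest aggregate's MA heavy atoms sit at
# radii r_fun(direction) around a known center; EO beads outside. Uses one
# many-polymer micelle's topology but overrides positions.
surface_fixture <- function(r_fun, n_polymers = 20, seed = 1, center = 60,
                            box = 120) {
  sp <- build_polymer_spec("diblock")
  gm <- generate_micelle(sp, n_polymers = n_polymers, seed = seed,
                         box = rep(box, 3), center = rep(center, 3))
  ens <- gm$ensemble
  set.seed(seed + 1000)
  comp <- ens$atoms$component
  n <- nrow(ens$frames[[1]]$positions)
  # Antipodal direction pairs within every (component, mass) group, with
  # pair-equal radii (and even r_fun), put the aggregate COM exactly at the
  # declared center.
  dirs <- matrix(0, n, 3)
  r <- numeric(n)
  for (g in unique(paste(comp, ens$atoms$mass))) {
    idx <- which(paste(comp, ens$atoms$mass) == g)
    k <- length(idx)
    stopifnot(k %% 2 == 0)
    h <- matrix(rnorm(3 * k / 2), ncol = 3)
    h <- h / sqrt(rowSums(h^2))
    dirs[idx, ] <- rbind(h, -h)
    if (startsWith(g, "MA")) {
      r[idx] <- r_fun(dirs[idx, , drop = FALSE])
    } else {
      rh <- 25 + 5 * runif(k / 2)
      r[idx] <- c(rh, rh)
    }
  }
  ens$frames[[1]]$positions <- dirs * r + center
  frame_ensemble(ens$frames, ens$atoms, ens$polymer_specs)
}

test_that("spherical anchor sets reproduce the sphere exactly", {
  ens <- surface_fixture(function(d) 15)
  surf <- build_surface(ens, 1, grid_resolution = 256)
  expect_true(all(abs(surf$s - 15) <= 0.1))
  # intrinsic distance equals r - 15 for arbitrary probes
  set.seed(2)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rr <- runif(100, 2, 30)
  probes <- sweep(u * rr, 2, surf$com, "+")
  expect_true(all(abs(intrinsic_distance(probes, surf) - (rr - 15)) <= 0.2))
  # particle at radius 10 has d_I = -5
  p10 <- sweep(u[1:5, ] * 10, 2, surf$com, "+")
  expect_equal(intrinsic_distance(p10, surf), rep(-5, 5), tolerance = 0.02)
  # area of the sphere, and the exact halving under doubled n_agg
  expect_equal(surf$area, 4 * pi * 15^2, tolerance = 0.01)
  expect_equal(area_per_polymer(surf, 20), surf$area / 20)
  expect_equal(area_per_polymer(surf, 40), area_per_polymer(surf, 20) / 2)
})

test_that("grid refinement tightens the spherical limit", {
  ens <- surface_fixture(function(d) 15)
  coarse <- build_surface(ens, 1, grid_resolution = 64)
  fine <- build_surface(ens, 1, grid_resolution = 256)
  # anchors lie exactly on the sphere, so both grids are near-exact; the
  # finer grid cannot be worse
  expect_lte(max(abs(fine$s - 15)), max(abs(coarse$s - 15)) + 1e-12)
})

test_that("anchors equal the brute-force per-cell argmax on a rough sphere", {
  r_fun <- function(d) 15 + 1.5 * sin(2 * acos(pmin(pmax(d[, 3], -1), 1))) *
    cos(3 * atan2(d[, 2], d[, 1]))
  ens <- surface_fixture(r_fun, seed = 3)
  surf <- build_surface(ens, 1, grid_resolution = 128)
  # brute force: for every cell, the outermost MA heavy atom
  agg <- identify_aggregates(ens, 1, 4.5)
  ac <- aggregate_coords(ens, 1, agg, agg$largest)
  m <- ens$atoms$mass[ac$atom_index]
  com <- colSums(ac$positions * m) / sum(m)
  sel <- ens$atoms$component[ac$atom_index] == "MA"
  xyz <- ac$positions[sel, , drop = FALSE]
  d <- sweep(xyz, 2, com)
  r <- sqrt(rowSums(d^2))
  cells <- micelletools:::grid_cell_of(surf$grid, d / r)
  for (c0 in unique(cells)) {
    expect_equal(surf$s[c0], max(r[cells == c0]), tolerance = 1e-9)
  }
})

test_that("a single displaced anchor affects only its locality", {
  ens <- surface_fixture(function(d) 15, seed = 4)
  pos <- ens$frames[[1]]$positions
  ma_idx <- which(ens$atoms$component == "MA")
  probe <- ma_idx[1]
  dirp <- pos[probe, ] - 60
  dirp <- dirp / sqrt(sum(dirp^2))
  ens$frames[[1]]$positions[probe, ] <- 60 + dirp * 20
  ens2 <- frame_ensemble(ens$frames, ens$atoms, ens$polymer_specs)
  surf <- build_surface(ens2, 1, grid_resolution = 128)
  far <- abs(surf$s - 15) > 0.5
  # the perturbed cells are the one holding the displaced anchor (plus
  # possibly empty-fill neighbors); all must be near it angularly
  cell_dirs <- local({
    g <- surf$grid
    iz <- ((seq_len(g$n_cells) - 1) %% g$n_z) + 1
    ip <- ((seq_len(g$n_cells) - 1) %/% g$n_z) + 1
    z <- (g$z_edges[iz] + g$z_edges[iz + 1]) / 2
    phi <- (g$phi_edges[ip] + g$phi_edges[ip + 1]) / 2
    cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  })
  ang <- acos(pmin(pmax(cell_dirs %*% dirp, -1), 1))
  expect_true(all(ang[far] < 0.6))
  expect_gt(max(surf$s[far]), 19)
})

test_that("intrinsic distances are rotation invariant within grid tolerance", {
  r_fun <- function(d) 15 + 1.2 * d[, 3]^2
  ens <- surface_fixture(r_fun, seed = 5)
  surf <- build_surface(ens, 1, grid_resolution = 256)
  set.seed(6)
  probes <- sweep(micelletools:::runif_ball(200, 22), 2, surf$com, "+")
  d1 <- intrinsic_distance(probes, surf)
  R <- micelletools:::random_rotation()
  rot <- function(x) sweep(sweep(x, 2, surf$com) %*% t(R), 2, surf$com, "+")
  ens2 <- ens
  ens2$frames[[1]]$positions <- rot(ens$frames[[1]]$positions)
  ens2 <- frame_ensemble(ens2$frames, ens2$atoms, ens2$polymer_specs)
  surf2 <- build_surface(ens2, 1, grid_resolution = 256)
  d2 <- intrinsic_distance(rot(probes), surf2)
  # tolerance: grid discretization of a surface with O(1 A) angular slope
  expect_lt(stats::median(abs(d1 - d2)), 0.2)
  expect_lt(max(abs(d1 - d2)), 1.2)
})

test_that("rough-sphere area matches a dense triangulation oracle", {
  r_fun <- function(d) 15 + 1.5 * sin(2 * acos(pmin(pmax(d[, 3], -1), 1))) *
    cos(3 * atan2(d[, 2], d[, 1]))
  ens <- surface_fixture(r_fun, seed = 7)
  surf <- build_surface(ens, 1, grid_resolution = 256)
  # oracle: dense triangulated area of the analytic surface r = f(theta,phi)
  f <- function(theta, phi) {
    d <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    r_fun(d)
  }
  nt <- 400; np <- 800
  th <- seq(0, pi, length.out = nt + 1)
  ph <- seq(-pi, pi, length.out = np + 1)
  A <- 0
  TH <- matrix(rep(th, np + 1), nt + 1, np + 1)
  PH <- matrix(rep(ph, each = nt + 1), nt + 1, np + 1)
  Rm <- f(as.vector(TH), as.vector(PH))
  X <- array(c(Rm * sin(TH) * cos(PH), Rm * sin(TH) * sin(PH),
               Rm * cos(TH)), c(nt + 1, np + 1, 3))
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    sqrt(sum(w^2)) / 2
  }
  for (i in seq_len(nt)) for (j in seq_len(np)) {
    p1 <- X[i, j, ]; p2 <- X[i + 1, j, ]; p3 <- X[i, j + 1, ]
    p4 <- X[i + 1, j + 1, ]
    A <- A + tri_area(p1, p2, p3) + tri_area(p2, p4, p3)
  }
  expect_equal(surf$area, A, tolerance = 0.02)
  # tilt-corrected area never undershoots the inscribed sphere of min s
  expect_gte(surf$area, 4 * pi * min(surf$s)^2 * 0.99)
})

test_that("too few core atoms and aspherical aggregates are refused", {
  gm <- tiny_micelle(n_polymers = 2, seed = 8)
  expect_error(build_surface(gm$ensemble, 1, grid_resolution = 4096),
               "coarser grid")
  ens <- surface_fixture(function(d) 15, seed = 9)
  expect_error(build_surface(ens, 1, max_eccentricity = 1e-6),
               "star-convex")
})

test_that("intrinsic density: uniform core fill is flat and mass is conserved", {
  ens <- surface_fixture(function(d) 15, seed = 10)
  # replace water-free fixture by adding a uniform ball of probes as water
  agg <- identify_aggregates(ens, 1, 4.5)
  ac <- aggregate_coords(ens, 1, agg, agg$largest)
  m <- ens$atoms$mass[ac$atom_index]
  com <- colSums(ac$positions * m) / sum(m)
  set.seed(11)
  n <- 5e4
  ball <- sweep(micelletools:::runif_ball(n, 15), 2, com, "+")
  ens2 <- frame_ensemble(
    list(list(positions = rbind(ens$frames[[1]]$positions, ball),
              box = ens$frames[[1]]$box)),
    rbind(ens$atoms[, c("name", "element", "mass", "molecule_id", "role")],
          data.frame(name = "OW", element = "O", mass = 18.015,
                     molecule_id = max(ens$atoms$molecule_id) + seq_len(n),
                     role = "water")),
    ens$polymer_specs)
  ga <- rep(NA_character_, nrow(ens2$atoms))
  ga[ens2$atoms$role == "water"] <- "probe"
  ip <- intrinsic_density(ens2, group_assignments = ga, bin_width = 2,
                          d_range = c(-14, 4), grid_resolution = 256,
                          n_mc = 2e5, seed = 12, mode = "number")
  p <- ip$profile
  rho0 <- n / (4 / 3 * pi * 15^3)
  core_bins <- p[p$d_hi <= -2, ]
  expect_true(all(abs(core_bins$density - rho0) / rho0 < 0.05))
  # conservation against the measured Monte-Carlo shell volumes
  tot <- sum(p$density * ip$shell_volumes[, 1])
  expect_equal(tot, unname(ip$mass_in_range[1, "probe"]), tolerance = 1e-6)
  # >= 99% of core-planted mass sits at negative intrinsic distance
  di <- intrinsic_distance(ball, build_surface(ens2, 1,
                                               grid_resolution = 256))
  expect_gte(mean(di < 0), 0.99)
})

test_that("partition identity: one group equals the total profile", {
  dm <- demo_micelle_trajectory(n_frames = 2, seed = 13)
  ens <- dm$ensemble
  ga_all <- rep(NA_character_, nrow(ens$atoms))
  ga_all[ens$atoms$role == "polymer"] <- "all"
  ip1 <- intrinsic_density(ens, group_assignments = ga_all, bin_width = 2,
                           stationary_range = 1, n_mc = 2e4, seed = 14)
  ip2 <- intrinsic_density(ens, bin_width = 2, stationary_range = 1,
                           n_mc = 2e4, seed = 14)
  # default grouping covers polymers + water oxygens; with no water the two
  # agree bin by bin
  expect_equal(ip1$profile$density, ip2$profile$density, tolerance = 1e-12)
})

test_that("core membership via d_I < 0 agrees with planted membership", {
  sp <- build_polymer_spec("diblock")
  gm <- generate_micelle(sp, n_polymers = 40, seed = 15)
  ens <- gm$ensemble
  surf <- build_surface(ens, 1, grid_resolution = 128)
  ctr <- unlist(gm$ground_truth$interface[1, c("center_x", "center_y",
                                               "center_z")])
  agree <- 0; tot <- 0
  for (id in ens$polymer_ids) {
    mc <- monomer_coms(ens, 1, id)
    planted <- sqrt(rowSums(sweep(mc, 2, ctr)^2)) <
      gm$ground_truth$interface$R_core[1]
    got <- intrinsic_distance(mc, surf) < 0
    agree <- agree + sum(planted == got)
    tot <- tot + length(planted)
  }
  expect_gte(agree / tot, 0.98)
})
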