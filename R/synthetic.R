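#' Synthetic micelle generation with planted ground truth
#'
#' These generators emulate the statistical structure that the analysis
#' stages assume — a hydrophobic MA core of given radius, a hydrated EO
#' corona, per-polymer conformational families, aggregate memberships, and
#' hydration shells — without any physical realism (no energies, no
#' dynamics). Every generated quantity of interest is recorded in a
#' `ground_truth` object so that analyses can be validated by planted-value
#' recovery.
#'
#' Conformational families are parameterized by two scalars, the MA-block and
#' EO-block extension fractions, which is exactly the axis along which
#' clustered conformations in micelles differ (relative extension of the
#' hydrophobic and hydrophilic blocks):
#' \itemize{
#'   \item `collapsed_MA`: compact MA block, extended EO corona arm;
#'   \item `intermediate`: intermediate extensions;
#'   \item `extended_MA`: extended MA block spanning the core, compact EO.
#' }
#'
#' @name synthetic_micelles
NULL

.FAMILIES <- list(
  collapsed_MA = list(f_MA = 0.28, f_EO = 0.88),
  intermediate = list(f_MA = 0.55, f_EO = 0.60),
  extended_MA  = list(f_MA = 0.85, f_EO = 0.35)
)

default_family_mix <- function() {
  c(collapsed_MA = 0.5, intermediate = 0.3, extended_MA = 0.2)
}

# Largest-remainder apportionment of n items to proportions p (sums to n).
apportion <- function(n, p) {
  q <- n * p / sum(p)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(q - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

# Per-monomer target radii for one polymer chain.
# Block geometry: terminal MA blocks dive from the interface to
# R_core - span with the free end deepest; internal MA blocks (ring,
# EO-terminated) follow a tent profile, deepest mid-block; EO blocks extend
# outward into the corona (tent-shaped when internal/cyclic). An "end-out"
# polymer has one terminal MA block reflected into the corona.
chain_radii <- function(spec, fam, R_core, corona_span, bond_length, end_out) {
  f_MA <- fam$f_MA; f_EO <- fam$f_EO
  radii <- numeric(spec$n_monomers)
  blocks <- spec$blocks
  terminal_MA <- which(blocks$label == "MA" &
                         (seq_len(nrow(blocks)) %in% c(1L, nrow(blocks))) &
                         !spec$cyclic)
  out_block <- if (end_out && length(terminal_MA)) terminal_MA[length(terminal_MA)] else 0L
  pos <- 1L
  for (b in seq_len(nrow(blocks))) {
    L <- blocks$n[b]
    a <- seq_len(L)
    if (blocks$label[b] == "MA") {
      span <- f_MA * min(L * bond_length, R_core - 2)
      if (b == out_block) {
        # planted in the corona: same profile, reflected outside the core
        prof <- if (b == 1L) (L - a + 1) / L else a / L
        r <- R_core + 3 + span * prof
      } else if (b %in% terminal_MA) {
        prof <- if (b == 1L) (L - a + 1) / L else a / L  # free end deepest
        r <- R_core - span * prof
      } else {
        r <- R_core - span * sin(pi * (a - 0.5) / L)    # internal: tent
      }
    } else {
      span <- f_EO * corona_span
      internal <- spec$cyclic || (b > 1L && b < nrow(blocks))
      if (internal) {
        r <- R_core + span * sin(pi * a / (L + 1))
      } else if (b == 1L) {
        r <- R_core + span * (L - a + 1) / L            # free end outermost
      } else {
        r <- R_core + span * a / L
      }
    }
    radii[pos:(pos + L - 1L)] <- r
    pos <- pos + L
  }
  radii
}

# Tangential offsets of the monomer chain within the plane perpendicular to
# the polymer's radial direction: a gentle helix for linear chains, a closed
# ellipse for rings. Deterministic, so a conformational family has one
# template and within-family variation comes only from declared noise.
chain_tangentials <- function(spec, helix_radius = 2.5, helix_period = 18,
                              ring_radius = 3.0) {
  n <- spec$n_monomers
  if (spec$cyclic) {
    chi <- 2 * pi * (seq_len(n) - 0.5) / n
    cbind(ring_radius * cos(chi), ring_radius * sin(chi))
  } else {
    chi <- 2 * pi * (seq_len(n) - 1) / helix_period
    cbind(helix_radius * cos(chi), helix_radius * sin(chi))
  }
}

# Build bead coordinates for one polymer given monomer COM targets.
# Bead offsets are mass-balanced so the monomer COM is exact before noise.
place_beads <- function(spec, mono_xyz, e1, e2, noise_sigma) {
  pos <- matrix(0, spec$n_atoms, 3L)
  for (m in seq_len(spec$n_monomers)) {
    idx <- spec$monomer_atom_map[[m]]
    c0 <- mono_xyz[m, ]
    mlab <- spec$monomer_label[m]
    if (mlab == "MA") {
      d_bb <- 0.9 * e1; d_oc <- 1.2 * e2
      mm <- spec$atom_mass[idx]
      d_cm <- -(mm[1] * d_bb + mm[2] * d_oc) / mm[3]
      off <- rbind(d_bb, d_oc, d_cm)
    } else {
      d_c <- 0.7 * e1
      mm <- spec$atom_mass[idx]
      off <- rbind(d_c, -d_c * mm[1] / mm[2])
    }
    pos[idx, ] <- sweep(off, 2L, c0, "+")
  }
  pos + matrix(stats::rnorm(length(pos), sd = noise_sigma), ncol = 3L)
}

build_polymer_positions <- function(spec, fam, u, R_core, corona_span,
                                    bond_length, noise_sigma, end_out) {
  radii <- chain_radii(spec, fam, R_core, corona_span, bond_length, end_out)
  tang <- chain_tangentials(spec)
  tb <- tangent_basis(u)
  mono <- outer(radii, u) +
    tang[, 1] %o% tb$e1 + tang[, 2] %o% tb$e2
  place_beads(spec, mono, tb$e1, tb$e2, noise_sigma)
}

# Rigidly translate disconnected chains into contact so that the planted
# aggregate is single-linkage connected at `connect_cutoff`. Rigid moves
# preserve every per-polymer conformational feature. The coarse bead model
# is far sparser than an atomistic core, so connectivity is enforced rather
# than emergent.
enforce_connectivity <- function(pos_list, connect_cutoff = 3.6,
                                 contact_target = 2.8) {
  n <- length(pos_list)
  if (n < 2L) return(pos_list)
  repeat {
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d2 <- outer(rowSums(pos_list[[i]]^2), rowSums(pos_list[[j]]^2), "+") -
        2 * tcrossprod(pos_list[[i]], pos_list[[j]])
      if (min(d2) <= connect_cutoff^2) adj[i, j] <- adj[j, i] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    if (max(comp) == 1L) return(pos_list)
    main <- which.max(tabulate(comp))
    A <- do.call(rbind, pos_list[comp == main])
    other <- which(comp != main)[1L]
    oc <- comp[other]
    B <- do.call(rbind, pos_list[comp == oc])
    d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * tcrossprod(B, A)
    w <- arrayInd(which.min(d2), dim(d2))
    v <- A[w[2L], ] - B[w[1L], ]
    dmin <- sqrt(max(0, min(d2)))
    shift <- v / dmin * (dmin - contact_target)
    for (p in which(comp == oc))
      pos_list[[p]] <- sweep(pos_list[[p]], 2L, shift, "+")
  }
}

new_ground_truth <- function(membership, family, interface, end_out, seed) {
  structure(list(
    aggregate_membership = membership,   # list per frame: polymer_id -> id
    conformation_family = family,        # named character, per polymer
    interface = interface,               # data.frame(aggregate_id, R_core, amplitude)
    end_out = end_out,                   # named logical, per polymer
    seed = seed
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  sizes <- table(x$aggregate_membership[[1]])
  cat(sprintf("<ground_truth> %d frame(s); aggregates {%s}; families: %s; %d end-out\n",
              length(x$aggregate_membership),
              paste(sort(as.integer(sizes), decreasing = TRUE), collapse = ","),
              paste(sprintf("%s=%d", names(table(x$conformation_family)),
                            table(x$conformation_family)), collapse = ", "),
              sum(x$end_out)))
  invisible(x)
}

#' Generate one synthetic micelle with planted ground truth
#'
#' Places `n_polymers` chains of the given topology around a common center:
#' MA beads inside the core radius `R_core` (with roughness from placement
#' noise), EO beads in a corona shell, each polymer drawn from a
#' conformational family (see [synthetic_micelles]). Deterministic for a
#' fixed seed.
#'
#' @param spec a [polymer_spec]; all polymers share it.
#' @param n_polymers number of chains (>= 1).
#' @param R_core target core radius (Angstrom).
#' @param family_mix named proportions over families; must sum to 1.
#' @param end_out_fraction fraction of polymers planted with a terminal MA
#'   block in the corona (only meaningful for topologies with terminal MA
#'   blocks; exact counts by largest remainder).
#' @param noise_sigma Gaussian positional noise per bead coordinate (Angstrom).
#' @param corona_span maximal radial extent of a fully extended EO arm
#'   beyond the core (Angstrom).
#' @param bond_length contour length per monomer (Angstrom).
#' @param box orthorhombic box edges; default `max(147, 2*(R_core+corona_span+15))`.
#' @param center micelle center; default box middle.
#' @param seed integer seed; all randomness derives from it.
#' @param molecule_id_offset first polymer gets `molecule_id_offset + 1`.
#' @return `list(ensemble = <frame_ensemble>, ground_truth = <ground_truth>)`.
#' @examples
#' sp <- build_polymer_spec("diblock")
#' gm <- generate_micelle(sp, n_polymers = 8, seed = 1)
#' gm$ground_truth
#' @export
generate_micelle <- function(spec, n_polymers = 20, R_core = 18,
                             family_mix = default_family_mix(),
                             end_out_fraction = 0, noise_sigma = 0.6,
                             corona_span = 35, bond_length = 3.0,
                             box = NULL, center = NULL, seed = 1,
                             molecule_id_offset = 0L) {
  stopifnot(n_polymers >= 1, R_core > 0)
  if (abs(sum(family_mix) - 1) > 1e-8)
    stop("family_mix proportions must sum to 1", call. = FALSE)
  if (!all(names(family_mix) %in% names(.FAMILIES)))
    stop(sprintf("unknown families: %s", paste(
      setdiff(names(family_mix), names(.FAMILIES)), collapse = ", ")),
      call. = FALSE)
  has_terminal_MA <- !spec$cyclic &&
    any(spec$blocks$label[c(1L, nrow(spec$blocks))] == "MA")
  if (end_out_fraction > 0 && !has_terminal_MA)
    stop(sprintf("topology '%s' has no terminal MA block to plant end-out",
                 spec$topology_class), call. = FALSE)

  n_ma_beads <- n_polymers * sum(spec$monomer_label == "MA") * 3L
  if (n_ma_beads / (4 / 3 * pi * R_core^3) > 0.08)
    stop(sprintf(
      "impossible packing: %d MA beads in a %.1f A core exceeds the density limit",
      n_ma_beads, R_core), call. = FALSE)

  if (is.null(box)) box <- rep(max(147, 2 * (R_core + corona_span + 15)), 3L)
  if (is.null(center)) center <- box / 2

  local_seed(derive_seed(seed, "generate_micelle"), {
    fam_counts <- apportion(n_polymers, family_mix)
    fam_of <- sample(rep(names(family_mix), fam_counts))
    n_out <- round(end_out_fraction * n_polymers)
    out_flag <- rep(FALSE, n_polymers)
    if (n_out > 0) out_flag[sample.int(n_polymers, n_out)] <- TRUE

    rot <- random_rotation()
    dirs <- sphere_directions(n_polymers) %*% rot
    jitter <- matrix(stats::rnorm(3L * n_polymers, sd = 0.12), ncol = 3L)
    dirs <- dirs + jitter
    dirs <- dirs / sqrt(rowSums(dirs^2))

    pos_list <- vector("list", n_polymers)
    for (p in seq_len(n_polymers)) {
      pos_list[[p]] <- build_polymer_positions(
        spec, .FAMILIES[[fam_of[p]]], dirs[p, ], R_core, corona_span,
        bond_length, noise_sigma, out_flag[p])
    }
    pos_list <- enforce_connectivity(pos_list)
    pos_list <- lapply(pos_list, function(x) sweep(x, 2L, center, "+"))

    ids <- molecule_id_offset + seq_len(n_polymers)
    atoms <- data.frame(
      name = rep(spec$atom_name, n_polymers),
      element = rep(spec$atom_element, n_polymers),
      mass = rep(spec$atom_mass, n_polymers),
      molecule_id = rep(ids, each = spec$n_atoms),
      role = "polymer",
      stringsAsFactors = FALSE
    )
    specs <- stats::setNames(rep(list(spec), n_polymers), as.character(ids))
    ens <- frame_ensemble(
      list(list(positions = do.call(rbind, pos_list), box = box)),
      atoms, specs)

    membership <- list(stats::setNames(rep(1L, n_polymers), ids))
    gt <- new_ground_truth(
      membership,
      stats::setNames(fam_of, ids),
      data.frame(aggregate_id = 1L, R_core = R_core, amplitude = noise_sigma,
                 center_x = center[1], center_y = center[2], center_z = center[3]),
      stats::setNames(out_flag, ids),
      seed)
    list(ensemble = ens, ground_truth = gt)
  })
}

#' Generate several well-separated micelles in one box
#'
#' Micelle centers sit on a cubic grid with spacing `separation`, so every
#' pair of centers is at least `separation` apart under minimum image.
#'
#' @param spec a [polymer_spec].
#' @param sizes integer vector of aggregation numbers, one per micelle.
#' @param separation center-to-center spacing (Angstrom); must exceed
#'   `2 * (R_core + corona_span)` for unambiguous ground truth.
#' @param R_core,family_mix,noise_sigma,corona_span,bond_length,seed
#'   as in [generate_micelle].
#' @return `list(ensemble, ground_truth)` with aggregate ids `1..length(sizes)`.
#' @export
generate_multi_micelle <- function(spec, sizes, separation = 120,
                                   R_core = 18,
                                   family_mix = default_family_mix(),
                                   noise_sigma = 0.6, corona_span = 35,
                                   bond_length = 3.0, seed = 1) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  if (separation <= 2 * (R_core + corona_span))
    stop(sprintf(
      "separation %.1f A too small: needs > 2*(R_core + corona span) = %.1f A",
      separation, 2 * (R_core + corona_span)), call. = FALSE)
  k <- length(sizes)
  g <- ceiling(k^(1 / 3))
  box <- rep(max(147, g * separation), 3L)
  if (g * separation > box[1] + 1e-9)
    stop("box too small to hold all micelles at the requested separation",
         call. = FALSE)
  grid_idx <- as.matrix(expand.grid(x = 0:(g - 1), y = 0:(g - 1), z = 0:(g - 1)))
  centers <- (grid_idx[seq_len(k), , drop = FALSE] + 0.5) * separation
  # keep centers inside the (possibly larger) box
  centers <- centers %% box[1]

  parts <- vector("list", k)
  offset <- 0L
  for (a in seq_len(k)) {
    parts[[a]] <- generate_micelle(
      spec, n_polymers = sizes[a], R_core = R_core, family_mix = family_mix,
      noise_sigma = noise_sigma, corona_span = corona_span,
      bond_length = bond_length, box = box, center = centers[a, ],
      seed = derive_seed(seed, paste0("micelle", a)),
      molecule_id_offset = offset)
    offset <- offset + as.integer(sizes[a])
  }
  ens <- parts[[1]]$ensemble
  frames <- list(list(
    positions = do.call(rbind, lapply(parts, function(p)
      frame_positions(p$ensemble, 1L))),
    box = box))
  atoms <- do.call(rbind, lapply(parts, function(p) p$ensemble$atoms))
  specs <- do.call(c, lapply(parts, function(p) p$ensemble$polymer_specs))
  ens <- frame_ensemble(frames, atoms, specs)

  membership <- stats::setNames(
    rep(seq_len(k), sizes),
    unlist(lapply(parts, function(p) names(p$ground_truth$aggregate_membership[[1]])))
  )
  interface <- do.call(rbind, lapply(seq_len(k), function(a) {
    d <- parts[[a]]$ground_truth$interface
    d$aggregate_id <- a
    d
  }))
  gt <- new_ground_truth(
    list(membership),
    do.call(c, lapply(parts, function(p) p$ground_truth$conformation_family)),
    interface,
    do.call(c, lapply(parts, function(p) p$ground_truth$end_out)),
    seed)
  list(ensemble = ens, ground_truth = gt)
}

#' Add water to a synthetic configuration
#'
#' Bulk water oxygens are placed uniformly in a spherical shell just outside
#' each micelle's corona. Optionally, exact water counts are planted inside
#' the first hydration shell of chosen carbonyl oxygens (for
#' coordination-number oracles) and inside the core (for core-hydration
#' oracles). Waters are single-oxygen beads of mass 18.015 amu.
#'
#' @param ens a single-frame [frame_ensemble] (add water before
#'   [make_trajectory]).
#' @param shell_thickness bulk shell thickness beyond the corona (Angstrom).
#' @param density bulk number density (waters / Angstrom^3) in the shell;
#'   0 places no bulk water.
#' @param hydration_counts optional data.frame with columns `polymer_id`,
#'   `monomer`, `count`: plants `count` waters within the hydration shell of
#'   that MA monomer's carbonyl oxygen, away from all other carbonyls.
#' @param core_waters number of waters placed uniformly deep inside the
#'   first micelle's core.
#' @param hydration_cutoff hydration-shell radius used for planting (Angstrom).
#' @param cluster_cutoff contact cutoff used to locate micelle centers.
#' @param seed integer seed.
#' @return a new [frame_ensemble] including the water molecules.
#' @export
add_water <- function(ens, shell_thickness = 8, density = 0.004,
                      hydration_counts = NULL, core_waters = 0,
                      hydration_cutoff = 3.5, cluster_cutoff = 4.5, seed = 1) {
  stopifnot(density >= 0, shell_thickness >= 0)
  if (n_frames(ens) != 1L)
    stop("add_water expects a single-frame ensemble; add water before make_trajectory",
         call. = FALSE)
  box <- frame_box(ens, 1L)
  pos <- frame_positions(ens, 1L)

  agg <- identify_aggregates(ens, frame = 1L, cutoff = cluster_cutoff)
  labels <- agg$labels
  centers <- list(); radii <- list()
  for (a in sort(unique(labels))) {
    members <- as.integer(names(labels)[labels == a])
    coords <- do.call(rbind, lapply(members, function(id)
      polymer_coords(ens, 1L, id)))
    com <- colMeans(coords)
    centers[[a]] <- com
    radii[[a]] <- max(sqrt(rowSums(sweep(coords, 2L, com)^2)))
  }

  carbonyl_xyz <- do.call(rbind, lapply(as.character(ens$polymer_ids), function(id) {
    sp <- ens$polymer_specs[[id]]
    idx <- ens$molecule_atoms[[id]][stats::na.omit(sp$carbonyl_oxygen_map)]
    pos[idx, , drop = FALSE]
  }))

  local_seed(derive_seed(seed, "add_water"), {
    waters <- list()

    if (density > 0 && shell_thickness > 0) {
      for (a in seq_along(centers)) {
        r0 <- radii[[a]] + 1
        r1 <- r0 + shell_thickness
        nw <- round(density * 4 / 3 * pi * (r1^3 - r0^3))
        if (nw == 0) next
        u <- matrix(stats::rnorm(3L * nw), ncol = 3L)
        u <- u / sqrt(rowSums(u^2))
        r <- (stats::runif(nw, r0^3, r1^3))^(1 / 3)
        waters[[length(waters) + 1L]] <- sweep(u * r, 2L, centers[[a]], "+")
      }
    }

    if (!is.null(hydration_counts) && nrow(hydration_counts) > 0) {
      for (i in seq_len(nrow(hydration_counts))) {
        id <- as.character(hydration_counts$polymer_id[i])
        m <- hydration_counts$monomer[i]
        cnt <- hydration_counts$count[i]
        sp <- ens$polymer_specs[[id]]
        if (is.null(sp)) stop(sprintf("unknown polymer %s", id), call. = FALSE)
        if (sp$monomer_label[m] != "MA")
          stop(sprintf("hydration_counts references non-MA monomer %d of polymer %s",
                       m, id), call. = FALSE)
        oc <- pos[ens$molecule_atoms[[id]][sp$carbonyl_oxygen_map[m]], ]
        placed <- 0L; tries <- 0L
        pts <- matrix(0, cnt, 3L)
        while (placed < cnt && tries < 3000L) {
          tries <- tries + 1L
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- oc + u * stats::runif(1, 0.60, 0.97) * hydration_cutoff
          d_others <- sqrt(colSums((t(carbonyl_xyz) - cand)^2))
          d_self <- sqrt(sum((cand - oc)^2))
          if (sum(d_others <= hydration_cutoff + 0.05) == 1L &&
              d_self <= hydration_cutoff) {
            placed <- placed + 1L
            pts[placed, ] <- cand
          }
        }
        if (placed < cnt)
          stop(sprintf("could not plant %d waters near polymer %s monomer %d",
                       cnt, id, m), call. = FALSE)
        waters[[length(waters) + 1L]] <- pts
      }
    }

    if (core_waters > 0) {
      pts <- sweep(runif_ball(core_waters, 0.6 * max(1, radii[[1]] / 3)),
                   2L, centers[[1]], "+")
      waters[[length(waters) + 1L]] <- pts
    }

    if (length(waters) == 0L) return(ens)
    wxyz <- do.call(rbind, waters)
    nw <- nrow(wxyz)
    next_id <- max(ens$atoms$molecule_id) + 1L
    watoms <- data.frame(
      name = "OW", element = "O", mass = 18.015,
      molecule_id = next_id + seq_len(nw) - 1L, role = "water",
      stringsAsFactors = FALSE)
    frame_ensemble(
      list(list(positions = rbind(pos, wxyz), box = box)),
      rbind(ens$atoms[, c("name", "element", "mass", "molecule_id", "role")], watoms),
      ens$polymer_specs, timestep = ens$timestep)
  })
}

#' Canonical demo micelle trajectory
#'
#' The package's reference synthetic system: one micelle of 20 polymers
#' drawn from the three conformational families at 50/30/20% occupancy,
#' expanded into a trajectory. Structural (frozen) noise is kept small and
#' thermal (per-frame) jitter large, so that per-frame conformational
#' fluctuation — not per-polymer identity — dominates within-family
#' variation, as in an equilibrated trajectory.
#'
#' @param spec a [polymer_spec] (default: diblock).
#' @param n_polymers,n_frames system size.
#' @param noise_sigma frozen structural noise (Angstrom).
#' @param jitter_sigma per-frame thermal noise (Angstrom).
#' @param end_out_fraction see [generate_micelle].
#' @param water add a bulk hydration shell ([add_water]) when TRUE.
#' @param seed integer seed.
#' @return `list(ensemble, ground_truth)`.
#' @export
demo_micelle_trajectory <- function(spec = build_polymer_spec("diblock"),
                                    n_polymers = 20, n_frames = 200,
                                    noise_sigma = 0.1, jitter_sigma = 0.5,
                                    end_out_fraction = 0, water = FALSE,
                                    seed = 1) {
  gm <- generate_micelle(spec, n_polymers = n_polymers,
                         noise_sigma = noise_sigma,
                         end_out_fraction = end_out_fraction,
                         seed = derive_seed(seed, "demo_base"))
  ens <- gm$ensemble
  if (water)
    ens <- add_water(ens, seed = derive_seed(seed, "demo_water"))
  make_trajectory(ens, n_frames = n_frames, jitter_sigma = jitter_sigma,
                  ground_truth = gm$ground_truth,
                  seed = derive_seed(seed, "demo_traj"))
}

#' Expand a configuration into a jittered trajectory
#'
#' Frames are independent Gaussian perturbations of the base configuration.
#' An optional burn-in profile starts a declared number of polymers
#' dissociated (displaced far from the micelle) and merges them back at a
#' declared frame, planting a stationarity changepoint for burn-in
#' estimation. The box is enlarged if needed to keep dissociated chains
#' unambiguously separated under minimum image.
#'
#' @param ens a single-frame [frame_ensemble].
#' @param n_frames number of frames (>= 1).
#' @param jitter_sigma per-coordinate Gaussian noise (Angstrom); 0 gives
#'   identical frames.
#' @param burn_in_profile optional `list(n_dissociated, merge_frame)`:
#'   frames `1..merge_frame` have the last `n_dissociated` polymers
#'   dissociated; they are merged from frame `merge_frame + 1` on.
#' @param ground_truth optional [generate_micelle] ground truth to expand
#'   per frame (membership updated for the burn-in phase).
#' @param seed integer seed.
#' @return `list(ensemble, ground_truth)`; `ground_truth` is `NULL` when not
#'   supplied.
#' @export
make_trajectory <- function(ens, n_frames, jitter_sigma = 0.15,
                            burn_in_profile = NULL, ground_truth = NULL,
                            seed = 1) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0)
  base <- frame_positions(ens, 1L)
  box <- frame_box(ens, 1L)
  natoms <- nrow(base)
  pol_ids <- ens$polymer_ids

  merge_frame <- 0L
  diss_ids <- integer(0)
  pre <- base
  if (!is.null(burn_in_profile)) {
    k <- burn_in_profile$n_dissociated
    merge_frame <- burn_in_profile$merge_frame
    stopifnot(k >= 1, merge_frame >= 1, merge_frame < n_frames)
    # dissociate chains whose removal keeps the remaining contact graph
    # connected: peel leaves of a spanning tree of the base-frame graph
    adj <- polymer_contact_graph(ens, 1L)
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(adj, attr(adj, "min_dist"), 0), mode = "undirected",
      weighted = TRUE)
    diss_ids <- integer(0)
    for (i in seq_len(k)) {
      deg <- igraph::degree(igraph::mst(g))
      leaves <- as.integer(igraph::V(g)$name[deg == 1L])
      pick <- max(leaves)
      diss_ids <- c(diss_ids, pick)
      g <- igraph::delete_vertices(g, as.character(pick))
    }
    keep_idx <- unlist(ens$molecule_atoms[as.character(setdiff(pol_ids, diss_ids))])
    mic_com <- colMeans(base[keep_idx, , drop = FALSE])
    mic_rad <- max(sqrt(rowSums(sweep(base[keep_idx, , drop = FALSE], 2L, mic_com)^2)))
    dirs <- sphere_directions(max(k, 2L))[seq_len(k), , drop = FALSE]
    for (i in seq_len(k)) {
      idx <- ens$molecule_atoms[[as.character(diss_ids[i])]]
      chain <- unwrap_molecule(base[idx, , drop = FALSE], box)
      ccom <- colMeans(chain)
      ext <- max(sqrt(rowSums(sweep(chain, 2L, ccom)^2)))
      d <- mic_rad + ext + 20
      target <- mic_com + dirs[i, ] * d
      pre[idx, ] <- sweep(chain, 2L, target - ccom, "+")
      box <- pmax(box, 2 * (d + ext + 10))
    }
  }

  frames <- local_seed(derive_seed(seed, "make_trajectory"), {
    lapply(seq_len(n_frames), function(f) {
      b <- if (f <= merge_frame) pre else base
      p <- b + if (jitter_sigma > 0)
        matrix(stats::rnorm(3L * natoms, sd = jitter_sigma), ncol = 3L)
      else 0
      list(positions = p, box = box)
    })
  })

  out_ens <- frame_ensemble(frames, ens$atoms, ens$polymer_specs,
                            timestep = ens$timestep)
  gt <- NULL
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    base_mem <- ground_truth$aggregate_membership[[1]]
    mem <- lapply(seq_len(n_frames), function(f) {
      m <- base_mem
      if (f <= merge_frame && length(diss_ids)) {
        m[as.character(diss_ids)] <- max(base_mem) + seq_along(diss_ids)
      }
      m
    })
    gt$aggregate_membership <- mem
  }
  list(ensemble = out_ens, ground_truth = gt)
}
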