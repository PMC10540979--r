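#' Shape, density, core and per-class statistics
#'
#' Structural characterization of a micelle: mass-weighted gyration-tensor
#' shape metrics, component-resolved radial density profiles about the
#' aggregate center of mass, core composition and hydration, and
#' intermolecular contact / carbonyl hydration statistics pooled over
#' chemically-equivalent monomer classes.
#'
#' @name structure_metrics
NULL

# Resolve an aggregate selector ("largest" or an aggregate id) for a frame.
resolve_aggregate <- function(ens, frame, cutoff, aggregate_selector) {
  assignment <- identify_aggregates(ens, frame, cutoff)
  id <- if (identical(aggregate_selector, "largest")) assignment$largest
        else as.integer(aggregate_selector)
  aggregate_coords(ens, frame, assignment, id)
}

#' Gyration and inertia shape metrics of a point cloud
#'
#' Low-level kernel used by [shape_of_aggregate], exposed for validation
#' against closed forms. Computes the mass-weighted gyration tensor about
#' the center of mass, the radius of gyration `R_G = sqrt(trace)`, the
#' principal moments of inertia, and the eccentricity
#' `eps = 1 - I_min / I_avg` (0 for a sphere).
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param masses atom masses (amu); unit masses by default.
#' @return list with `rg`, `eigenvalues` (gyration, descending, A^2),
#'   `inertia` (principal moments, amu A^2), `eccentricity`.
#' @export
gyration_metrics <- function(positions, masses = rep(1, nrow(positions))) {
  stopifnot(nrow(positions) >= 1L, length(masses) == nrow(positions))
  w <- masses / sum(masses)
  com <- colSums(positions * w)
  x <- sweep(positions, 2L, com)
  S <- crossprod(x * w, x)                      # gyration tensor (A^2)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  rg <- sqrt(sum(diag(S)))
  r2 <- rowSums(x^2)
  I <- diag(sum(masses * r2), 3L) - crossprod(x * masses, x)  # inertia tensor
  Iev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  ecc <- 1 - Iev[1L] / mean(Iev)
  list(rg = rg, eigenvalues = ev, inertia = Iev, eccentricity = ecc)
}

#' Shape metrics of an aggregate over stationary frames
#'
#' Per frame, the selected aggregate is unwrapped and its mass-weighted
#' gyration tensor and principal moments of inertia computed; the radius of
#' gyration and eccentricity are then averaged over frames.
#'
#' @param ens a [frame_ensemble].
#' @param aggregate_selector `"largest"` (default) or an aggregate id.
#' @param cutoff contact cutoff used to identify aggregates (Angstrom).
#' @param stationary_range frames to analyse (default: all).
#' @return an object of class `shape_metrics` with per-frame values and
#'   summary statistics.
#' @export
shape_of_aggregate <- function(ens, aggregate_selector = "largest",
                               cutoff = 4.5, stationary_range = NULL) {
  frames <- stationary_range %||% seq_len(n_frames(ens))
  if (length(frames) == 0L) stop("empty frame selection", call. = FALSE)
  rows <- lapply(frames, function(f) {
    ac <- resolve_aggregate(ens, f, cutoff, aggregate_selector)
    gm <- gyration_metrics(ac$positions, ens$atoms$mass[ac$atom_index])
    data.frame(frame = f, rg = gm$rg, eccentricity = gm$eccentricity,
               ev1 = gm$eigenvalues[1], ev2 = gm$eigenvalues[2],
               ev3 = gm$eigenvalues[3], n_agg = length(ac$members))
  })
  pf <- do.call(rbind, rows)
  structure(list(
    per_frame = pf,
    rg_mean = mean(pf$rg), rg_sd = stats::sd(pf$rg),
    eccentricity_mean = mean(pf$eccentricity),
    eccentricity_sd = stats::sd(pf$eccentricity),
    nagg_mean = mean(pf$n_agg), nagg_sd = stats::sd(pf$n_agg)
  ), class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  sd0 <- function(v) if (is.na(v)) 0 else v
  cat(sprintf("<shape_metrics> %d frame(s)\n", nrow(x$per_frame)))
  cat(sprintf("  R_G = %.2f +/- %.2f A\n", x$rg_mean, sd0(x$rg_sd)))
  cat(sprintf("  eccentricity = %.3f +/- %.3f\n",
              x$eccentricity_mean, sd0(x$eccentricity_sd)))
  cat(sprintf("  N_agg = %.1f +/- %.1f\n", x$nagg_mean, sd0(x$nagg_sd)))
  invisible(x)
}

#' Component-resolved radial density profile
#'
#' Histograms component masses (MA, EO, water) by distance from the
#' aggregate center of mass (minimum image for atoms outside the unwrapped
#' aggregate), divides by spherical-shell volumes, and averages over frames.
#' Mass densities are in g/cm^3; a number-density mode (atoms/A^3) is
#' available.
#'
#' @param ens a [frame_ensemble].
#' @param aggregate_selector `"largest"` or an aggregate id.
#' @param components character vector of components to profile.
#' @param bin_width radial bin width (Angstrom, > 0).
#' @param r_max outermost radius (default: half the smallest box edge).
#' @param cutoff aggregation cutoff (Angstrom).
#' @param stationary_range frames to analyse (default: all).
#' @param mode `"mass"` (g/cm^3) or `"number"` (atoms/A^3).
#' @return object of class `density_profile`: data.frame `profile` with
#'   columns `r_lo`, `r_hi`, `r_mid`, `component`, `density`, `density_sd`,
#'   `shell_volume`, plus totals for conservation checks.
#' @export
radial_density <- function(ens, aggregate_selector = "largest",
                           components = c("MA", "EO", "water"),
                           bin_width = 1, r_max = NULL, cutoff = 4.5,
                           stationary_range = NULL, mode = c("mass", "number")) {
  stopifnot(bin_width > 0)
  mode <- match.arg(mode)
  frames <- stationary_range %||% seq_len(n_frames(ens))
  r_max <- r_max %||% (min(frame_box(ens, frames[1L])) / 2)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)  # exact last shell
  nb <- length(edges) - 1L
  vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)

  acc <- array(0, dim = c(nb, length(components), length(frames)),
               dimnames = list(NULL, components, NULL))
  mass_in_range <- matrix(0, length(frames), length(components),
                          dimnames = list(NULL, components))
  for (k in seq_along(frames)) {
    f <- frames[k]
    ac <- resolve_aggregate(ens, f, cutoff, aggregate_selector)
    m <- ens$atoms$mass[ac$atom_index]
    com <- colSums(ac$positions * m) / sum(m)
    box <- frame_box(ens, f)
    for (ci in seq_along(components)) {
      comp <- components[ci]
      if (comp %in% c("MA", "EO")) {
        sel <- ens$atoms$component[ac$atom_index] == comp
        r <- sqrt(rowSums(sweep(ac$positions[sel, , drop = FALSE], 2L, com)^2))
        w <- ens$atoms$mass[ac$atom_index][sel]
      } else {
        idx <- which(ens$atoms$component == comp)
        if (comp == "water") idx <- intersect(idx, ens$water_oxygens)
        p <- frame_positions(ens, f)[idx, , drop = FALSE]
        r <- sqrt(rowSums(min_image_disp(p, com, box)^2))
        w <- if (comp == "water") rep(18.015, length(idx))
             else ens$atoms$mass[idx]
      }
      if (mode == "number") w <- rep(1, length(r))
      keep <- r < r_max
      bins <- findInterval(r[keep], edges, rightmost.closed = FALSE)
      acc[, ci, k] <- vapply(seq_len(nb), function(b)
        sum(w[keep][bins == b]), numeric(1))
      mass_in_range[k, ci] <- sum(w[keep])
    }
  }
  conv <- if (mode == "mass") AMU_PER_A3_TO_G_CM3 else 1
  dens <- sweep(acc, 1L, vol, "/") * conv
  prof <- do.call(rbind, lapply(seq_along(components), function(ci) {
    data.frame(
      r_lo = edges[-length(edges)], r_hi = edges[-1L],
      r_mid = (edges[-1L] + edges[-length(edges)]) / 2,
      component = components[ci],
      density = apply(dens[, ci, , drop = FALSE], 1L, mean),
      density_sd = apply(dens[, ci, , drop = FALSE], 1L, stats::sd),
      shell_volume = vol,
      stringsAsFactors = FALSE)
  }))
  structure(list(
    profile = prof, edges = edges, mode = mode, bin_width = bin_width,
    mean_mass_in_range = colMeans(mass_in_range),
    unit = if (mode == "mass") "g/cm^3" else "1/A^3"
  ), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d bins x %d component(s) [%s]\n",
              length(x$edges) - 1L,
              length(unique(x$profile$component)), x$unit))
  invisible(x)
}

# Radius where the EO density first exceeds the MA density going outward
# from the MA-rich interior (radial crossover core definition).
radial_crossover <- function(ens, aggregate_selector, cutoff,
                             stationary_range = NULL, bin_width = 1) {
  prof <- radial_density(ens, aggregate_selector,
                         components = c("MA", "EO"), bin_width = bin_width,
                         cutoff = cutoff, stationary_range = stationary_range)
  p <- prof$profile
  ma <- p$density[p$component == "MA"]
  eo <- p$density[p$component == "EO"]
  mid <- p$r_mid[p$component == "MA"]
  i0 <- which.max(ma)
  cross <- which(eo > ma & seq_along(ma) > i0 & (ma + eo) > 0)
  if (length(cross) == 0L)
    stop(paste("no MA/EO radial crossover found; use the ICSI core",
               "definition (core_definition = 'icsi_surface')"), call. = FALSE)
  mid[cross[1L]]
}

#' Core composition, hydration and end-out fraction
#'
#' A monomer is "in the core" when its center of mass lies inside the core
#' boundary — either the radius where EO density overtakes MA density
#' (`radial_crossover`) or the intrinsic core-shell interface
#' (`icsi_surface`). Reports per-frame counts of core EO and MA monomers,
#' hydration of core monomers (distinct water oxygens within
#' `hydration_cutoff` of any atom of a core monomer, averaged per core
#' monomer), and the fraction of polymers with at least one terminal MA
#' block whose center of mass sits outside the core ("end-out", the
#' flower-micelle escape conformation).
#'
#' @param ens a [frame_ensemble].
#' @param aggregate_selector `"largest"` or an aggregate id.
#' @param core_definition `"radial_crossover"` or `"icsi_surface"`.
#' @param hydration_cutoff hydration-shell radius (Angstrom, > 0).
#' @param cutoff aggregation cutoff (Angstrom).
#' @param stationary_range frames to analyse.
#' @param grid_resolution ICSI angular cells (used for `icsi_surface`).
#' @return object of class `core_report`.
#' @export
core_report <- function(ens, aggregate_selector = "largest",
                        core_definition = c("radial_crossover", "icsi_surface"),
                        hydration_cutoff = 3.5, cutoff = 4.5,
                        stationary_range = NULL, grid_resolution = 256L) {
  core_definition <- match.arg(core_definition)
  stopifnot(hydration_cutoff > 0)
  frames <- stationary_range %||% seq_len(n_frames(ens))

  r_core <- if (core_definition == "radial_crossover")
    radial_crossover(ens, aggregate_selector, cutoff, frames) else NA_real_

  per_frame <- lapply(frames, function(f) {
    ac <- resolve_aggregate(ens, f, cutoff, aggregate_selector)
    box <- frame_box(ens, f)
    m <- ens$atoms$mass[ac$atom_index]
    com <- colSums(ac$positions * m) / sum(m)
    if (core_definition == "icsi_surface") {
      surf <- build_surface(ens, frame = f, cutoff = cutoff,
                            aggregate_selector = aggregate_selector,
                            grid_resolution = grid_resolution)
    }
    in_core_fun <- function(xyz) {
      if (core_definition == "radial_crossover")
        sqrt(rowSums(sweep(xyz, 2L, com)^2)) < r_core
      else intrinsic_distance(xyz, surf) < 0
    }
    wpos <- frame_positions(ens, f)[ens$water_oxygens, , drop = FALSE]
    if (nrow(wpos) > 0) {
      # only waters near the core boundary can hydrate core monomers
      r_keep <- (if (core_definition == "radial_crossover") r_core
                 else max(surf$s)) + hydration_cutoff + 2
      wr <- sqrt(rowSums(min_image_disp(wpos, com, box)^2))
      wpos <- wpos[wr <= r_keep, , drop = FALSE]
    }

    eo_core <- 0L; ma_core <- 0L
    ma_h2o <- 0; eo_h2o <- 0
    end_out <- 0L; n_term <- 0L
    core_atom_xyz <- list(); core_atom_key <- list(); core_atom_is_ma <- list()
    for (id in ac$members) {
      sp <- ens$polymer_specs[[as.character(id)]]
      rows <- which(ens$atoms$molecule_id[ac$atom_index] == id)
      xyz <- ac$positions[rows, , drop = FALSE]
      mm <- sp$atom_mass
      mono_com <- t(vapply(sp$monomer_atom_map, function(ai) {
        w <- mm[ai] / sum(mm[ai])
        colSums(xyz[ai, , drop = FALSE] * w)
      }, numeric(3)))
      core_mono <- in_core_fun(mono_com)
      is_ma <- sp$monomer_label == "MA"
      eo_core <- eo_core + sum(core_mono & !is_ma)
      ma_core <- ma_core + sum(core_mono & is_ma)
      for (mi in which(core_mono)) {
        ai <- sp$monomer_atom_map[[mi]]
        core_atom_xyz[[length(core_atom_xyz) + 1L]] <- xyz[ai, , drop = FALSE]
        core_atom_key[[length(core_atom_key) + 1L]] <-
          rep(sprintf("%d_%d", id, mi), length(ai))
        core_atom_is_ma[[length(core_atom_is_ma) + 1L]] <- is_ma[mi]
      }
      # terminal MA blocks: first/last block of a linear chain
      if (!sp$cyclic) {
        nb <- nrow(sp$blocks)
        term <- which(sp$blocks$label == "MA" & seq_len(nb) %in% c(1L, nb))
        if (length(term)) {
          n_term <- n_term + 1L
          out <- FALSE
          for (b in term) {
            mono_idx <- which(sp$monomer_block == b)
            bl_atoms <- unlist(sp$monomer_atom_map[mono_idx])
            w <- mm[bl_atoms] / sum(mm[bl_atoms])
            bcom <- colSums(xyz[bl_atoms, , drop = FALSE] * w)
            if (!in_core_fun(matrix(bcom, 1L))) out <- TRUE
          }
          if (out) end_out <- end_out + 1L
        }
      }
    }
    # hydration: one distance matrix core-monomer atoms x water oxygens,
    # then distinct waters per monomer (any atom within the cutoff)
    if (length(core_atom_xyz) && nrow(wpos) > 0) {
      axyz <- do.call(rbind, core_atom_xyz)
      akey <- unlist(core_atom_key)
      mono_is_ma <- unlist(core_atom_is_ma)
      names(mono_is_ma) <- vapply(core_atom_key, `[`, character(1), 1L)
      dm <- pbc_dist_mat(axyz, wpos, box) <= hydration_cutoff
      per_mono <- rowsum(dm + 0, akey) > 0       # monomer x water
      nw <- rowSums(per_mono)
      ma_h2o <- sum(nw[mono_is_ma[rownames(per_mono)]])
      eo_h2o <- sum(nw[!mono_is_ma[rownames(per_mono)]])
    }
    data.frame(
      frame = f, EO_core = eo_core, MA_core = ma_core,
      MA_H2O = if (ma_core > 0) ma_h2o / ma_core else 0,
      EO_H2O = if (eo_core > 0) eo_h2o / eo_core else 0,
      end_out_fraction = if (n_term > 0) end_out / n_term else NA_real_)
  })
  pf <- do.call(rbind, per_frame)
  ms <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  structure(list(
    per_frame = pf,
    EO_core = ms(pf$EO_core), MA_core = ms(pf$MA_core),
    MA_H2O = ms(pf$MA_H2O), EO_H2O = ms(pf$EO_H2O),
    end_out_fraction = if (all(is.na(pf$end_out_fraction))) NA_real_
                       else mean(pf$end_out_fraction, na.rm = TRUE),
    core_definition = core_definition,
    core_radius = r_core, hydration_cutoff = hydration_cutoff,
    denominator = "per core monomer, frame-averaged"
  ), class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("<core_report> (%s%s)\n", x$core_definition,
              if (!is.na(x$core_radius))
                sprintf(", r_core = %.1f A", x$core_radius) else ""))
  cat(sprintf("  EO_core = %.1f +/- %.1f   MA_core = %.1f +/- %.1f\n",
              x$EO_core["mean"], x$EO_core["sd"],
              x$MA_core["mean"], x$MA_core["sd"]))
  cat(sprintf("  MA_H2O = %.2f +/- %.2f   EO_H2O = %.2f +/- %.2f  (%s)\n",
              x$MA_H2O["mean"], x$MA_H2O["sd"],
              x$EO_H2O["mean"], x$EO_H2O["sd"], x$denominator))
  if (!is.na(x$end_out_fraction))
    cat(sprintf("  end-out fraction = %.2f\n", x$end_out_fraction))
  invisible(x)
}

# Pool per-monomer values into equivalence classes and normalize by the
# maximum class mean (per topology).
pool_classes <- function(values, classes) {
  cls <- sort(unique(classes))
  # order MA1..MAk numerically
  cls <- cls[order(as.integer(sub("^MA", "", cls)))]
  raw <- vapply(cls, function(cl) mean(values[classes == cl]), numeric(1))
  norm <- if (max(raw) > 0) raw / max(raw) else raw
  data.frame(class = cls, raw = unname(raw), normalized = unname(norm),
             stringsAsFactors = FALSE)
}

#' Intermolecular MA contact counts per equivalence class
#'
#' For every MA monomer, counts heavy-atom pairs to MA monomers of *other*
#' polymers within `contact_cutoff` (intramolecular pairs contribute
#' nothing), averages within chemically-equivalent classes over monomers
#' and frames, and normalizes class means by the per-topology maximum
#' (largest class = 1).
#'
#' @param ens a [frame_ensemble].
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom, > 0).
#' @param stationary_range frames to analyse.
#' @return object of class `class_profile` (data.frame in `$classes`).
#' @export
class_contacts <- function(ens, contact_cutoff = 4.5,
                           stationary_range = NULL) {
  stopifnot(contact_cutoff > 0)
  frames <- stationary_range %||% seq_len(n_frames(ens))
  ids <- ens$polymer_ids

  # flatten all MA atoms with polymer / monomer / class annotation
  ma_info <- do.call(rbind, lapply(as.character(ids), function(id) {
    sp <- ens$polymer_specs[[id]]
    mono <- which(sp$monomer_label == "MA")
    do.call(rbind, lapply(mono, function(mi) {
      data.frame(atom = ens$molecule_atoms[[id]][sp$monomer_atom_map[[mi]]],
                 polymer = as.integer(id), monomer = mi,
                 class = sp$equivalence_classes[mi],
                 stringsAsFactors = FALSE)
    }))
  }))
  heavy <- ens$atoms$element[ma_info$atom] != "H"
  ma_info <- ma_info[heavy, ]

  key <- paste(ma_info$polymer, ma_info$monomer)
  counts_sum <- stats::setNames(numeric(length(unique(key))), unique(key))
  for (f in frames) {
    pos <- frame_positions(ens, f)[ma_info$atom, , drop = FALSE]
    box <- frame_box(ens, f)
    dm <- pbc_dist_mat(pos, pos, box)
    inter <- outer(ma_info$polymer, ma_info$polymer, "!=")
    hit <- (dm <= contact_cutoff) & inter
    per_atom <- rowSums(hit)
    per_mono <- tapply(per_atom, key, sum)
    counts_sum[names(per_mono)] <- counts_sum[names(per_mono)] + per_mono
  }
  per_mono_mean <- counts_sum / length(frames)
  mono_class <- ma_info$class[!duplicated(key)]
  names(mono_class) <- key[!duplicated(key)]
  classes <- pool_classes(per_mono_mean[names(mono_class)], mono_class)
  structure(list(classes = classes, metric = "intermolecular MA contacts",
                 cutoff = contact_cutoff, frames = frames),
            class = "class_profile")
}

#' Carbonyl-oxygen hydration per equivalence class
#'
#' Counts water oxygens within `shell_cutoff` (closed boundary: a water at
#' exactly the cutoff is included) of each MA monomer's carbonyl oxygen,
#' averages per class over monomers and frames, and reports raw coordination
#' numbers alongside per-topology max-normalized values.
#'
#' @param ens a [frame_ensemble].
#' @param shell_cutoff first-hydration-shell radius (Angstrom, > 0);
#'   3.5 A is the carbonyl-O/water-O first RDF minimum convention.
#' @param stationary_range frames to analyse.
#' @return object of class `class_profile`.
#' @export
carbonyl_hydration <- function(ens, shell_cutoff = 3.5,
                               stationary_range = NULL) {
  stopifnot(shell_cutoff > 0)
  frames <- stationary_range %||% seq_len(n_frames(ens))
  ids <- as.character(ens$polymer_ids)
  info <- do.call(rbind, lapply(ids, function(id) {
    sp <- ens$polymer_specs[[id]]
    if (all(is.na(sp$carbonyl_oxygen_map)))
      stop(sprintf("polymer %s's spec lacks a carbonyl-oxygen map", id),
           call. = FALSE)
    mono <- which(!is.na(sp$carbonyl_oxygen_map))
    data.frame(atom = ens$molecule_atoms[[id]][sp$carbonyl_oxygen_map[mono]],
               class = sp$equivalence_classes[mono],
               stringsAsFactors = FALSE)
  }))
  wat <- ens$water_oxygens
  coord <- matrix(0, nrow(info), length(frames))
  if (length(wat)) {
    for (k in seq_along(frames)) {
      f <- frames[k]
      pos <- frame_positions(ens, f)
      dm <- pbc_dist_mat(pos[info$atom, , drop = FALSE],
                         pos[wat, , drop = FALSE], frame_box(ens, f))
      coord[, k] <- rowSums(dm <= shell_cutoff)
    }
  }
  classes <- pool_classes(rowMeans(coord), info$class)
  structure(list(classes = classes, metric = "carbonyl-O hydration",
                 cutoff = shell_cutoff, frames = frames),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile> %s (cutoff %.2f A, %d frame(s))\n",
              x$metric, x$cutoff, length(x$frames)))
  print(transform(x$classes, raw = round(raw, 3),
                  normalized = round(normalized, 3)), row.names = FALSE)
  invisible(x)
}
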