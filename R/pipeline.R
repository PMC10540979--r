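#' Config-driven end-to-end pipeline
#'
#' Runs the analysis stages in order — burn-in detection, aggregate
#' identification, shape, radial density, intrinsic interface, core report,
#' contacts, hydration, conformational landscape — from one YAML (or list)
#' configuration, writing CSV outputs and a JSON run manifest with the
#' config snapshot, seed, package version, warnings and per-file checksums.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' Every tunable of every stage, with its default. Thresholds that the
#' analyses depend on (contact cutoffs, hydration shells, bin widths,
#' clustering hyperparameters) are deliberately surfaced here rather than
#' buried in function defaults.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "micelle_run",
    input = list(
      synth = list(topology = "diblock", n_polymers = 20L, n_frames = 200L,
                   noise_sigma = 0.1, jitter_sigma = 0.6,
                   end_out_fraction = 0, water = TRUE),
      structure = NULL, trajectory = NULL, spec_config = NULL
    ),
    stages = c("aggregate", "shape", "density", "icsi", "core",
               "contacts", "hydration", "conformations"),
    burn_in = list(window = 20L, tolerance = 0.5),
    aggregate = list(cutoff = 4.5),
    shape = list(),
    density = list(bin_width = 1, mode = "mass"),
    icsi = list(grid_resolution = 512L, bin_width = 1,
                d_range = c(-25, 15), n_mc = 20000L),
    core = list(definition = "radial_crossover", hydration_cutoff = 3.5),
    contacts = list(cutoff = 4.5),
    hydration = list(shell_cutoff = 3.5),
    conformations = list(n_neighbors = 15L, min_dist = 0.1,
                         min_cluster_size = NULL, min_samples = NULL,
                         localize = TRUE)
  )
}

#' Describe the configuration schema
#'
#' Prints the default configuration as YAML with the meaning and units of
#' every key.
#'
#' @return the default config, invisibly.
#' @export
config_describe <- function() {
  cat("# pipeline configuration (defaults shown; all lengths in Angstrom)\n")
  cat("# seed: master seed for every stochastic step\n")
  cat("# input.synth: synthetic system (ignored when input.structure given)\n")
  cat("# burn_in: stationarity window (frames) and N_agg tolerance\n")
  cat("# aggregate.cutoff: heavy-atom single-linkage contact cutoff\n")
  cat("# density.bin_width: radial bin; mode mass (g/cm^3) or number (1/A^3)\n")
  cat("# icsi: angular cells, intrinsic bin width, d_I range, MC volume samples\n")
  cat("# core.definition: radial_crossover or icsi_surface\n")
  cat("# hydration.shell_cutoff: carbonyl-O/water-O first-shell radius\n")
  cat("# conformations: embedding + clustering hyperparameters\n")
  cat(yaml::as.yaml(default_config()))
  invisible(default_config())
}

# Deep-merge user config over defaults; unknown keys are schema errors.
merge_config <- function(user, defaults = default_config(), path = "") {
  if (!is.list(user)) return(user)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, bad, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]])))
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Merges over [default_config] and checks the schema: unknown keys,
#' non-positive cutoffs and bin widths, unsatisfied stage dependencies.
#'
#' @param config a list or YAML file path.
#' @return the merged, validated configuration.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  errs <- character(0)
  chk <- function(val, key) {
    if (!is.null(val) && (!is.numeric(val) || any(val <= 0)))
      errs <<- c(errs, key)
  }
  chk(cfg$aggregate$cutoff, "aggregate.cutoff")
  chk(cfg$density$bin_width, "density.bin_width")
  chk(cfg$icsi$bin_width, "icsi.bin_width")
  chk(cfg$icsi$grid_resolution, "icsi.grid_resolution")
  chk(cfg$icsi$n_mc, "icsi.n_mc")
  chk(cfg$core$hydration_cutoff, "core.hydration_cutoff")
  chk(cfg$contacts$cutoff, "contacts.cutoff")
  chk(cfg$hydration$shell_cutoff, "hydration.shell_cutoff")
  chk(cfg$burn_in$window, "burn_in.window")
  chk(cfg$conformations$n_neighbors, "conformations.n_neighbors")
  if (length(errs))
    stop(sprintf("config schema violation (must be > 0): %s",
                 paste(errs, collapse = ", ")), call. = FALSE)
  unknown_stages <- setdiff(cfg$stages, default_config()$stages)
  if (length(unknown_stages))
    stop(sprintf("unknown stage(s): %s",
                 paste(unknown_stages, collapse = ", ")), call. = FALSE)
  if ("conformations" %in% cfg$stages && isTRUE(cfg$conformations$localize) &&
      !"icsi" %in% cfg$stages)
    stop("stage dependency: conformations.localize requires the icsi stage",
         call. = FALSE)
  if (!is.null(cfg$core) && cfg$core$definition == "icsi_surface" &&
      "core" %in% cfg$stages && !"icsi" %in% cfg$stages)
    stop("stage dependency: core.definition = icsi_surface requires the icsi stage",
         call. = FALSE)
  cfg
}

write_csv_out <- function(df, path) {
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' @param config a list or YAML file path; see [default_config] and
#'   [config_describe].
#' @param output_dir overrides `config$output_dir`.
#' @return an object of class `run_manifest` (also written as
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- cfg$seed
  t_start <- Sys.time()
  files <- character(0)
  warnings <- character(0)
  results <- list()
  note <- function(msg) warnings <<- c(warnings, msg)
  timing <- list()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    v <- withCallingHandlers(expr, warning = function(w) {
      note(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timing[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    v
  }

  # ---- input ----
  gt <- NULL
  if (!is.null(cfg$input$structure)) {
    ens <- timed("load", load_ensemble(cfg$input$structure,
                                       cfg$input$trajectory,
                                       cfg$input$spec_config))
  } else {
    sy <- cfg$input$synth
    dm <- timed("synth", demo_micelle_trajectory(
      spec = build_polymer_spec(sy$topology),
      n_polymers = sy$n_polymers, n_frames = sy$n_frames,
      noise_sigma = sy$noise_sigma, jitter_sigma = sy$jitter_sigma,
      end_out_fraction = sy$end_out_fraction, water = isTRUE(sy$water),
      seed = seed))
    ens <- dm$ensemble
    gt <- dm$ground_truth
  }

  # ---- burn-in + aggregates ----
  nd_all <- timed("aggregate", nagg_distribution(ens, cfg$aggregate$cutoff))
  burn <- if (n_frames(ens) >= 2L * cfg$burn_in$window) {
    timed("burn_in", estimate_burn_in(nd_all$largest_series,
                                      window = cfg$burn_in$window,
                                      tolerance = cfg$burn_in$tolerance))
  } else 0L
  if (isTRUE(attr(burn, "fallback")))
    note("burn-in fallback: no stationary plateau found")
  stationary <- (as.integer(burn) + 1L):n_frames(ens)
  results$burn_in <- as.integer(burn)
  results$stationary_frames <- length(stationary)

  if ("aggregate" %in% cfg$stages) {
    nd <- nagg_distribution(ens, cfg$aggregate$cutoff, stationary)
    asn <- do.call(rbind, lapply(seq_along(nd$frames), function(i) {
      data.frame(frame = nd$frames[i],
                 polymer_id = as.integer(names(nd$labels[[i]])),
                 aggregate_id = as.integer(nd$labels[[i]]))
    }))
    files <- c(files, write_csv_out(asn, file.path(out, "assignments.csv")))
    dist_df <- data.frame(n_agg = as.integer(names(nd$prob)),
                          p_polymer_weighted = as.numeric(nd$prob))
    uw <- data.frame(n_agg = as.integer(names(nd$prob_unweighted)),
                     p_unweighted = as.numeric(nd$prob_unweighted))
    dist_df <- merge(dist_df, uw, all = TRUE)
    dist_df[is.na(dist_df)] <- 0
    files <- c(files, write_csv_out(dist_df,
                                    file.path(out, "nagg_distribution.csv")))
    results$nagg_largest_mean <- nd$largest_mean
    results$nagg_largest_sd <- nd$largest_sd
  }

  if ("shape" %in% cfg$stages) {
    sh <- timed("shape", shape_of_aggregate(ens, cutoff = cfg$aggregate$cutoff,
                                            stationary_range = stationary))
    files <- c(files, write_csv_out(sh$per_frame,
                                    file.path(out, "shape_per_frame.csv")))
    results$rg_mean <- sh$rg_mean; results$rg_sd <- sh$rg_sd
    results$eccentricity_mean <- sh$eccentricity_mean
    results$eccentricity_sd <- sh$eccentricity_sd
  }

  if ("density" %in% cfg$stages) {
    rd <- timed("density", radial_density(
      ens, bin_width = cfg$density$bin_width, cutoff = cfg$aggregate$cutoff,
      stationary_range = stationary, mode = cfg$density$mode))
    files <- c(files, write_csv_out(rd$profile,
                                    file.path(out, "radial_density.csv")))
  }

  surf1 <- NULL
  if ("icsi" %in% cfg$stages) {
    surf1 <- timed("icsi", build_surface(
      ens, frame = stationary[1L], cutoff = cfg$aggregate$cutoff,
      grid_resolution = cfg$icsi$grid_resolution))
    g <- surf1$grid
    cells <- data.frame(cell = seq_len(g$n_cells),
                        s = surf1$s, anchored = surf1$anchored,
                        anchor_atom = surf1$anchor_atom)
    files <- c(files, write_csv_out(cells, file.path(out, "surface_cells.csv")))
    ip <- timed("icsi_density", intrinsic_density(
      ens, bin_width = cfg$icsi$bin_width, d_range = cfg$icsi$d_range,
      cutoff = cfg$aggregate$cutoff, stationary_range = stationary[1L],
      grid_resolution = cfg$icsi$grid_resolution,
      surfaces = list(surf1), n_mc = cfg$icsi$n_mc, seed = seed))
    files <- c(files, write_csv_out(ip$profile,
                                    file.path(out, "intrinsic_density.csv")))
    n_agg1 <- max(lengths(split(seq_along(nd_all$labels[[stationary[1L]]]),
                                nd_all$labels[[stationary[1L]]])))
    results$area_per_polymer <- area_per_polymer(surf1, n_agg1)
    results$icsi_area <- surf1$area
  }

  if ("core" %in% cfg$stages) {
    cr <- timed("core", core_report(
      ens, core_definition = cfg$core$definition,
      hydration_cutoff = cfg$core$hydration_cutoff,
      cutoff = cfg$aggregate$cutoff, stationary_range = stationary,
      grid_resolution = cfg$icsi$grid_resolution))
    files <- c(files, write_csv_out(cr$per_frame,
                                    file.path(out, "core_report.csv")))
    results$EO_core <- unname(cr$EO_core["mean"])
    results$MA_core <- unname(cr$MA_core["mean"])
    results$MA_H2O <- unname(cr$MA_H2O["mean"])
    results$EO_H2O <- unname(cr$EO_H2O["mean"])
    results$end_out_fraction <- cr$end_out_fraction
  }

  if ("contacts" %in% cfg$stages) {
    cc <- timed("contacts", class_contacts(ens, cfg$contacts$cutoff,
                                           stationary_range = stationary))
    files <- c(files, write_csv_out(cc$classes,
                                    file.path(out, "class_contacts.csv")))
  }

  if ("hydration" %in% cfg$stages) {
    ch <- timed("hydration", carbonyl_hydration(ens, cfg$hydration$shell_cutoff,
                                                stationary_range = stationary))
    files <- c(files, write_csv_out(ch$classes,
                                    file.path(out, "carbonyl_hydration.csv")))
  }

  if ("conformations" %in% cfg$stages) {
    land <- timed("conformations", conformation_landscape(
      ens, stationary_range = stationary,
      n_neighbors = cfg$conformations$n_neighbors,
      min_dist = cfg$conformations$min_dist,
      min_cluster_size = cfg$conformations$min_cluster_size,
      min_samples = cfg$conformations$min_samples,
      seed = seed))
    emb_df <- data.frame(land$row_index,
                         x = land$embedding[, 1L], y = land$embedding[, 2L],
                         cluster = land$labels)
    files <- c(files, write_csv_out(emb_df, file.path(out, "embedding.csv")))
    fr_df <- data.frame(cluster = names(land$fractions),
                        percent = as.numeric(land$fractions))
    files <- c(files, write_csv_out(fr_df, file.path(out, "fractions.csv")))
    files <- c(files, unname(write_medoids(land, ens, out)))
    results$n_clusters <- land$n_clusters
    results$noise_percent <- 100 * land$noise_fraction
    if (land$noise_fraction > 0.08)
      note("noise fraction exceeds 8% of the data")
    if (isTRUE(cfg$conformations$localize)) {
      loc <- timed("localize", localize_clusters(
        land, ens, frames = stationary[1L],
        bin_width = cfg$icsi$bin_width, d_range = cfg$icsi$d_range,
        grid_resolution = cfg$icsi$grid_resolution,
        cutoff = cfg$aggregate$cutoff, n_mc = cfg$icsi$n_mc, seed = seed))
      files <- c(files, write_csv_out(loc$profile,
                                      file.path(out, "cluster_localization.csv")))
      results$cluster_mean_d <- as.list(loc$mean_d)
    }
  }

  manifest <- structure(list(
    package = "micelletools",
    version = as.character(utils::packageVersion("micelletools")),
    seed = seed,
    config = cfg,
    results = results,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))),
    warnings = warnings,
    timing_s = timing,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> micelletools %s, seed %d\n", x$version, x$seed))
  cat(sprintf("  %d output file(s), %d warning(s), %.1f s\n",
              length(x$files), length(x$warnings), x$elapsed_s))
  for (k in names(x$results)) {
    v <- x$results[[k]]
    if (is.numeric(v) && length(v) == 1L)
      cat(sprintf("  %s = %s\n", k, format(v, digits = 6)))
  }
  invisible(x)
}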