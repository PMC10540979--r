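#' Reading and writing MD structure and trajectory files
#'
#' Structures are read from GRO or PDB; trajectories from DCD (binary, via
#' bio3d), multi-model PDB, or multi-frame GRO. GRO files are written at
#' 5 decimals (nm) so coordinates survive a round trip within 1e-3 Angstrom.
#' Only orthorhombic boxes are supported; triclinic box lines are rejected.
#'
#' @name micelle_io
NULL

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

guess_element <- function(name) {
  el <- sub("^[0-9]*", "", trimws(name))
  el <- toupper(substr(el, 1L, 1L))
  ifelse(el %in% names(.ELEMENT_MASS), el, "C")
}

# ---- GRO ----------------------------------------------------------------

# Parse every frame of a (possibly multi-frame) GRO file.
# Returns list(frames = list(list(positions, box)), atoms = data.frame).
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stop(sprintf("%s: malformed GRO atom count at line %d", path, i + 1L),
           call. = FALSE)
    rows <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- as.integer(substr(rows, 1L, 5L))
    resname <- trimws(substr(rows, 6L, 10L))
    atname <- trimws(substr(rows, 11L, 15L))
    coords <- t(vapply(strsplit(trimws(substr(rows, 21L, 1000L)), "\\s+"),
                       function(x) as.numeric(x[1:3]), numeric(3)))
    boxv <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-12))
      stop(sprintf("%s: triclinic box not supported", path), call. = FALSE)
    frames[[length(frames) + 1L]] <- list(
      positions = coords * 10,      # nm -> Angstrom
      box = boxv[1:3] * 10
    )
    if (is.null(atoms)) {
      atoms <- data.frame(name = atname, resname = resname,
                          molecule_id = resid, stringsAsFactors = FALSE)
    }
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  list(frames = frames, atoms = atoms)
}

format_gro_frame <- function(ens, frame, title, decimals = 5L) {
  pos <- frame_positions(ens, frame) / 10   # Angstrom -> nm
  box <- frame_box(ens, frame) / 10
  at <- ens$atoms
  resname <- ifelse(at$role == "water", "SOL", "POL")
  w <- decimals + 5L
  fmt <- sprintf("%%5d%%-5s%%5s%%5d%%%d.%df%%%d.%df%%%d.%df",
                 w, decimals, w, decimals, w, decimals)
  c(title,
    sprintf("%5d", nrow(at)),
    sprintf(fmt, at$molecule_id %% 100000L, resname, substr(at$name, 1L, 5L),
            seq_len(nrow(at)) %% 100000L, pos[, 1], pos[, 2], pos[, 3]),
    sprintf("%12.6f%12.6f%12.6f", box[1], box[2], box[3]))
}

write_gro <- function(ens, path, frames = seq_len(n_frames(ens))) {
  out <- unlist(lapply(frames, function(f) {
    format_gro_frame(ens, f, sprintf("micelletools frame %d, t= %.3f", f,
                                     if (is.na(ens$timestep)) 0 else (f - 1) * ens$timestep))
  }))
  writeLines(out, path)
  invisible(path)
}

# ---- PDB ----------------------------------------------------------------

write_pdb <- function(ens, path, frames = seq_len(n_frames(ens))) {
  at <- ens$atoms
  if (max(at$molecule_id) > 9999L)
    stop("PDB residue numbers are limited to 9999; write GRO instead",
         call. = FALSE)
  resname <- ifelse(at$role == "water", "SOL", "POL")
  box <- frame_box(ens, frames[1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1], box[2], box[3], 90, 90, 90), con)
  serial <- seq_len(nrow(at)) %% 100000L
  for (f in seq_along(frames)) {
    pos <- frame_positions(ens, frames[f])
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, substr(at$name, 1L, 4L), resname, at$molecule_id,
      pos[, 1], pos[, 2], pos[, 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_pdb_file <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst) >= 1L) {
    v <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
    ang <- as.numeric(c(substr(cryst[1], 34, 40), substr(cryst[1], 41, 47),
                        substr(cryst[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-6))
      stop(sprintf("%s: triclinic box not supported", path), call. = FALSE)
    box <- v
  } else {
    stop(sprintf("%s: no CRYST1 record; box is required", path), call. = FALSE)
  }
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    list(positions = matrix(xyz[f, ], ncol = 3L, byrow = TRUE), box = box)
  })
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      resname = trimws(pdb$atom$resid),
                      molecule_id = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  list(frames = frames, atoms = atoms)
}

# ---- loading ------------------------------------------------------------

read_structure_or_traj <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gro = read_gro(path),
    pdb = read_pdb_file(path),
    stop(sprintf("unsupported structure format '.%s' (use .gro or .pdb)", ext),
         call. = FALSE)
  )
}

read_trajectory_frames <- function(path, ref_box) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb")) return(read_structure_or_traj(path)$frames)
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    return(lapply(seq_len(nrow(xyz)), function(f) {
      list(positions = matrix(xyz[f, ], ncol = 3L, byrow = TRUE), box = ref_box)
    }))
  }
  stop(sprintf("unsupported trajectory format '.%s' (use .gro, .pdb or .dcd)",
               ext), call. = FALSE)
}

normalize_spec_config <- function(spec_config) {
  if (is.character(spec_config) && length(spec_config) == 1L)
    spec_config <- yaml::read_yaml(spec_config)
  stopifnot(is.list(spec_config))
  spec_config$water_mass <- spec_config$water_mass %||% 18.015
  spec_config
}

#' Load a structure + trajectory into a frame_ensemble
#'
#' Binds standard MD file formats to the package's data model. The polymer
#' specification (`spec_config`) declares, per polymer molecule, the topology
#' class and block lengths, and declares which molecules are water — roles
#' are never guessed from residue names. Polymer bead metadata (elements,
#' masses, monomer maps) comes from the reconstructed [polymer_spec], so a
#' written-then-reloaded ensemble carries identical metadata.
#'
#' @param structure_path GRO or PDB file; defines atoms and the box.
#' @param trajectory_path optional GRO/PDB/DCD file with frames; its atom
#'   count must equal the structure's. DCD frames inherit the structure box.
#' @param spec_config a list or YAML file path with entries: `polymers` (a
#'   list of `list(molecule_ids, topology_class, blocks)`), optional
#'   `water_molecule_ids` (default: every remaining molecule), optional
#'   `water_mass`, optional `timestep`.
#' @return a validated [frame_ensemble].
#' @export
load_ensemble <- function(structure_path, trajectory_path = NULL, spec_config) {
  cfg <- normalize_spec_config(spec_config)
  st <- read_structure_or_traj(structure_path)
  frames <- st$frames[1L]
  if (!is.null(trajectory_path)) {
    frames <- read_trajectory_frames(trajectory_path, st$frames[[1L]]$box)
    ntraj <- nrow(frames[[1L]]$positions)
    nstr <- nrow(st$frames[[1L]]$positions)
    if (ntraj != nstr)
      stop(sprintf("atom-count mismatch: trajectory has %d atoms, structure has %d",
                   ntraj, nstr), call. = FALSE)
  }

  at <- st$atoms
  at$element <- NA_character_
  at$mass <- NA_real_
  specs <- list()
  role <- rep(NA_character_, nrow(at))
  for (p in cfg$polymers) {
    ids <- p$molecule_ids %||% p$molecule_id
    sp <- build_polymer_spec(p$topology_class,
                             block_lengths = unlist(p$blocks) %||% NULL)
    for (id in ids) {
      idx <- which(at$molecule_id == id)
      if (length(idx) == 0L)
        stop(sprintf("spec_config names polymer molecule %s absent from the file",
                     id), call. = FALSE)
      if (length(idx) != sp$n_atoms)
        stop(sprintf("polymer molecule %s has %d atoms, spec expects %d",
                     id, length(idx), sp$n_atoms), call. = FALSE)
      specs[[as.character(id)]] <- sp
      role[idx] <- "polymer"
      at$element[idx] <- sp$atom_element
      at$mass[idx] <- sp$atom_mass
      at$name[idx] <- sp$atom_name
    }
  }
  water_ids <- cfg$water_molecule_ids %||%
    setdiff(unique(at$molecule_id), as.integer(names(specs)))
  for (id in water_ids) {
    idx <- which(at$molecule_id == id)
    role[idx] <- "water"
    at$element[idx] <- guess_element(at$name[idx])
    if (length(idx) == 1L) {
      at$element[idx] <- "O"
      at$mass[idx] <- cfg$water_mass
    } else {
      at$mass[idx] <- .ELEMENT_MASS[at$element[idx]]
    }
  }
  if (anyNA(role)) {
    bad <- which(is.na(role))
    stop(sprintf(
      "spec_config leaves %d atoms unmapped (atom indices %s%s; molecules %s)",
      length(bad), paste(utils::head(bad, 10L), collapse = ", "),
      if (length(bad) > 10L) ", ..." else "",
      paste(unique(at$molecule_id[bad]), collapse = ", ")), call. = FALSE)
  }
  at$role <- role
  frame_ensemble(frames, at[, c("name", "element", "mass", "molecule_id", "role")],
                 specs, timestep = cfg$timestep %||% NA_real_)
}

#' Write a frame_ensemble to structure (and trajectory) files
#'
#' The structure file holds the first frame; the trajectory file, if
#' requested, holds every frame (multi-frame GRO or multi-model PDB).
#'
#' @param ens a [frame_ensemble].
#' @param structure_path output `.gro` or `.pdb` path.
#' @param trajectory_path optional output `.gro` or `.pdb` path for all frames.
#' @return `structure_path`, invisibly.
#' @export
write_ensemble <- function(ens, structure_path, trajectory_path = NULL) {
  writer <- function(path, frames) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
      gro = write_gro(ens, path, frames),
      pdb = write_pdb(ens, path, frames),
      stop(sprintf("unsupported output format '.%s' (use .gro or .pdb)", ext),
           call. = FALSE)
    )
  }
  writer(structure_path, 1L)
  if (!is.null(trajectory_path)) writer(trajectory_path, seq_len(n_frames(ens)))
  invisible(structure_path)
}

#' Spec-config list describing an ensemble's molecules
#'
#' Produces the `spec_config` (suitable for [load_ensemble] or for writing as
#' the YAML sidecar of a fixture) that reconstructs the ensemble's polymer
#' specs and water roles.
#'
#' @param ens a [frame_ensemble].
#' @return a list with `polymers`, `water_molecule_ids` and `water_mass`.
#' @export
ensemble_spec_config <- function(ens) {
  groups <- list()
  for (id in ens$polymer_ids) {
    sp <- ens$polymer_specs[[as.character(id)]]
    key <- paste(sp$topology_class, paste(sp$blocks$n, collapse = ","))
    groups[[key]] <- list(
      molecule_ids = c(groups[[key]]$molecule_ids, id),
      topology_class = sp$topology_class,
      blocks = as.list(sp$blocks$n)
    )
  }
  wm <- ens$atoms$mass[ens$atoms$role == "water"]
  list(polymers = unname(groups),
       water_molecule_ids = as.integer(ens$water_ids),
       water_mass = if (length(wm)) wm[1L] else 18.015)
}
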