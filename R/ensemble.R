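#' Frame ensembles
#'
#' A `frame_ensemble` holds per-frame coordinates (Angstrom) and orthorhombic
#' box edge lengths for every atom of a micellar system, atom metadata
#' (element, mass, molecule id, role), and the [polymer_spec] of every polymer
#' molecule. Water molecules are identified by role, declared explicitly
#' rather than guessed from residue names, and must expose exactly one oxygen
#' each for hydration analysis.
#'
#' @param frames list of frames, each `list(positions = <n x 3 matrix>,
#'   box = <numeric(3)>)`.
#' @param atoms data.frame with columns `name`, `element`, `mass`,
#'   `molecule_id`, `role` (one row per atom).
#' @param polymer_specs named list mapping polymer `molecule_id` (as
#'   character) to [polymer_spec] objects.
#' @param timestep optional time between frames (ps), recorded as metadata.
#' @return an object of class `frame_ensemble`.
#' @export
frame_ensemble <- function(frames, atoms, polymer_specs, timestep = NA_real_) {
  ens <- structure(list(
    frames = frames,
    atoms = atoms,
    polymer_specs = polymer_specs,
    timestep = timestep,
    uid = next_ensemble_uid()
  ), class = "frame_ensemble")
  ens <- index_ensemble(ens)
  validate_ensemble(ens)
  ens
}

# Precompute atom-index caches and per-atom component labels.
index_ensemble <- function(ens) {
  at <- ens$atoms
  ens$molecule_atoms <- split(seq_len(nrow(at)), at$molecule_id)
  first <- !duplicated(at$molecule_id)
  pol <- at$molecule_id[first][at$role[first] == "polymer"]
  ens$polymer_ids <- sort(pol)
  ens$water_ids <- sort(at$molecule_id[first][at$role[first] != "polymer"])
  ens$water_oxygens <- which(at$role == "water" & at$element == "O")
  comp <- rep(NA_character_, nrow(at))
  comp[at$role == "water"] <- "water"
  for (id in as.character(ens$polymer_ids)) {
    sp <- ens$polymer_specs[[id]]
    if (is.null(sp)) next
    idx <- ens$molecule_atoms[[id]]
    lab <- rep(sp$monomer_label, lengths(sp$monomer_atom_map))
    comp[idx] <- lab
  }
  ens$atoms$component <- comp
  ens
}

#' Validate a frame_ensemble's invariants
#'
#' All positions finite; box edges positive; every polymer molecule has a
#' spec whose atom count matches; every water molecule exposes exactly one
#' oxygen; all frames share the atom count of the metadata table.
#'
#' @param ens a `frame_ensemble`.
#' @return the ensemble, invisibly; errors on violation.
#' @export
validate_ensemble <- function(ens) {
  stopifnot(inherits(ens, "frame_ensemble"))
  n <- nrow(ens$atoms)
  for (f in seq_along(ens$frames)) {
    fr <- ens$frames[[f]]
    if (!is.matrix(fr$positions) || ncol(fr$positions) != 3L)
      stop(sprintf("frame %d: positions must be an n x 3 matrix", f), call. = FALSE)
    if (nrow(fr$positions) != n)
      stop(sprintf("frame %d has %d atoms but metadata describes %d",
                   f, nrow(fr$positions), n), call. = FALSE)
    if (!all(is.finite(fr$positions)))
      stop(sprintf("frame %d contains non-finite coordinates", f), call. = FALSE)
    if (length(fr$box) != 3L || !all(is.finite(fr$box)) || any(fr$box <= 0))
      stop(sprintf("frame %d: box must be 3 positive orthorhombic edges", f),
           call. = FALSE)
  }
  for (id in as.character(ens$polymer_ids)) {
    sp <- ens$polymer_specs[[id]]
    if (is.null(sp))
      stop(sprintf("polymer molecule %s has no polymer_spec", id), call. = FALSE)
    idx <- ens$molecule_atoms[[id]]
    if (length(idx) != sp$n_atoms)
      stop(sprintf("polymer molecule %s has %d atoms, spec expects %d",
                   id, length(idx), sp$n_atoms), call. = FALSE)
  }
  wat <- ens$atoms$role == "water"
  if (any(wat)) {
    n_ox <- tapply(ens$atoms$element[wat] == "O",
                   ens$atoms$molecule_id[wat], sum)
    bad <- names(n_ox)[n_ox != 1L]
    if (length(bad))
      stop(sprintf("water molecule %s exposes %d oxygens; exactly 1 required",
                   bad[1L], n_ox[[bad[1L]]]), call. = FALSE)
  }
  invisible(ens)
}

#' @export
print.frame_ensemble <- function(x, ...) {
  cat(sprintf("<frame_ensemble> %d frame(s), %d atoms\n",
              n_frames(x), nrow(x$atoms)))
  cat(sprintf("  %d polymer(s), %d water(s); box %s A\n",
              length(x$polymer_ids), length(x$water_ids),
              paste(sprintf("%.1f", x$frames[[1]]$box), collapse = " x ")))
  invisible(x)
}

# Ensembles are immutable once constructed; a session-unique id lets
# per-frame aggregate assignments be memoized across analysis stages.
.ensemble_counter <- new.env(parent = emptyenv())
next_ensemble_uid <- function() {
  n <- (get0("n", envir = .ensemble_counter, ifnotfound = 0L)) + 1L
  assign("n", n, envir = .ensemble_counter)
  n
}

#' Number of frames in an ensemble
#' @param ens a `frame_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

# positions / box accessors
frame_positions <- function(ens, frame) ens$frames[[frame]]$positions
frame_box <- function(ens, frame) ens$frames[[frame]]$box

#' Restrict an ensemble to a subset of frames
#' @param ens a `frame_ensemble`.
#' @param frames integer vector of frame indices to keep.
#' @return a `frame_ensemble` with only the selected frames.
#' @export
subset_frames <- function(ens, frames) {
  stopifnot(all(frames >= 1L), all(frames <= n_frames(ens)))
  ens$frames <- ens$frames[frames]
  ens$uid <- next_ensemble_uid()
  ens
}

# Unwrap one molecule across periodic boundaries by walking its atoms in
# chain order and joining each atom to its predecessor by minimum image.
unwrap_molecule <- function(pos, box) {
  n <- nrow(pos)
  if (n <= 1L) return(pos)
  d <- diff(pos)
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  out <- rbind(pos[1L, , drop = FALSE], d)
  out <- apply(out, 2L, cumsum)
  dimnames(out) <- NULL
  out
}

# Unwrapped coordinates of one polymer molecule in a given frame.
polymer_coords <- function(ens, frame, molecule_id) {
  idx <- ens$molecule_atoms[[as.character(molecule_id)]]
  unwrap_molecule(frame_positions(ens, frame)[idx, , drop = FALSE],
                  frame_box(ens, frame))
}

#' Monomer centers of mass of one polymer in one frame
#'
#' The molecule is unwrapped across periodic boundaries before mass-weighted
#' monomer centers are taken, so the result is continuous in space.
#'
#' @param ens a `frame_ensemble`.
#' @param frame frame index.
#' @param molecule_id polymer molecule id.
#' @return an `n_monomers x 3` matrix of coordinates (Angstrom).
#' @export
monomer_coms <- function(ens, frame, molecule_id) {
  sp <- ens$polymer_specs[[as.character(molecule_id)]]
  pos <- polymer_coords(ens, frame, molecule_id)
  m <- sp$atom_mass
  t(vapply(sp$monomer_atom_map, function(idx) {
    w <- m[idx] / sum(m[idx])
    colSums(pos[idx, , drop = FALSE] * w)
  }, numeric(3)))
}
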