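#' Polymer topology specifications
#'
#' A `polymer_spec` describes one amphiphilic block copolymer at the
#' monomer/bead level: its architecture (linear diblock, hydrophobe- or
#' hydrophile-terminated triblock, or ring), the ordered block sequence of
#' methyl-acrylate (MA) and ethylene-oxide (EO) monomers, the map from
#' monomers to atoms, the carbonyl-oxygen atom of every MA monomer, and the
#' chemically-equivalent monomer classes induced by the chain's topological
#' symmetry.
#'
#' The coarse bead model uses three beads per MA monomer (backbone carbons,
#' carbonyl oxygen, ester methyl group) and two per EO monomer (ethylene
#' carbons, ether oxygen); bead masses sum to the monomer formula masses
#' (MA: C4H6O2, 86.09 amu; EO: C2H4O, 44.05 amu).
#'
#' @name polymer_spec
NULL

.BEADS <- list(
  MA = data.frame(
    name = c("CB", "OC", "CM"),
    element = c("C", "O", "C"),
    mass = c(27.046, 15.999, 43.045),
    stringsAsFactors = FALSE
  ),
  EO = data.frame(
    name = c("CE", "OE"),
    element = c("C", "O"),
    mass = c(28.054, 15.999),
    stringsAsFactors = FALSE
  )
)

.TOPOLOGIES <- list(
  diblock                = list(labels = c("MA", "EO"), lengths = c(12L, 30L), cyclic = FALSE),
  triblock_MA_terminated = list(labels = c("MA", "EO", "MA"), lengths = c(6L, 31L, 6L), cyclic = FALSE),
  triblock_EO_terminated = list(labels = c("EO", "MA", "EO"), lengths = c(15L, 12L, 15L), cyclic = FALSE),
  ring                   = list(labels = c("MA", "EO"), lengths = c(12L, 31L), cyclic = TRUE)
)

#' Build a polymer topology specification
#'
#' Constructs the monomer- and atom-level description of one polymer chain,
#' including the chemically-equivalent monomer classes used to pool contact
#' and hydration statistics. Classes are derived from the bonded distance of
#' each MA monomer to its nearest EO monomer (respecting cyclic closure for
#' rings): symmetric architectures (both triblocks and the ring) map their 12
#' MA monomers onto 6 classes MA1..MA6 with MA1 adjacent to the EO block,
#' while the diblock has 12 singleton classes MA1..MA12.
#'
#' @param topology_class one of `"diblock"`, `"triblock_MA_terminated"`,
#'   `"triblock_EO_terminated"`, `"ring"`.
#' @param block_lengths integer vector of monomers per block, in chain order.
#'   Defaults to the canonical compositions MA12-EO30 (diblock),
#'   MA6-EO31-MA6, EO15-MA12-EO15 and ring MA12-EO31.
#' @param atoms_per_monomer named integer vector giving beads per monomer
#'   type; the default `c(MA = 3, EO = 2)` matches the bundled bead model.
#' @return an object of class `polymer_spec`.
#' @examples
#' sp <- build_polymer_spec("triblock_MA_terminated")
#' table(sp$equivalence_classes[sp$monomer_label == "MA"])
#' @export
build_polymer_spec <- function(topology_class,
                               block_lengths = NULL,
                               atoms_per_monomer = c(MA = 3L, EO = 2L)) {
  topology_class <- match.arg(topology_class, names(.TOPOLOGIES))
  topo <- .TOPOLOGIES[[topology_class]]
  if (is.null(block_lengths)) block_lengths <- topo$lengths
  if (length(block_lengths) != length(topo$labels)) {
    stop(sprintf(
      "topology '%s' requires %d blocks (%s), got %d block lengths",
      topology_class, length(topo$labels),
      paste(topo$labels, collapse = "-"), length(block_lengths)
    ), call. = FALSE)
  }
  block_lengths <- as.integer(block_lengths)
  if (any(block_lengths < 1L)) stop("block lengths must be >= 1", call. = FALSE)

  blocks <- data.frame(label = topo$labels, n = block_lengths,
                       stringsAsFactors = FALSE)
  monomer_label <- rep(blocks$label, blocks$n)
  monomer_block <- rep(seq_len(nrow(blocks)), blocks$n)
  n_mono <- length(monomer_label)

  # atoms laid out monomer-by-monomer along the chain (1-based, per molecule)
  napm <- as.integer(atoms_per_monomer[monomer_label])
  ends <- cumsum(napm)
  starts <- ends - napm + 1L
  monomer_atom_map <- unname(Map(seq.int, starts, ends))

  atom_name <- character(ends[n_mono])
  atom_element <- character(ends[n_mono])
  atom_mass <- numeric(ends[n_mono])
  carbonyl <- rep(NA_integer_, n_mono)
  for (m in seq_len(n_mono)) {
    b <- .BEADS[[monomer_label[m]]]
    if (nrow(b) != napm[m]) {
      stop(sprintf("bead model defines %d atoms for %s monomers, spec asks %d",
                   nrow(b), monomer_label[m], napm[m]), call. = FALSE)
    }
    idx <- monomer_atom_map[[m]]
    atom_name[idx] <- b$name
    atom_element[idx] <- b$element
    atom_mass[idx] <- b$mass
    if (monomer_label[m] == "MA") carbonyl[m] <- idx[match("OC", b$name)]
  }

  spec <- structure(list(
    topology_class = topology_class,
    blocks = blocks,
    cyclic = topo$cyclic,
    n_monomers = n_mono,
    monomer_label = monomer_label,
    monomer_block = monomer_block,
    monomer_atom_map = monomer_atom_map,
    carbonyl_oxygen_map = carbonyl,
    atom_name = atom_name,
    atom_element = atom_element,
    atom_mass = atom_mass,
    n_atoms = length(atom_mass)
  ), class = "polymer_spec")
  spec$equivalence_classes <- equivalence_classes(spec)
  validate_polymer_spec(spec)
  spec
}

# Bonded monomer adjacency distance from each MA monomer to the nearest EO
# monomer; cyclic chains wrap. Returns the class label vector.
equivalence_classes <- function(spec) {
  lab <- spec$monomer_label
  n <- spec$n_monomers
  eo <- which(lab == "EO")
  out <- ifelse(lab == "EO", "EO", NA_character_)
  for (m in which(lab == "MA")) {
    d <- abs(eo - m)
    if (spec$cyclic) d <- pmin(d, n - d)
    out[m] <- paste0("MA", min(d))
  }
  out
}

#' Validate a polymer_spec's structural invariants
#'
#' Checks that every atom belongs to exactly one monomer, that block counts
#' match the monomer sequence, that every MA monomer has a carbonyl oxygen,
#' and that equivalence classes obey the chain's topological symmetry.
#'
#' @param spec a `polymer_spec`.
#' @return the spec, invisibly; errors on violation.
#' @export
validate_polymer_spec <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  all_atoms <- as.integer(unname(sort(unlist(spec$monomer_atom_map))))
  if (!identical(all_atoms, seq_len(spec$n_atoms)))
    stop("every atom index must appear in exactly one monomer", call. = FALSE)
  if (sum(spec$blocks$n) != spec$n_monomers)
    stop("block lengths do not match the monomer sequence", call. = FALSE)
  ma <- spec$monomer_label == "MA"
  if (any(is.na(spec$carbonyl_oxygen_map[ma])))
    stop("every MA monomer needs a carbonyl oxygen atom", call. = FALSE)
  if (any(!is.na(spec$carbonyl_oxygen_map[!ma])))
    stop("EO monomers must not carry a carbonyl oxygen", call. = FALSE)
  # symmetry: reversing the chain must leave class labels unchanged; for a
  # ring the reversal is composed with the cyclic rotation aligning the cycle
  cls <- spec$equivalence_classes
  rev_cls <- rev(cls)
  sym <- spec$topology_class %in%
    c("triblock_MA_terminated", "triblock_EO_terminated", "ring")
  if (sym) {
    ok <- if (spec$cyclic) {
      n <- length(cls)
      any(vapply(seq_len(n), function(s)
        identical(rev_cls[((seq_len(n) + s - 2L) %% n) + 1L], cls), logical(1)))
    } else identical(rev_cls, cls)
    if (!ok)
      stop("equivalence classes violate end-for-end chain symmetry", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.polymer_spec <- function(x, ...) {
  comp <- paste(sprintf("%s%d", x$blocks$label, x$blocks$n), collapse = "-")
  cat(sprintf("<polymer_spec> %s (%s%s)\n", x$topology_class, comp,
              if (x$cyclic) ", cyclic" else ""))
  cat(sprintf("  %d monomers, %d atoms\n", x$n_monomers, x$n_atoms))
  ma_cls <- x$equivalence_classes[x$monomer_label == "MA"]
  cat(sprintf("  MA classes: %s\n",
              paste(names(table(ma_cls)), collapse = " ")))
  invisible(x)
}

# chain-order bonded neighbor of each monomer (list of integer vectors)
monomer_adjacency <- function(spec) {
  n <- spec$n_monomers
  adj <- lapply(seq_len(n), function(m) {
    nb <- c(m - 1L, m + 1L)
    if (spec$cyclic) nb <- ((nb - 1L) %% n) + 1L
    nb[nb >= 1L & nb <= n]
  })
  adj
}
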