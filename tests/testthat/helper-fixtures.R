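# Shared fixtures and independent brute-force oracles.

tiny_micelle <- function(topology = "diblock", n_polymers = 5, seed = 1, ...) {
  sp <- build_polymer_spec(topology)
  generate_micelle(sp, n_polymers = n_polymers, seed = seed, ...)
}

# O(N^2) minimum-image distance, plain loops; the reference for everything.
bf_min_image_dist <- function(a, b, box) {
  d <- a - b
  for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  sqrt(sum(d^2))
}

# Brute-force polymer contact adjacency: all heavy-atom pairs, all polymer
# pairs, no prefilters.
bf_contact_adjacency <- function(ens, frame, cutoff) {
  ids <- ens$polymer_ids
  pos <- ens$frames[[frame]]$positions
  box <- ens$frames[[frame]]$box
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    ai <- ens$molecule_atoms[[as.character(ids[i])]]
    ai <- ai[ens$atoms$element[ai] != "H"]
    for (j in (i + 1):n) {
      aj <- ens$molecule_atoms[[as.character(ids[j])]]
      aj <- aj[ens$atoms$element[aj] != "H"]
      hit <- FALSE
      for (p in ai) {
        for (q in aj) {
          if (bf_min_image_dist(pos[p, ], pos[q, ], box) <= cutoff) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      adj[i, j] <- adj[j, i] <- hit
    }
  }
  adj
}

# Brute-force per-monomer intermolecular MA contact counts.
bf_ma_contacts <- function(ens, frame, cutoff) {
  pos <- ens$frames[[frame]]$positions
  box <- ens$frames[[frame]]$box
  rows <- list()
  for (id in as.character(ens$polymer_ids)) {
    sp <- ens$polymer_specs[[id]]
    for (mi in which(sp$monomer_label == "MA")) {
      atoms <- ens$molecule_atoms[[id]][sp$monomer_atom_map[[mi]]]
      atoms <- atoms[ens$atoms$element[atoms] != "H"]
      rows[[length(rows) + 1]] <- list(id = as.integer(id), mono = mi,
                                       class = sp$equivalence_classes[mi],
                                       atoms = atoms)
    }
  }
  counts <- numeric(length(rows))
  for (a in seq_along(rows)) {
    for (b in seq_along(rows)) {
      if (rows[[a]]$id == rows[[b]]$id) next
      for (p in rows[[a]]$atoms) for (q in rows[[b]]$atoms) {
        if (bf_min_image_dist(pos[p, ], pos[q, ], box) <= cutoff)
          counts[a] <- counts[a] + 1
      }
    }
  }
  data.frame(class = vapply(rows, `[[`, character(1), "class"),
             count = counts, stringsAsFactors = FALSE)
}

# Brute-force carbonyl-oxygen coordination numbers.
bf_carbonyl_coordination <- function(ens, frame, cutoff) {
  pos <- ens$frames[[frame]]$positions
  box <- ens$frames[[frame]]$box
  wat <- ens$water_oxygens
  out <- list()
  for (id in as.character(ens$polymer_ids)) {
    sp <- ens$polymer_specs[[id]]
    for (mi in which(!is.na(sp$carbonyl_oxygen_map))) {
      oc <- ens$molecule_atoms[[id]][sp$carbonyl_oxygen_map[mi]]
      cnt <- 0
      for (w in wat)
        if (bf_min_image_dist(pos[oc, ], pos[w, ], box) <= cutoff)
          cnt <- cnt + 1
      out[[length(out) + 1]] <- data.frame(
        polymer = as.integer(id), mono = mi,
        class = sp$equivalence_classes[mi], count = cnt)
    }
  }
  do.call(rbind, out)
}

# Analytic principal moments of a uniform solid ellipsoid (semi-axes a,b,c,
# unit mass): I_x = (b^2+c^2)/5 etc. Independent closed-form oracle.
ellipsoid_eccentricity <- function(a, b, c) {
  I <- c((b^2 + c^2) / 5, (a^2 + c^2) / 5, (a^2 + b^2) / 5)
  1 - min(I) / mean(I)
}

# Adjusted Rand index between integer label vectors (mclust is the
# independent implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Map planted family labels to integers aligned with landscape rows.
planted_family_labels <- function(ground_truth, row_index) {
  fam <- ground_truth$conformation_family[as.character(row_index$polymer_id)]
  match(fam, c("collapsed_MA", "intermediate", "extended_MA"))
}
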