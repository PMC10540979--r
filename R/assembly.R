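#' Aggregate identification and aggregation-number statistics
#'
#' Micelles are identified per frame as connected components of a polymer
#' contact graph: two polymers are in contact when any pair of their heavy
#' atoms lies within a cutoff under minimum image (single linkage, default
#' 4.5 Angstrom). Unimers count as aggregates of size one.
#'
#' @name assembly
NULL

.agg_cache <- new.env(parent = emptyenv())

heavy_atoms_of <- function(ens, id) {
  idx <- ens$molecule_atoms[[as.character(id)]]
  idx[ens$atoms$element[idx] != "H"]
}

#' Polymer contact graph of one frame
#'
#' Edge (i, j) present iff the minimum-image distance between any heavy atom
#' of polymer i and any heavy atom of polymer j is at most `cutoff`. A
#' bounding-sphere prefilter skips far pairs; the result is identical to the
#' all-pairs computation.
#'
#' @param ens a [frame_ensemble].
#' @param frame frame index.
#' @param cutoff contact cutoff (Angstrom, > 0).
#' @return symmetric logical adjacency matrix with polymer ids as dimnames.
#' @export
polymer_contact_graph <- function(ens, frame = 1L, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  ids <- ens$polymer_ids
  n <- length(ids)
  box <- frame_box(ens, frame)
  pos <- frame_positions(ens, frame)
  coords <- lapply(ids, function(id) {
    idx <- heavy_atoms_of(ens, id)
    unwrap_molecule(pos[idx, , drop = FALSE], box)
  })
  # wrap each molecule's internal COM back into the box for the prefilter
  coms <- t(vapply(coords, colMeans, numeric(3)))
  radii <- vapply(seq_len(n), function(i)
    max(sqrt(rowSums(sweep(coords[[i]], 2L, coms[i, ])^2))), numeric(1))

  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  dmat <- matrix(Inf, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        dcom <- sqrt(sum(min_image(coms[j, ] - coms[i, ], box)^2))
        if (dcom - radii[i] - radii[j] > cutoff) next
        dmin <- min(pbc_dist_mat(coords[[i]], coords[[j]], box))
        dmat[i, j] <- dmat[j, i] <- dmin
        if (dmin <= cutoff) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  attr(adj, "min_dist") <- dmat
  adj
}

#' Identify aggregates in one frame
#'
#' Aggregates are connected components of [polymer_contact_graph] (single
#' linkage). Labels are renumbered so that aggregate 1 contains the
#' lowest-numbered polymer.
#'
#' @inheritParams polymer_contact_graph
#' @return a list with `labels` (named integer vector, polymer id ->
#'   aggregate id), `sizes` (polymers per aggregate), `largest` (id of the
#'   largest aggregate) and the adjacency `graph`.
#' @export
identify_aggregates <- function(ens, frame = 1L, cutoff = 4.5) {
  key <- sprintf("%d_%d_%.6g", ens$uid %||% 0L, frame, cutoff)
  hit <- get0(key, envir = .agg_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  if (length(ls(.agg_cache)) > 5000L)
    rm(list = ls(.agg_cache), envir = .agg_cache)
  adj <- polymer_contact_graph(ens, frame, cutoff)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- stats::setNames(as.integer(comp), rownames(adj))
  # canonical numbering: by first (lowest) member polymer
  first <- tapply(seq_along(labels), labels, min)
  relabel <- match(labels, as.integer(names(sort(first))))
  labels <- stats::setNames(as.integer(relabel), names(labels))
  sizes <- as.integer(table(labels))
  out <- list(labels = labels, sizes = sizes,
              largest = which.max(sizes), graph = adj)
  assign(key, out, envir = .agg_cache)
  out
}

#' Unwrapped coordinates of one aggregate
#'
#' Re-joins the aggregate across periodic boundaries: each polymer is
#' unwrapped internally, then polymers are joined breadth-first over the
#' contact graph, each shifted by the box image that realizes the minimum
#' distance to its already-placed neighbor. Downstream geometry (shape,
#' densities, interfaces) requires these unwrapped coordinates.
#'
#' @param ens a [frame_ensemble].
#' @param frame frame index.
#' @param assignment result of [identify_aggregates] for this frame.
#' @param aggregate_id which aggregate to extract.
#' @return list with `positions` (unwrapped n x 3), `atom_index` (rows of
#'   the ensemble atom table), `members` (polymer ids).
#' @export
aggregate_coords <- function(ens, frame, assignment, aggregate_id) {
  labels <- assignment$labels
  members <- as.integer(names(labels)[labels == aggregate_id])
  if (length(members) == 0L) stop("empty aggregate selection", call. = FALSE)
  box <- frame_box(ens, frame)
  pos <- frame_positions(ens, frame)
  chain <- lapply(members, function(id) {
    idx <- ens$molecule_atoms[[as.character(id)]]
    list(idx = idx, xyz = unwrap_molecule(pos[idx, , drop = FALSE], box))
  })
  names(chain) <- members

  placed <- stats::setNames(rep(FALSE, length(members)), members)
  order_out <- integer(0)
  adj <- assignment$graph[as.character(members), as.character(members), drop = FALSE]
  queue <- members[1L]
  placed[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, cur)
    nb <- members[adj[as.character(cur), ] & !placed]
    for (j in nb) {
      # shift polymer j so its closest atom to polymer cur is at minimum image
      dm <- pbc_dist_mat(chain[[as.character(j)]]$xyz,
                         chain[[as.character(cur)]]$xyz, box)
      w <- arrayInd(which.min(dm), dim(dm))
      a <- chain[[as.character(j)]]$xyz[w[1L], ]
      b <- chain[[as.character(cur)]]$xyz[w[2L], ]
      shift <- -box * round((a - b) / box)
      chain[[as.character(j)]]$xyz <-
        sweep(chain[[as.character(j)]]$xyz, 2L, shift, "+")
      placed[as.character(j)] <- TRUE
      queue <- c(queue, j)
    }
  }
  ord <- as.character(members)
  list(positions = do.call(rbind, lapply(ord, function(id) chain[[id]]$xyz)),
       atom_index = unlist(lapply(ord, function(id) chain[[id]]$idx)),
       members = members)
}

#' Aggregation-number distribution over stationary frames
#'
#' Per frame, aggregates are identified and their sizes recorded. The
#' default probability distribution is polymer-weighted (each polymer
#' contributes the size of the aggregate it belongs to — the distribution of
#' micelle size as experienced per polymer molecule); the unweighted
#' per-aggregate variant is also reported. Largest-aggregate statistics are
#' the mean and sd of the largest size per frame.
#'
#' @param ens a [frame_ensemble].
#' @param cutoff contact cutoff (Angstrom).
#' @param stationary_range integer frame indices to analyse (default: all).
#' @return an object of class `aggregate_assignment`.
#' @export
nagg_distribution <- function(ens, cutoff = 4.5, stationary_range = NULL) {
  frames <- stationary_range %||% seq_len(n_frames(ens))
  if (length(frames) == 0L) stop("stationary_range is empty", call. = FALSE)
  per_frame <- lapply(frames, function(f) identify_aggregates(ens, f, cutoff))
  sizes_list <- lapply(per_frame, `[[`, "sizes")
  labels_list <- lapply(per_frame, `[[`, "labels")

  npol <- length(ens$polymer_ids)
  stopifnot(all(vapply(sizes_list, sum, integer(1)) == npol))

  polymer_sizes <- unlist(lapply(seq_along(frames), function(i) {
    sizes_list[[i]][labels_list[[i]]]
  }))
  pw <- table(polymer_sizes) / length(polymer_sizes)
  all_sizes <- unlist(sizes_list)
  uw <- table(all_sizes) / length(all_sizes)
  largest <- vapply(sizes_list, max, integer(1))

  structure(list(
    frames = frames,
    labels = labels_list,
    nagg = sizes_list,
    prob = stats::setNames(as.numeric(pw), names(pw)),
    prob_unweighted = stats::setNames(as.numeric(uw), names(uw)),
    largest_series = largest,
    largest_mean = mean(largest),
    largest_sd = stats::sd(largest),
    cutoff = cutoff,
    weighting = "polymer"
  ), class = "aggregate_assignment")
}

#' @export
print.aggregate_assignment <- function(x, ...) {
  cat(sprintf("<aggregate_assignment> %d frame(s), cutoff %.2f A\n",
              length(x$frames), x$cutoff))
  cat(sprintf("  largest aggregate N_agg = %.2f +/- %.2f\n",
              x$largest_mean, if (is.na(x$largest_sd)) 0 else x$largest_sd))
  cat("  polymer-weighted P(N_agg):\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Estimate the burn-in (first stationary frame)
#'
#' Slides a window of `window` frames over the largest-aggregate size
#' series and returns the smallest 0-based frame index `t` such that every
#' window starting at or after `t` has a mean within `tolerance` of the
#' final window's mean. Returns 0 for an already-stationary series. If no
#' such index exists, half the series length is returned with a warning and
#' the result is flagged via `attr(, "fallback")`.
#'
#' @param nagg_series numeric vector: largest-aggregate size per frame.
#' @param window sliding-window width (frames); series must span at least
#'   two windows.
#' @param tolerance allowed deviation of window means from the final window
#'   mean (polymers).
#' @return 0-based first stationary frame index.
#' @export
estimate_burn_in <- function(nagg_series, window = 20L, tolerance = 0.5) {
  Tn <- length(nagg_series)
  if (Tn < 2L * window)
    stop(sprintf("series of %d frames is shorter than two windows (%d)",
                 Tn, 2L * window), call. = FALSE)
  cs <- c(0, cumsum(nagg_series))
  starts <- seq_len(Tn - window + 1L)
  means <- (cs[starts + window] - cs[starts]) / window
  final <- means[length(means)]
  ok <- abs(means - final) <= tolerance
  # smallest t such that all windows from t on are within tolerance
  bad <- which(!ok)
  if (length(bad) == 0L) return(0L)
  t0 <- max(bad)                      # 0-based first stationary frame
  if (t0 > Tn - 2L * window) {
    # stationary portion shorter than two windows: no credible plateau
    warning("no stationary plateau found; falling back to half the series")
    return(structure(as.integer(floor(Tn / 2)), fallback = TRUE))
  }
  as.integer(t0)
}
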