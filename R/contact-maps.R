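#' Minimum inter-residue atom distance
#'
#' Smallest Euclidean distance over all cross pairs between two residues'
#' atom sets — the "smallest distance" semantics of classic MD contact-matrix
#' tools.
#'
#' @param coords_i,coords_j numeric matrices (n_atoms x 3), non-empty.
#' @return The minimum cross-pair distance.
#' @export
residue_min_distance <- function(coords_i, coords_j) {
  coords_i <- rbind(coords_i)
  coords_j <- rbind(coords_j)
  if (nrow(coords_i) == 0 || nrow(coords_j) == 0) {
    abort("residue atom sets must be non-empty")
  }
  d2 <- outer(rowSums(coords_i^2), rowSums(coords_j^2), "+") -
    2 * coords_i %*% t(coords_j)
  sqrt(max(min(d2), 0))
}

new_contact_map <- function(matrix, mode, cutoff, n_frames, segments,
                            normalized, index_map) {
  structure(list(matrix = matrix, mode = mode, cutoff = cutoff,
                 n_frames = n_frames, segments = segments,
                 normalized = normalized, index_map = index_map),
            class = "contact_map")
}

#' Per-segment residue contact map
#'
#' Computes the N x N residue-residue contact matrix of one trajectory
#' segment over the residues of `index_map` (N = monomers x L, global dense
#' indexing). In `"frequency"` mode entry (i, j) is the fraction of frames in
#' which the minimum inter-atom distance between residues i and j falls below
#' `cutoff`; higher values mean more frequent contacts. In `"distance"` mode
#' it is the mean over frames of that minimum distance clamped at `cutoff`
#' (mean-smallest-distance semantics). The diagonal is 1 (frequency) or 0
#' (distance). Atoms of monomers outside `index_map` are ignored.
#'
#' @param segment a [run_langevin()] segment (or any list with a
#'   frames x atoms x 3 `coords` array and a `segment_id`).
#' @param system the [molecular_system()] the segment was simulated from.
#' @param index_map a [residue_index_map()].
#' @param mode `"frequency"` or `"distance"`.
#' @param cutoff contact cutoff d_c (same length unit as the coordinates);
#'   default 4.5, the conventional heavy-atom contact distance in Angstrom.
#' @return A `contact_map` object.
#' @export
compute_contact_map <- function(segment, system, index_map,
                                mode = c("frequency", "distance"),
                                cutoff = 4.5) {
  mode <- match.arg(mode)
  coords <- segment$coords
  if (dim(coords)[2] != nrow(system$atoms)) {
    abort("segment and system disagree on atom count")
  }
  keep <- system$atoms$monomer %in% attr(index_map, "monomers")
  atoms <- system$atoms[keep, ]
  res_idx <- global_index(index_map, atoms$monomer, atoms$resno)
  n_res <- length(attr(index_map, "monomers")) * attr(index_map, "L")
  coords <- coords[, keep, , drop = FALSE]

  M <- cpp_contact_map(coords, as.integer(res_idx), as.integer(n_res),
                       if (mode == "frequency") 0L else 1L, cutoff)
  new_contact_map(M, mode, cutoff, n_frames = dim(coords)[1],
                  segments = segment$segment_id, normalized = FALSE,
                  index_map = index_map)
}

#' Sum contact maps and normalize by the matrix maximum
#'
#' Aggregates per-segment maps of one conformation by entrywise summation
#' (in segment-id order, so permuting the input list cannot change the
#' result), then divides by the maximum entry so the strongest contact is
#' exactly 1. In frequency mode the diagonal (trivially 1 every frame) is
#' excluded from the maximum search.
#'
#' @param maps non-empty list of [compute_contact_map()] results sharing
#'   shape, mode and cutoff.
#' @param normalize divide by the maximum entry (default `TRUE`).
#' @return A `contact_map` with `segments` the union of inputs and `n_frames`
#'   their total.
#' @export
aggregate_and_normalize <- function(maps, normalize = TRUE) {
  if (length(maps) == 0) abort("need at least one contact map")
  modes <- unique(vapply(maps, function(m) m$mode, character(1)))
  cuts <- unique(vapply(maps, function(m) m$cutoff, numeric(1)))
  dims <- unique(vapply(maps, function(m) nrow(m$matrix), integer(1)))
  if (length(modes) != 1 || length(cuts) != 1 || length(dims) != 1) {
    abort("maps differ in mode, cutoff or shape; cannot aggregate")
  }
  ids <- vapply(maps, function(m) paste(m$segments, collapse = "+"), character(1))
  maps <- maps[order(ids)]
  S <- Reduce(`+`, lapply(maps, function(m) m$matrix))
  if (normalize) {
    search <- S
    if (modes == "frequency") diag(search) <- -Inf
    mx <- max(search)
    if (!is.finite(mx) || mx <= 0) {
      abort("cannot normalize: aggregated map has no positive off-diagonal entry")
    }
    S <- S / mx
  }
  new_contact_map(S, modes, cuts,
                  n_frames = sum(vapply(maps, function(m) m$n_frames, numeric(1))),
                  segments = sort(unlist(lapply(maps, function(m) m$segments))),
                  normalized = normalize, index_map = maps[[1]]$index_map)
}

#' Mask near-diagonal entries of a contact map
#'
#' Zeroes entries with |i - j| <= `width` between residues of the same
#' monomer. Off by default in the pipeline: sequence-local tail contacts are
#' genuinely the strongest signal and are kept.
#'
#' @param map a `contact_map`.
#' @param width neighbour window to mask.
#' @return The masked `contact_map`.
#' @export
mask_near_diagonal <- function(map, width = 2) {
  im <- map$index_map
  L <- attr(im, "L")
  n <- nrow(map$matrix)
  g <- 0:(n - 1)
  mono <- g %/% L
  same <- outer(mono, mono, "==")
  near <- abs(outer(g, g, "-")) <= width
  map$matrix[same & near] <- 0
  map
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", nrow(x$matrix), "x", ncol(x$matrix),
      " (", x$mode, ", cutoff ", x$cutoff, ")\n", sep = "")
  cat("  ", x$n_frames, " frames over ", length(x$segments), " segment(s); ",
      if (x$normalized) "normalized" else "raw", "; max off-diag ",
      signif(max(x$matrix - diag(diag(x$matrix))), 4), "\n", sep = "")
  invisible(x)
}
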