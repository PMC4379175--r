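#' Tile a global contact map into monomer blocks
#'
#' Cuts the (n.L) x (n.L) global map into n x n blocks of L x L, block (a, b)
#' holding the interactions between monomer a and monomer b. Tiling is
#' lossless: the blocks reassemble to the original matrix exactly.
#'
#' @param map a `contact_map` whose side equals `n_monomers * L` for the
#'   monomers of `index_map`.
#' @param index_map the [residue_index_map()] defining the tiling (defaults
#'   to the one stored in `map`).
#' @return An object of class `block_decomposition`: list with `blocks`
#'   (L x L x n x n array), `L`, `n`, `monomers`, `frame_resno` (author
#'   residue numbers of the monomer frame) and the source map metadata.
#' @export
tile_blocks <- function(map, index_map = NULL) {
  index_map <- index_map %||% map$index_map
  L <- attr(index_map, "L")
  monomers <- attr(index_map, "monomers")
  n <- length(monomers)
  side <- nrow(map$matrix)
  if (side != n * L) {
    abort(paste0("map side ", side, " does not tile into ", n,
                 " monomer blocks of ", L))
  }
  blocks <- array(NA_real_, c(L, L, n, n))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      blocks[, , a, b] <- map$matrix[(a - 1) * L + seq_len(L),
                                     (b - 1) * L + seq_len(L)]
    }
  }
  frame_resno <- index_map$resno[index_map$monomer == monomers[1]]
  structure(list(blocks = blocks, L = L, n = n, monomers = monomers,
                 frame_resno = frame_resno, mode = map$mode,
                 cutoff = map$cutoff, source_normalized = map$normalized),
            class = "block_decomposition")
}

#' Reassemble blocks into the global matrix
#'
#' @param blocks a [tile_blocks()] decomposition.
#' @return The (n.L) x (n.L) matrix.
#' @export
reassemble_blocks <- function(blocks) {
  L <- blocks$L
  n <- blocks$n
  M <- matrix(NA_real_, n * L, n * L)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      M[(a - 1) * L + seq_len(L), (b - 1) * L + seq_len(L)] <- blocks$blocks[, , a, b]
    }
  }
  M
}

#' Sum monomer blocks into a symmetrized map
#'
#' Exploits ring symmetry by summing all ordered monomer-pair blocks
#' B^(a,b) over a monomer subset into one L x L monomer-frame matrix,
#' the symmetrized map. The full subset corresponds to summing every block
#' of the global map; a restricted subset (e.g. the cis-ring monomers only,
#' excluding a co-chaperone) confines the sum to those monomers'
#' interactions. Intra-ring symmetry makes the full sum invariant under any
#' relabelling of the monomers.
#'
#' @param blocks a [tile_blocks()] decomposition.
#' @param subset monomer ranks to sum over (1-based, default all).
#' @param normalize divide the summed map by its maximum off-diagonal entry
#'   afterwards (default `FALSE`; whether to re-normalize after block
#'   summation is a presentation choice, so both outputs are available).
#' @param component `"both"` sums all ordered pairs including a = b;
#'   `"intra"` only the diagonal blocks, `"inter"` only a != b.
#' @return An object of class `symmetrized_map`: list with `matrix` (L x L),
#'   `subset`, `frame_resno`, `mode`, `cutoff`, `normalized`, `component`.
#' @export
sum_blocks <- function(blocks, subset = seq_len(blocks$n), normalize = FALSE,
                       component = c("both", "intra", "inter")) {
  component <- match.arg(component)
  if (length(subset) == 0) abort("monomer subset must be non-empty")
  if (any(subset < 1 | subset > blocks$n)) {
    abort(paste0("monomer rank out of range 1..", blocks$n))
  }
  L <- blocks$L
  S <- matrix(0, L, L)
  for (a in subset) {
    for (b in subset) {
      if (component == "intra" && a != b) next
      if (component == "inter" && a == b) next
      S <- S + blocks$blocks[, , a, b]
    }
  }
  normalized <- FALSE
  if (normalize) {
    search <- S
    if (blocks$mode == "frequency") diag(search) <- -Inf
    mx <- max(search)
    if (!is.finite(mx) || mx <= 0) abort("cannot normalize an all-zero symmetrized map")
    S <- S / mx
    normalized <- TRUE
  }
  structure(list(matrix = S, subset = sort(subset),
                 monomers = blocks$monomers[sort(subset)],
                 frame_resno = blocks$frame_resno, mode = blocks$mode,
                 cutoff = blocks$cutoff, normalized = normalized,
                 component = component),
            class = "symmetrized_map")
}

#' @export
print.symmetrized_map <- function(x, ...) {
  cat("<symmetrized_map> ", nrow(x$matrix), "x", ncol(x$matrix),
      " over ", length(x$subset), " monomer(s) [", x$component, "]",
      if (x$normalized) ", normalized", "\n", sep = "")
  invisible(x)
}
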