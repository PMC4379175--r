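#' Tail rows of a symmetrized map
#'
#' Extracts the submatrix of contacts between the C-terminal tail residues
#' and every residue of the monomer frame (tail x L), rows addressed by
#' author residue numbers.
#'
#' @param sym a [sum_blocks()] symmetrized map.
#' @param tail_range author residue numbers of the tail (vector, or
#'   `c(from, to)` treated as an inclusive range when length 2 and
#'   increasing).
#' @return A matrix (length(tail) x L) with author-number dimnames.
#' @export
extract_tail_rows <- function(sym, tail_range) {
  resno <- sym$frame_resno
  tail <- expand_range(tail_range)
  idx <- match(tail, resno)
  if (anyNA(idx)) {
    abort(paste0("tail residue ", tail[is.na(idx)][1], " outside the monomer frame"))
  }
  out <- sym$matrix[idx, , drop = FALSE]
  dimnames(out) <- list(tail, resno)
  out
}

expand_range <- function(x) {
  x <- as.integer(x)
  if (length(x) == 2 && x[2] > x[1]) seq.int(x[1], x[2]) else x
}

#' Contact profile of a single terminal residue
#'
#' Pulls the row of a symmetrized map for one residue (typically the very
#' last, e.g. M548) and zeroes the entries of the given author-number ranges
#' — conventionally the whole tail, so the profile shows where the terminus
#' touches the rest of the monomer rather than its own (trivially proximal)
#' tail neighbours.
#'
#' @param sym a [sum_blocks()] symmetrized map.
#' @param residue author residue number of the terminal residue.
#' @param zero_ranges list of author-number ranges (each a vector or
#'   `c(from, to)`) whose profile entries are set to exactly 0; `NULL` keeps
#'   the raw row.
#' @return A tibble of class `tail_profile` with columns `resno`, `score`
#'   and attributes `terminal_residue`, `zeroed`, `mode`.
#' @export
terminal_profile <- function(sym, residue, zero_ranges = NULL) {
  resno <- sym$frame_resno
  i <- match(as.integer(residue), resno)
  if (is.na(i)) abort(paste0("residue ", residue, " outside the monomer frame"))
  score <- sym$matrix[i, ]
  zeroed <- integer(0)
  if (!is.null(zero_ranges)) {
    if (!is.list(zero_ranges)) zero_ranges <- list(zero_ranges)
    zeroed <- sort(unique(unlist(lapply(zero_ranges, expand_range))))
    bad <- setdiff(zeroed, resno)
    if (length(bad) > 0) {
      abort(paste0("zero range residue ", bad[1], " outside the monomer frame"))
    }
    score[match(zeroed, resno)] <- 0
  }
  structure(tibble(resno = resno, score = unname(score)),
            terminal_residue = as.integer(residue), zeroed = zeroed,
            mode = sym$mode,
            class = c("tail_profile", class(tibble())))
}

#' Rank contact partners of a profile
#'
#' Top-k nonzero profile entries in descending score order, ties broken by
#' ascending author residue number (deterministic). If fewer than `k`
#' nonzero entries exist, all of them are returned and the result is flagged
#' via the `truncated` attribute.
#'
#' @param profile a [terminal_profile()].
#' @param k number of partners requested, >= 1.
#' @return Tibble (`resno`, `score`) of at most `k` rows, attribute
#'   `truncated` TRUE when fewer than `k` nonzero entries were available.
#' @export
rank_partners <- function(profile, k) {
  if (k < 1) abort("k must be >= 1")
  nz <- profile[profile$score > 0, ]
  ord <- order(-nz$score, nz$resno)
  nz <- nz[ord, ]
  truncated <- nrow(nz) < k
  if (truncated) {
    warn(paste0("only ", nrow(nz), " nonzero entries available for k = ", k))
  }
  out <- head(nz, k)
  attr(out, "truncated") <- truncated
  out
}
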