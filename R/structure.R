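#' Molecular system container
#'
#' A `molecular_system` bundles an atom table with a monomer table. Atoms keep
#' the author residue numbering of the source file verbatim (GroEL's last
#' residue is M548 even though each monomer holds 547 residues, Met1 being
#' absent); monomers sharing a ring id must have identical length and residue
#' sequence so that ring-symmetry block summation is well defined downstream.
#'
#' @param atoms tibble with columns `monomer` (chr), `resno` (int, author
#'   numbering), `resid` (chr, residue name), `elety` (chr, atom name),
#'   `element` (chr), `x`, `y`, `z` (numeric, Angstrom), `mobile` (logical).
#' @param monomers tibble with columns `monomer`, `ring`, `L` (residue count);
#'   if `NULL` it is derived from `atoms`, grouping monomers with identical
#'   residue sequences into rings.
#' @param title character scalar.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, monomers = NULL, title = "") {
  atoms <- as_tibble(atoms)
  need <- c("monomer", "resno", "resid", "elety", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"mobile" %in% names(atoms)) atoms$mobile <- TRUE
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(monomers)) monomers <- derive_monomers(atoms)
  sys <- structure(list(atoms = atoms, monomers = as_tibble(monomers), title = title),
                   class = "molecular_system")
  validate_molecular_system(sys)
  sys
}

# group monomers with identical (L, residue-name sequence) into shared rings
derive_monomers <- function(atoms) {
  ids <- unique(atoms$monomer)
  seqs <- lapply(ids, function(m) {
    a <- atoms[atoms$monomer == m, ]
    a$resid[!duplicated(a$resno)]
  })
  key <- vapply(seqs, function(s) paste(s, collapse = "|"), character(1))
  ring <- paste0("ring", as.integer(factor(key, levels = unique(key))))
  tibble(monomer = ids, ring = ring, L = lengths(seqs))
}

validate_molecular_system <- function(sys) {
  atoms <- sys$atoms
  mono <- sys$monomers
  stray <- setdiff(unique(atoms$monomer), mono$monomer)
  if (length(stray) > 0) {
    abort(paste0("atoms reference monomer(s) absent from monomer table: ",
                 paste(stray, collapse = ", ")))
  }
  for (m in mono$monomer) {
    r <- atoms$resno[atoms$monomer == m]
    r <- r[!duplicated(r)]
    if (length(r) > 1 && any(diff(r) <= 0)) {
      abort(paste0("author residue numbers not strictly increasing in monomer ", m))
    }
  }
  for (rg in unique(mono$ring)) {
    ids <- mono$monomer[mono$ring == rg]
    if (length(ids) < 2) next
    seqs <- lapply(ids, function(m) {
      a <- atoms[atoms$monomer == m, ]
      a$resid[!duplicated(a$resno)]
    })
    if (length(unique(vapply(seqs, paste, character(1), collapse = "|"))) != 1) {
      abort(paste0("monomers of ring ", rg, " differ in residue sequence or length"))
    }
  }
  invisible(sys)
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", x$title, "\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms, ", nrow(x$monomers), " monomer(s), ",
      length(unique(x$monomers$ring)), " ring group(s)\n", sep = "")
  cat("  mobile atoms: ", sum(x$atoms$mobile), "\n", sep = "")
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM records into a [molecular_system()]. Chains become monomers and
#' author residue numbers are preserved verbatim (no renumbering). HETATM
#' records (e.g. nucleotide atoms) are ignored. Alternate locations are
#' resolved by keeping the highest-occupancy record, ties going to the first
#' encountered. Files using insertion codes are rejected as an unsupported
#' dialect.
#'
#' @param path path to a PDB file.
#' @return A [molecular_system()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  prescan_pdb(path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no ATOM records in ", path))
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy, tie -> first encountered
  at$.ord <- seq_len(nrow(at))
  at <- dplyr::group_by(at, .data$chain, .data$resno, .data$elety)
  at <- dplyr::slice(at, order(-.data$o, .data$.ord)[1])
  at <- dplyr::ungroup(at)
  at <- dplyr::arrange(at, .data$.ord)
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  atoms <- tibble(
    monomer = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z, mobile = TRUE, b = at$b
  )
  molecular_system(atoms, title = basename(path))
}

# light fixed-width validation so malformed records fail with a line number
# and insertion codes are rejected up front (bio3d reports neither)
prescan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0) abort(paste0("no ATOM records in ", path))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("malformed PDB record at line ", i, ": fewer than 54 columns"))
    }
    ins <- substr(ln, 27, 27)
    if (ins != " " && ins != "") {
      abort(paste0("insertion codes are an unsupported PDB dialect (line ", i, ")"))
    }
    nums <- suppressWarnings(as.numeric(c(substr(ln, 23, 26), substr(ln, 31, 38),
                                          substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(nums)) {
      abort(paste0("malformed PDB record at line ", i,
                   ": non-numeric residue number or coordinate"))
    }
  }
  invisible(TRUE)
}

#' Write a structure to a PDB file
#'
#' Emits ATOM records with author residue numbering preserved. Monomer ids are
#' written to the chain column (first character when longer than one).
#'
#' @param system a [molecular_system()].
#' @param path output file.
#' @param b per-atom B-factor vector (recycled scalar allowed); default 0.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, b = 0) {
  atoms <- system$atoms
  n <- nrow(atoms)
  if (length(b) == 1) b <- rep(b, n)
  if (length(b) != n) abort("b must be scalar or one value per atom")
  chain <- substr(atoms$monomer, 1, 1)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(n), elety = atoms$elety, chain = chain,
                   o = rep(1, n), b = round(b, 2), elesy = atoms$element)
  invisible(path)
}

#' Dense residue index map
#'
#' Maps (monomer id, author residue number) to a dense 0-based global index
#' `g = m * L + r`, where `m` is the monomer rank within the selection and `r`
#' the 0-based residue rank within the monomer. This is the coordinate system
#' of the full contact map and of its monomer-by-monomer block tiling.
#'
#' @param system a [molecular_system()].
#' @param monomers character vector of monomer ids to include (default: all).
#'   All selected monomers must have the same residue count L.
#' @return A tibble of class `residue_index_map` with columns `monomer`,
#'   `resno`, `global`, and attributes `L` and `monomers`.
#' @export
residue_index_map <- function(system, monomers = NULL) {
  mono <- system$monomers
  if (is.null(monomers)) monomers <- mono$monomer
  missing_m <- setdiff(monomers, mono$monomer)
  if (length(missing_m) > 0) {
    abort(paste0("unknown monomer(s): ", paste(missing_m, collapse = ", ")))
  }
  Ls <- mono$L[match(monomers, mono$monomer)]
  if (length(unique(Ls)) != 1) {
    abort("selected monomers differ in residue count; a dense index map needs equal L")
  }
  L <- Ls[1]
  rows <- purrr::map2_dfr(monomers, seq_along(monomers) - 1L, function(m, rank) {
    a <- system$atoms[system$atoms$monomer == m, ]
    resno <- a$resno[!duplicated(a$resno)]
    tibble(monomer = m, resno = resno, global = rank * L + seq_along(resno) - 1L)
  })
  structure(rows, L = L, monomers = monomers,
            class = c("residue_index_map", class(rows)))
}

#' Look up global indices
#'
#' @param map a [residue_index_map()].
#' @param monomer,resno vectors identifying residues (recycled together).
#' @return Integer vector of 0-based global indices.
#' @export
global_index <- function(map, monomer, resno) {
  key <- paste(map$monomer, map$resno)
  idx <- match(paste(monomer, resno), key)
  if (anyNA(idx)) {
    bad <- paste(monomer, resno)[is.na(idx)][1]
    abort(paste0("residue not in index map: (monomer, resno) = (", bad, ")"))
  }
  map$global[idx]
}

#' Inverse lookup of a global index
#'
#' @param map a [residue_index_map()].
#' @param global 0-based global indices.
#' @return Tibble with columns `monomer`, `resno`.
#' @export
residue_at <- function(map, global) {
  idx <- match(global, map$global)
  if (anyNA(idx)) abort("global index outside map")
  map[idx, c("monomer", "resno")]
}

#' Define the freeze group
#'
#' Splits each monomer into an immobile N-terminal core and a mobile
#' C-terminal tail, mirroring the frozen-scaffold simulation setup in which
#' only the disordered termini move. The mobile set is the last
#' `mobile_tail_length` residues of each monomer, optionally extended by one
#' preceding hinge residue; everything else is frozen. For a 547-residue
#' GroEL monomer with a 23-residue tail and the hinge included this freezes
#' the N-terminal 523 residues.
#'
#' @param system a [molecular_system()].
#' @param mobile_tail_length number of C-terminal residues left mobile; must
#'   be positive and smaller than the monomer length.
#' @param include_hinge also free the residue immediately preceding the tail.
#' @return A tibble of class `freeze_spec` with columns `monomer`, `resno`
#'   listing the frozen residues.
#' @export
define_freeze <- function(system, mobile_tail_length, include_hinge = TRUE) {
  if (mobile_tail_length <= 0) abort("mobile_tail_length must be positive")
  frozen <- purrr::map_dfr(system$monomers$monomer, function(m) {
    a <- system$atoms[system$atoms$monomer == m, ]
    resno <- a$resno[!duplicated(a$resno)]
    L <- length(resno)
    if (mobile_tail_length >= L) {
      abort(paste0("mobile_tail_length (", mobile_tail_length,
                   ") must be smaller than monomer length (", L, ") in monomer ", m))
    }
    n_mobile <- mobile_tail_length + as.integer(include_hinge)
    n_frozen <- max(L - n_mobile, 0L)
    tibble(monomer = m, resno = resno[seq_len(n_frozen)])
  })
  structure(frozen, class = c("freeze_spec", class(frozen)))
}

#' Apply a freeze spec to a system
#'
#' @param system a [molecular_system()].
#' @param freeze a [define_freeze()] spec; atoms of listed residues become
#'   immobile, all others mobile.
#' @return The system with its `mobile` flags updated.
#' @export
apply_freeze <- function(system, freeze) {
  key <- paste(freeze$monomer, freeze$resno)
  system$atoms$mobile <- !(paste(system$atoms$monomer, system$atoms$resno) %in% key)
  system
}

#' Project per-residue scores onto structure as B-factors
#'
#' Writes a PDB file whose B-factor column carries the supplied per-residue
#' scores, linearly min-max scaled to the range 0 to 99.99 (the format's
#' field limit).
#' This is how terminal-contact profiles are painted onto a representative
#' monomer for rendering. A degenerate score range (all equal) maps to 0.00;
#' residues without a score get 0.00.
#'
#' @param system a [molecular_system()].
#' @param scores tibble with columns `monomer`, `resno`, `score`; every key
#'   must exist in `system`.
#' @param path output PDB path.
#' @return Invisibly, a tibble of the scaled scores actually written.
#' @export
project_scores <- function(system, scores, path) {
  scores <- as_tibble(scores)
  sys_key <- paste(system$atoms$monomer, system$atoms$resno)
  sc_key <- paste(scores$monomer, scores$resno)
  missing_k <- !(sc_key %in% sys_key)
  if (any(missing_k)) {
    abort(paste0("score key absent from system: (monomer, resno) = (",
                 sc_key[missing_k][1], ")"))
  }
  rng <- range(scores$score)
  scaled <- if (diff(rng) == 0) rep(0, nrow(scores)) else {
    (scores$score - rng[1]) / diff(rng) * 99.99
  }
  b <- scaled[match(sys_key, sc_key)]
  b[is.na(b)] <- 0
  write_structure(system, path, b = b)
  invisible(tibble(monomer = scores$monomer, resno = scores$resno, b = scaled))
}
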