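#' Grow a coarse-grained C-terminal tail
#'
#' Appends one Calpha-level bead per tail residue to a monomer by seeded,
#' clash-avoiding chain growth, standing in for manual modelling of residues
#' missing from crystal structures (disordered C-termini do not appear in
#' electron density). Each bead is placed at `bond_length` from its
#' predecessor along an isotropic random direction, rejected and redrawn while
#' it comes closer than `clash_radius` to any atom of the system or any
#' previously placed bead (the bonded predecessor is exempt, since
#' `bond_length` may be below `clash_radius`). Author numbering continues
#' consecutively from the anchor residue, so a monomer ending at residue 525
#' grows a 23-residue tail ending at 548.
#'
#' @param system a [molecular_system()].
#' @param monomer monomer id to extend.
#' @param tail_sequence character vector of residue names, N- to C-terminal;
#'   empty means no-op.
#' @param bond_length consecutive bead distance, default 3.8 Angstrom
#'   (canonical Calpha-Calpha).
#' @param clash_radius minimum allowed distance from a new bead to every
#'   non-bonded atom, default 4.0 Angstrom.
#' @param max_attempts placement attempts per residue before giving up.
#' @param seed RNG seed; growth is bit-reproducible given the seed.
#' @return The extended [molecular_system()] (tail beads flagged mobile).
#' @export
build_tail <- function(system, monomer, tail_sequence,
                       bond_length = 3.8, clash_radius = 4.0,
                       max_attempts = 500, seed = 1) {
  if (length(tail_sequence) == 0) return(system)
  if (!monomer %in% system$monomers$monomer) {
    abort(paste0("unknown monomer: ", monomer))
  }
  atoms <- system$atoms
  sel <- atoms$monomer == monomer
  mono_atoms <- atoms[sel, ]
  last_resno <- max(mono_atoms$resno)
  last_res <- mono_atoms[mono_atoms$resno == last_resno, ]
  anchor_row <- if ("CA" %in% last_res$elety) {
    last_res[last_res$elety == "CA", ][1, ]
  } else {
    last_res[nrow(last_res), ]
  }
  anchor <- c(anchor_row$x, anchor_row$y, anchor_row$z)

  existing <- as.matrix(atoms[, c("x", "y", "z")])
  n_tail <- length(tail_sequence)
  beads <- matrix(NA_real_, n_tail, 3)

  withr::with_seed(seed, {
    prev <- anchor
    for (i in seq_len(n_tail)) {
      placed <- FALSE
      for (try in seq_len(max_attempts)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- prev + bond_length * u
        # clash set: all existing atoms + placed beads, minus the bonded
        # predecessor (the anchor for the first bead)
        d2_exist <- colSums((t(existing) - cand)^2)
        if (i == 1) {
          anchor_idx <- which(sel)[which(mono_atoms$resno == last_resno &
                                           mono_atoms$elety == anchor_row$elety)[1]]
          d2_exist <- d2_exist[-anchor_idx]
        }
        ok <- all(d2_exist >= clash_radius^2)
        if (ok && i > 2) {
          d2_beads <- colSums((t(beads[seq_len(i - 2), , drop = FALSE]) - cand)^2)
          ok <- all(d2_beads >= clash_radius^2)
        }
        if (ok) {
          beads[i, ] <- cand
          prev <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("tail growth failed at residue ", i, " of ", n_tail,
                     " after ", max_attempts, " attempts"))
      }
    }
  })

  new_atoms <- tibble(
    monomer = monomer,
    resno = last_resno + seq_len(n_tail),
    resid = tail_sequence,
    elety = "CA", element = "C",
    x = beads[, 1], y = beads[, 2], z = beads[, 3],
    mobile = TRUE
  )
  for (nm in setdiff(names(atoms), names(new_atoms))) new_atoms[[nm]] <- NA
  new_atoms <- new_atoms[, names(atoms)]

  last_of_monomer <- max(which(sel))
  out <- dplyr::bind_rows(
    atoms[seq_len(last_of_monomer), ],
    new_atoms,
    if (last_of_monomer < nrow(atoms)) atoms[(last_of_monomer + 1):nrow(atoms), ]
  )
  molecular_system(out, title = system$title)
}
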