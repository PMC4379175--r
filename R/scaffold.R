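#' Build a Cn-symmetric ring scaffold with mobile tails
#'
#' Constructs a toy bead model of a ring chaperonin: `n_monomers` identical
#' monomers placed with exact Cn symmetry about the z axis. Each monomer core
#' is a vertical column of `L_core` beads; the chain runs top to bottom so the
#' C-terminal anchor sits at the base of the column, as the real C-terminus
#' does in the equatorial domain. A disordered tail of `L_tail` beads is grown
#' from the anchor with [build_tail()] (per-monomer seeds derived from `seed`).
#' `site_spec` designates one "apical" core bead (near the top, standing in
#' for the substrate-binding helix I face) and one "equatorial" bead (near the
#' base, standing in for the stem loop); attraction wells placed on either set
#' give the generator its recoverable ground truth.
#'
#' All lengths are in reduced units (bead diameter sigma = 1).
#'
#' @param n_monomers number of monomers in the ring (1 allowed, max 26).
#' @param L_core core beads per monomer (frozen during simulation), >= 2.
#' @param L_tail tail beads per monomer (mobile), >= 0.
#' @param ring_radius distance of each core column from the z axis.
#' @param site_spec list with integer elements `apical` and `equatorial`:
#'   core residue indices (1-based along the chain) of the designated sites.
#' @param core_spacing vertical bead spacing within a core column.
#' @param bond_length tail bond length.
#' @param clash_radius tail-growth clash radius.
#' @param seed base seed; monomer m uses `seed + m`.
#' @return A [molecular_system()] with attribute `sites`: a tibble
#'   (`monomer`, `role`, `resno`) of the designated site beads.
#' @export
make_ring_scaffold <- function(n_monomers, L_core, L_tail, ring_radius,
                               site_spec = list(apical = 1L,
                                                equatorial = L_core - 1L),
                               core_spacing = 1, bond_length = 1,
                               clash_radius = 0.9, seed = 1) {
  if (n_monomers < 1) abort("n_monomers must be >= 1")
  if (n_monomers > 26) abort("at most 26 monomers supported (chain ids)")
  if (L_core < 2) abort("L_core must be >= 2")
  if (L_tail < 0) abort("L_tail must be >= 0")
  if (n_monomers >= 2) {
    chord <- 2 * ring_radius * sin(pi / n_monomers)
    if (chord < 1) {
      abort(paste0("ring_radius too small: adjacent cores only ",
                   signif(chord, 3), " sigma apart"))
    }
  }
  for (role in c("apical", "equatorial")) {
    k <- site_spec[[role]]
    if (is.null(k) || k < 1 || k > L_core) {
      abort(paste0("site_spec$", role, " must be a core residue index in 1..", L_core))
    }
  }

  ids <- LETTERS[seq_len(n_monomers)]
  atoms <- purrr::map_dfr(seq_len(n_monomers), function(m) {
    theta <- 2 * pi * (m - 1) / n_monomers
    k <- seq_len(L_core)
    tibble(
      monomer = ids[m], resno = k, resid = "ALA", elety = "CA", element = "C",
      x = ring_radius * cos(theta), y = ring_radius * sin(theta),
      z = (L_core - k) * core_spacing, mobile = FALSE
    )
  })
  sys <- molecular_system(atoms, title = sprintf("C%d ring scaffold", n_monomers))

  if (L_tail > 0) {
    for (m in seq_len(n_monomers)) {
      sys <- build_tail(sys, ids[m], rep("GLY", L_tail),
                        bond_length = bond_length, clash_radius = clash_radius,
                        seed = seed + m)
    }
  }

  sites <- purrr::map_dfr(c("apical", "equatorial"), function(role) {
    k <- as.integer(site_spec[[role]])
    tibble(monomer = ids, role = role, resno = k)
  })
  attr(sys, "sites") <- sites
  sys
}

#' Designated site beads of a scaffold
#'
#' @param system a scaffold from [make_ring_scaffold()].
#' @param role `"apical"` or `"equatorial"`.
#' @return Tibble (`monomer`, `role`, `resno`, `atom`) where `atom` is the
#'   1-based row index into the atom table.
#' @export
site_beads <- function(system, role = c("apical", "equatorial")) {
  role <- match.arg(role)
  sites <- attr(system, "sites")
  if (is.null(sites)) abort("system carries no site annotation")
  s <- sites[sites$role == role, ]
  key <- paste(system$atoms$monomer, system$atoms$resno)
  s$atom <- match(paste(s$monomer, s$resno), key)
  s
}

#' Attraction wells on designated sites
#'
#' Builds the well table for [sim_params()] placing one Gaussian attraction
#' well of depth `epsilon` (in kT) and range `range` (sigma) on every site
#' bead of the chosen role: `"open"` mode attracts the tails to the apical
#' sites, `"closed"` mode to the equatorial sites.
#'
#' @param system a scaffold from [make_ring_scaffold()].
#' @param mode `"open"` (apical wells) or `"closed"` (equatorial wells).
#' @param epsilon well depth in kT units.
#' @param range well width in sigma units.
#' @return Tibble (`atom`, `epsilon`, `range`).
#' @export
site_wells <- function(system, mode = c("open", "closed"),
                       epsilon = 3, range = 1.5) {
  mode <- match.arg(mode)
  role <- if (mode == "open") "apical" else "equatorial"
  s <- site_beads(system, role)
  tibble(atom = s$atom, epsilon = epsilon, range = range)
}
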