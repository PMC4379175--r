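#' Langevin simulation parameters
#'
#' Parameters of the coarse-grained Langevin simulator, in reduced units
#' (kT = 1, bead mass = 1, bead diameter sigma = 1 by default). The potential
#' is harmonic bonds along each chain, WCA purely repulsive excluded volume
#' between every mobile-any non-bonded pair, and optional Gaussian attraction
#' wells between mobile beads and designated site beads. The integrator is
#' BAOAB splitting; the stability bound `dt <= 0.01 * sqrt(mass / k_bond)` is
#' enforced at construction. A nominal physical temperature may be recorded as
#' metadata (`temperature_label`); it does not enter the dynamics, which know
#' only kT.
#'
#' @param kT thermal energy (reduced), > 0.
#' @param gamma friction coefficient (1/time), > 0.
#' @param mass bead mass.
#' @param dt integration timestep.
#' @param n_steps number of integration steps.
#' @param k_bond bond spring constant (energy/length^2).
#' @param r0 equilibrium bond length.
#' @param sigma excluded-volume diameter, > 0.
#' @param wells tibble (`atom`, `epsilon`, `range`) of attraction wells, or
#'   `NULL` for none; `atom` is a 1-based row index into the atom table.
#' @param seed RNG seed.
#' @param frame_interval default steps between recorded frames.
#' @param temperature_label optional nominal temperature metadata (e.g. 370).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(kT = 1, gamma = 1, mass = 1, dt = 0.001,
                       n_steps = 2e5, k_bond = 100, r0 = 1, sigma = 1,
                       wells = NULL, seed = 1, frame_interval = 100,
                       temperature_label = NULL) {
  if (dt <= 0) abort("dt must be positive")
  if (gamma <= 0) abort("gamma must be positive")
  if (kT <= 0) abort("kT must be positive")
  if (sigma <= 0) abort("sigma must be positive")
  bound <- 0.01 * sqrt(mass / k_bond)
  if (dt > bound * (1 + 1e-12)) {
    abort(paste0("unstable timestep: dt = ", dt, " exceeds 0.01*sqrt(mass/k_bond) = ",
                 signif(bound, 6)))
  }
  if (!is.null(wells)) {
    wells <- as_tibble(wells)
    stopifnot(all(c("atom", "epsilon", "range") %in% names(wells)))
  }
  structure(list(kT = kT, gamma = gamma, mass = mass, dt = dt,
                 n_steps = as.integer(n_steps), k_bond = k_bond, r0 = r0,
                 sigma = sigma, wells = wells, seed = as.integer(seed),
                 frame_interval = as.integer(frame_interval),
                 temperature_label = temperature_label),
            class = "sim_params")
}

# chain bonds between consecutive residues of each monomer, restricted to
# bonds touching at least one mobile bead (frozen-frozen bonds exert no force)
chain_bonds <- function(system) {
  atoms <- system$atoms
  per_res <- table(paste(atoms$monomer, atoms$resno))
  if (any(per_res > 1)) {
    abort("the CG simulator expects one bead per residue (Calpha-level systems)")
  }
  out <- list()
  for (m in system$monomers$monomer) {
    idx <- which(atoms$monomer == m)
    if (length(idx) < 2) next
    i <- idx[-length(idx)]
    j <- idx[-1]
    keep <- atoms$mobile[i] | atoms$mobile[j]
    out[[m]] <- cbind(i[keep], j[keep])
  }
  bonds <- do.call(rbind, out)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds
}

#' Run a frozen-core Langevin segment
#'
#' Integrates the mobile beads of `system` under the potential described in
#' [sim_params()] while frozen beads stay exactly fixed. Frames are recorded
#' at evenly spaced steps (including the initial configuration). The mobile
#' kinetic temperature averaged over the second half of the run is stored in
#' the segment for thermostat diagnostics. Deterministic given `params$seed`.
#'
#' @param system a Calpha-bead [molecular_system()]; its `mobile` flags define
#'   the freeze group unless `freeze` is given.
#' @param params a [sim_params()].
#' @param freeze optional [define_freeze()] spec applied before the run.
#' @param n_frames number of frames to record; default derives from
#'   `params$frame_interval`.
#' @param segment_id,role segment metadata (`role` is `"equilibration"` or
#'   `"production"`).
#' @return An object of class `trajectory_segment`: list with `coords`
#'   (n_frames x n_atoms x 3 array), `step_index`, `segment_id`, `role`,
#'   `seed`, `mobile`, `kinetic_temperature`, `frame_temperature`, `params`.
#' @export
run_langevin <- function(system, params, freeze = NULL, n_frames = NULL,
                         segment_id = "seg-1",
                         role = c("production", "equilibration")) {
  role <- match.arg(role)
  if (!is.null(freeze)) system <- apply_freeze(system, freeze)
  atoms <- system$atoms
  n <- nrow(atoms)
  if (is.null(n_frames)) {
    n_frames <- params$n_steps %/% params$frame_interval + 1L
  }
  if (n_frames < 1) abort("n_frames must be >= 1")
  record_steps <- unique(as.integer(round(
    seq(0, params$n_steps, length.out = n_frames))))

  bonds <- chain_bonds(system)
  wells <- params$wells
  wmat <- if (is.null(wells) || nrow(wells) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    if (any(wells$atom < 1 | wells$atom > n)) abort("well site atom index out of range")
    cbind(wells$atom - 1, wells$epsilon, wells$range)
  }

  res <- withr::with_seed(params$seed, cpp_run_langevin(
    coords0 = as.matrix(atoms[, c("x", "y", "z")]),
    mobile = atoms$mobile,
    bonds = matrix(as.integer(bonds - 1L), ncol = 2),
    k_bond = params$k_bond, r0 = params$r0, sigma = params$sigma,
    wells = wmat, kT = params$kT, gamma = params$gamma, dt = params$dt,
    mass = params$mass, n_steps = params$n_steps,
    record_steps = record_steps
  ))

  structure(list(
    coords = res$frames,
    step_index = record_steps,
    n_frames = length(record_steps),
    segment_id = segment_id, role = role, seed = params$seed,
    mobile = atoms$mobile,
    kinetic_temperature = res$kinetic_temperature,
    frame_temperature = res$frame_temperature,
    params = params
  ), class = "trajectory_segment")
}

#' @export
print.trajectory_segment <- function(x, ...) {
  cat("<trajectory_segment> ", x$segment_id, " (", x$role, ")\n", sep = "")
  cat("  ", x$n_frames, " frames x ", dim(x$coords)[2], " beads; seed ", x$seed,
      "; kinetic T = ", signif(x$kinetic_temperature, 4), "\n", sep = "")
  invisible(x)
}

#' Final frame of a segment
#'
#' @param segment a [run_langevin()] segment.
#' @return n_atoms x 3 coordinate matrix of the last recorded frame.
#' @export
final_frame <- function(segment) {
  f <- segment$n_frames
  matrix(segment$coords[f, , ], ncol = 3)
}

#' Replace coordinates of a system
#'
#' @param system a [molecular_system()].
#' @param coords n_atoms x 3 matrix.
#' @return The system with updated coordinates.
#' @export
set_coords <- function(system, coords) {
  if (nrow(coords) != nrow(system$atoms)) abort("coordinate count mismatch")
  system$atoms$x <- coords[, 1]
  system$atoms$y <- coords[, 2]
  system$atoms$z <- coords[, 3]
  system
}
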