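# Fixtures and independent oracles shared across the suite.
# Oracles are deliberately naive (quadruple loops, exhaustive sorts,
# numerical minimization) and never call the code paths they check.

# Hand-written PDB text: one CA atom per residue at given coordinates.
write_toy_pdb <- function(path, coords, resno, chain = "A",
                          resid = "ALA", elety = " CA ", b = 0) {
  n <- nrow(coords)
  chain <- rep(chain, length.out = n)
  resid <- rep(resid, length.out = n)
  b <- rep(b, length.out = n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, elety, resid[i], chain[i], resno[i],
            coords[i, 1], coords[i, 2], coords[i, 3], 1.0, b[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# A small two-chain CA-only system built in memory.
toy_two_chain_system <- function(L = 5) {
  atoms <- tibble::tibble(
    monomer = rep(c("A", "B"), each = L),
    resno = rep(seq_len(L), 2),
    resid = "ALA", elety = "CA", element = "C",
    x = c(seq_len(L), seq_len(L) + 10), y = 0, z = 0,
    mobile = TRUE
  )
  ringtail::molecular_system(atoms)
}

# Brute-force contact map: frames x residue pairs x atom pairs, straight
# loops, no vectorization shared with the implementation.
oracle_contact_map <- function(coords, res_of_atom, n_res, mode, cutoff) {
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  M <- matrix(0, n_res, n_res)
  for (a in seq_len(n_res)) {
    for (b in seq_len(n_res)) {
      if (a == b) next
      ai <- which(res_of_atom == a)
      bi <- which(res_of_atom == b)
      acc <- 0
      for (f in seq_len(n_frames)) {
        dmin <- Inf
        for (i in ai) for (j in bi) {
          d <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
          if (d < dmin) dmin <- d
        }
        if (mode == "frequency") {
          if (dmin < cutoff) acc <- acc + 1
        } else {
          acc <- acc + min(dmin, cutoff)
        }
      }
      M[a, b] <- acc / n_frames
    }
  }
  diag(M) <- if (mode == "frequency") 1 else 0
  M
}

# Independent rigid-fit oracle: numerical minimization of RMSD over a
# rotation-vector parameterization plus translation.
oracle_min_rmsd <- function(A, B) {
  rotvec_to_mat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(p) {
    R <- rotvec_to_mat(p[1:3])
    moved <- sweep(B %*% t(R), 2, p[4:6], "+")
    sqrt(mean(rowSums((A - moved)^2)))
  }
  best <- Inf
  set.seed(99)
  for (start in seq_len(8)) {
    p0 <- c(stats::runif(3, -pi, pi), colMeans(A) - colMeans(B))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Small deterministic trajectory segment wrapper for contact-map tests.
as_segment <- function(coords, segment_id = "toy") {
  structure(list(coords = coords, step_index = seq_len(dim(coords)[1]) - 1L,
                 n_frames = dim(coords)[1], segment_id = segment_id,
                 role = "production", seed = 0L,
                 mobile = rep(TRUE, dim(coords)[2]),
                 kinetic_temperature = NA_real_),
            class = "trajectory_segment")
}

# Demo-scale ground-truth run shared by property and acceptance tests.
recovery_run <- function(mode, seed, n_steps = 2e5) {
  sc <- make_ring_scaffold(3, 4, 5, 2.5, seed = seed)
  sc <- apply_freeze(sc, define_freeze(sc, 5, include_hinge = FALSE))
  p <- sim_params(n_steps = n_steps,
                  wells = site_wells(sc, mode, epsilon = 3, range = 1.5),
                  seed = seed * 100 + 7)
  seg <- run_langevin(sc, p)
  imap <- residue_index_map(sc)
  cm <- compute_contact_map(seg, sc, imap, "frequency", cutoff = 1.3)
  sym <- sum_blocks(tile_blocks(aggregate_and_normalize(list(cm)), imap))
  terminal_profile(sym, 9, zero_ranges = list(c(5, 9)))
}
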