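#' Kabsch least-squares superposition
#'
#' Closed-form optimal rigid superposition of paired point sets: the
#' rotation R and translation t minimizing the RMSD of `R b + t` against
#' `a` over all pairs, with the reflection case corrected so R is always a
#' proper rotation (det = +1).
#'
#' @param coords_a,coords_b numeric matrices (n x 3); `coords_b` is moved
#'   onto `coords_a`.
#' @param pairing optional 2-column index matrix pairing rows of `coords_a`
#'   with rows of `coords_b`; default pairs row i with row i.
#' @return An object of class `superposition_result`: list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd`, `n_pairs`, `n_cycles = 0`.
#' @export
kabsch <- function(coords_a, coords_b, pairing = NULL) {
  if (!is.null(pairing)) {
    coords_a <- coords_a[pairing[, 1], , drop = FALSE]
    coords_b <- coords_b[pairing[, 2], , drop = FALSE]
  }
  n <- nrow(coords_a)
  if (n != nrow(coords_b)) abort("paired coordinate sets differ in size")
  if (n < 3) abort("need at least 3 paired atoms")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  if (svd(A)$d[2] < 1e-9 * max(svd(A)$d[1], 1) ||
      svd(B)$d[2] < 1e-9 * max(svd(B)$d[1], 1)) {
    abort("paired atoms are collinear; superposition underdetermined")
  }
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(ca - R %*% cb)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - moved)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_pairs = n, n_cycles = 0L),
            class = "superposition_result")
}

#' Apply a superposition to coordinates
#'
#' @param result a `superposition_result`.
#' @param coords n x 3 matrix (the "moving" frame).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(result, coords) {
  sweep(coords %*% t(result$rotation), 2, result$translation, "+")
}

# pair atoms of two systems on (monomer rank, monomer-relative residue
# number, atom name); sequence offsets between author numberings reconciled
# by subtracting each monomer's first residue number
pair_atoms <- function(system_a, system_b) {
  key <- function(sys) {
    atoms <- sys$atoms
    ranks <- match(atoms$monomer, sys$monomers$monomer)
    first <- tapply(atoms$resno, atoms$monomer, min)
    rel <- atoms$resno - as.integer(first[atoms$monomer])
    paste(ranks, rel, trimws(atoms$elety))
  }
  ka <- key(system_a)
  kb <- key(system_b)
  ia <- match(kb, ka)
  pairs <- cbind(ia[!is.na(ia)], which(!is.na(ia)))
  dropped <- (nrow(system_a$atoms) - nrow(pairs)) + sum(is.na(ia))
  attr(pairs, "n_unmatched") <- dropped
  pairs
}

#' Superpose two systems with iterative outlier rejection
#'
#' Pairs atoms by monomer-relative residue number and atom name, then
#' alternates Kabsch superposition with pruning of pairs whose deviation
#' exceeds `sigma_factor` times the RMS pair deviation of the current fit,
#' the way interactive alignment tools refine a fit. Reports both the RMSD over the
#' retained pairs and the all-atom RMSD of every pair under the final
#' transform (conformer comparisons are usually quoted as the latter).
#'
#' @param system_a,system_b [molecular_system()] objects with a common core.
#' @param cycles maximum rejection cycles (default 5).
#' @param sigma_factor pruning threshold in standard deviations (default 2).
#' @return A `superposition_result` with additional fields `rmsd_all`
#'   (all-pair RMSD under the final transform), `n_pairs_total`, and
#'   `n_unmatched` (atoms without a partner, dropped before fitting).
#' @export
align_with_rejection <- function(system_a, system_b, cycles = 5,
                                 sigma_factor = 2.0) {
  pairs <- pair_atoms(system_a, system_b)
  if (nrow(pairs) == 0) abort("no atom pairs in common between the two systems")
  A <- as.matrix(system_a$atoms[pairs[, 1], c("x", "y", "z")])
  B <- as.matrix(system_b$atoms[pairs[, 2], c("x", "y", "z")])
  keep <- rep(TRUE, nrow(A))
  fit <- kabsch(A, B)
  n_cycles <- 0L
  for (cyc in seq_len(cycles)) {
    fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    dev <- sqrt(rowSums((A - apply_superposition(fit, B))^2))
    # spread measured as the RMS deviation about zero: deviation norms are
    # one-sided, so a centered sd would prune well-fitted pairs en masse
    s <- sqrt(mean(dev[keep]^2))
    if (!is.finite(s) || s < 1e-9) break
    drop_now <- keep & dev > sigma_factor * s
    if (!any(drop_now)) break
    keep <- keep & !drop_now
    n_cycles <- cyc
    if (sum(keep) < 3) abort("outlier rejection left fewer than 3 pairs")
  }
  fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
  dev_all <- rowSums((A - apply_superposition(fit, B))^2)
  fit$rmsd_all <- sqrt(mean(dev_all))
  fit$n_pairs_total <- nrow(A)
  fit$n_cycles <- n_cycles
  fit$n_unmatched <- attr(pairs, "n_unmatched")
  fit
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result> rmsd ", signif(x$rmsd, 4), " over ", x$n_pairs,
      " pairs (", x$n_cycles, " rejection cycle(s))\n", sep = "")
  if (!is.null(x$rmsd_all)) {
    cat("  all-atom rmsd ", signif(x$rmsd_all, 4), " over ", x$n_pairs_total,
        " pairs\n", sep = "")
  }
  invisible(x)
}
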