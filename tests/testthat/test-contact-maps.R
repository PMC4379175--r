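make_map <- function(M, mode = "frequency", cutoff = 4.5, n_frames = 1,
                     segments = "s1") {
  structure(list(matrix = M, mode = mode, cutoff = cutoff,
                 n_frames = n_frames, segments = segments,
                 normalized = FALSE, index_map = NULL),
            class = "contact_map")
}

test_that("residue_min_distance is the exhaustive cross-pair minimum", {
  expect_equal(residue_min_distance(matrix(c(1, 2, 3), 1),
                                    matrix(c(1, 2, 3), 1)), 0)
  expect_equal(residue_min_distance(matrix(0, 1, 3),
                                    rbind(c(3, 4, 0), c(10, 0, 0))), 5)
  set.seed(17)
  for (rep in 1:5) {
    a <- matrix(stats::rnorm(12), 4, 3)
    b <- matrix(stats::rnorm(9), 3, 3)
    brute <- min(apply(a, 1, function(p) {
      apply(b, 1, function(q) sqrt(sum((p - q)^2)))
    }))
    expect_equal(residue_min_distance(a, b), brute, tolerance = 1e-12)
  }
  expect_error(residue_min_distance(matrix(numeric(0), 0, 3), matrix(0, 1, 3)),
               "non-empty")
})

test_that("contact maps follow frequency and clamped-distance definitions", {
  sys <- molecular_system(tibble::tibble(
    monomer = "A", resno = 1:2, resid = "ALA", elety = "CA", element = "C",
    x = c(0, 3), y = 0, z = 0, mobile = TRUE))
  imap <- residue_index_map(sys)

  coords1 <- array(0, c(1, 2, 3))
  coords1[1, 2, 1] <- 3
  m1 <- compute_contact_map(as_segment(coords1), sys, imap, "frequency", 4.5)
  expect_equal(m1$matrix[1, 2], 1)
  expect_equal(diag(m1$matrix), c(1, 1))

  coords2 <- array(0, c(2, 2, 3))
  coords2[1, 2, 1] <- 3
  coords2[2, 2, 1] <- 6
  mf <- compute_contact_map(as_segment(coords2), sys, imap, "frequency", 4.5)
  expect_equal(mf$matrix[1, 2], 0.5)
  md <- compute_contact_map(as_segment(coords2), sys, imap, "distance", 4.5)
  expect_equal(md$matrix[1, 2], (3 + 4.5) / 2)
  expect_equal(diag(md$matrix), c(0, 0))
})

test_that("contact maps match the brute-force quadruple-loop oracle exactly", {
  set.seed(31)
  n_res <- 10
  atoms_per_res <- sample(1:3, n_res, replace = TRUE)
  res_of_atom <- rep(seq_len(n_res), atoms_per_res)
  n_atoms <- length(res_of_atom)
  sys <- molecular_system(tibble::tibble(
    monomer = "A", resno = res_of_atom, resid = "ALA",
    elety = paste0("C", sequence(atoms_per_res)), element = "C",
    x = stats::rnorm(n_atoms, sd = 3), y = stats::rnorm(n_atoms, sd = 3),
    z = stats::rnorm(n_atoms, sd = 3), mobile = TRUE))
  imap <- residue_index_map(sys)
  coords <- array(stats::rnorm(8 * n_atoms * 3, sd = 3), c(8, n_atoms, 3))
  seg <- as_segment(coords)
  for (mode in c("frequency", "distance")) {
    got <- compute_contact_map(seg, sys, imap, mode, cutoff = 4)
    want <- oracle_contact_map(coords, res_of_atom, n_res, mode, 4)
    expect_equal(got$matrix, want, tolerance = 1e-15)
    expect_identical(got$matrix, t(got$matrix))  # exact symmetry
  }
})

test_that("raising the cutoff never lowers a contact frequency", {
  set.seed(5)
  n_atoms <- 12
  sys <- molecular_system(tibble::tibble(
    monomer = "A", resno = seq_len(n_atoms), resid = "ALA", elety = "CA",
    element = "C", x = stats::rnorm(n_atoms, sd = 2),
    y = stats::rnorm(n_atoms, sd = 2), z = stats::rnorm(n_atoms, sd = 2),
    mobile = TRUE))
  imap <- residue_index_map(sys)
  coords <- array(stats::rnorm(5 * n_atoms * 3, sd = 2), c(5, n_atoms, 3))
  maps <- lapply(c(2, 3, 4.5, 6), function(dc) {
    compute_contact_map(as_segment(coords), sys, imap, "frequency", dc)$matrix
  })
  for (k in seq_len(length(maps) - 1)) {
    expect_true(all(maps[[k + 1]] - maps[[k]] >= 0))
  }
})

test_that("aggregation sums then normalizes by the off-diagonal maximum", {
  A <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  one <- aggregate_and_normalize(list(make_map(A)))
  expect_equal(one$matrix[1, 2], 1)
  expect_true(one$normalized)

  # 19 identical maps behave like a single normalized map
  nineteen <- aggregate_and_normalize(
    lapply(sprintf("s%02d", 1:19), function(id) make_map(A, segments = id)))
  expect_equal(nineteen$matrix, one$matrix)
  expect_equal(length(nineteen$segments), 19)
  expect_equal(max(nineteen$matrix[row(nineteen$matrix) != col(nineteen$matrix)]), 1)

  # hand computation on 3x3 fixtures
  B1 <- matrix(c(1, .2, .1, .2, 1, .5, .1, .5, 1), 3, 3)
  B2 <- matrix(c(1, .3, .2, .3, 1, .1, .2, .1, 1), 3, 3)
  agg <- aggregate_and_normalize(list(make_map(B1, segments = "a"),
                                      make_map(B2, segments = "b")))
  S <- B1 + B2
  diag(S) <- NA
  expect_equal(agg$matrix[1, 2], (B1 + B2)[1, 2] / max(S, na.rm = TRUE))
})

test_that("aggregation is order-invariant and validates its inputs", {
  set.seed(7)
  maps <- lapply(sprintf("s%02d", 1:6), function(id) {
    M <- matrix(stats::runif(16), 4, 4)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    make_map(M, segments = id)
  })
  a <- aggregate_and_normalize(maps)
  b <- aggregate_and_normalize(rev(maps))
  expect_identical(a$matrix, b$matrix)

  expect_error(aggregate_and_normalize(list()), "at least one")
  expect_error(aggregate_and_normalize(list(maps[[1]],
                                            make_map(matrix(1, 2, 2)))),
               "mode, cutoff or shape")
  zero <- matrix(0, 3, 3)
  diag(zero) <- 1
  expect_error(aggregate_and_normalize(list(make_map(zero))), "normalize")
})

test_that("near-diagonal masking zeroes only in-monomer neighbours", {
  sys <- toy_two_chain_system(4)
  imap <- residue_index_map(sys)
  M <- matrix(1, 8, 8)
  cm <- make_map(M)
  cm$index_map <- imap
  masked <- mask_near_diagonal(cm, width = 1)
  expect_equal(masked$matrix[1, 2], 0)   # neighbours within monomer A
  expect_equal(masked$matrix[4, 5], 1)   # A4-B1: adjacent indices, different monomers
  expect_equal(masked$matrix[1, 3], 1)
})
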