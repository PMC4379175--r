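test_that("PDB round trip preserves atoms, numbering and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  coords <- matrix(c(1.234, 2.345, 3.456,
                     4.001, 5.002, 6.003,
                     7.5, 8.25, 9.125), 3, 3, byrow = TRUE)
  write_toy_pdb(path, coords, resno = c(2, 3, 4))
  sys <- read_structure(path)
  expect_equal(nrow(sys$atoms), 3)
  expect_equal(sys$atoms$resno, c(2L, 3L, 4L))
  expect_equal(as.matrix(sys$atoms[, c("x", "y", "z")]), coords,
               ignore_attr = TRUE, tolerance = 1e-3)

  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, out)
  sys2 <- read_structure(out)
  expect_equal(sys2$atoms$resno, sys$atoms$resno)
  expect_equal(sys2$atoms$elety, sys$atoms$elety)
  expect_equal(sys2$atoms$resid, sys$atoms$resid)
  expect_equal(as.matrix(sys2$atoms[, c("x", "y", "z")]),
               as.matrix(sys$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("malformed and insertion-code records are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   2       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   3       bad      2.0     3.0   1.00  0.00"
  ), path)
  expect_error(read_structure(path), "line 2")

  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   2A      1.000   2.000   3.000  1.00  0.00"
  ), path2)
  expect_error(read_structure(path2), "insertion code")
})

test_that("altloc records resolve to highest occupancy, tie to first", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   2       1.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BALA A   2       2.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA AALA A   3       3.000   0.000   0.000  0.50  0.00",
    "ATOM      4  CA BALA A   3       4.000   0.000   0.000  0.50  0.00",
    "END"
  ), path)
  sys <- read_structure(path)
  expect_equal(nrow(sys$atoms), 2)
  expect_equal(sys$atoms$x, c(2, 3))  # B wins on occupancy; A wins the tie
})

test_that("residue index map is a bijection with dense m*L + r indexing", {
  sys <- toy_two_chain_system(L = 5)
  imap <- residue_index_map(sys)
  expect_equal(imap$global, 0:9)
  expect_equal(global_index(imap, "A", 1), 0L)
  expect_equal(global_index(imap, "B", 5), 9L)
  # round-trip identity over every index, including randomized fixtures
  for (L in c(3, 7, 11)) {
    sysL <- toy_two_chain_system(L = L)
    m <- residue_index_map(sysL)
    back <- residue_at(m, m$global)
    expect_equal(global_index(m, back$monomer, back$resno), m$global)
  }
  expect_error(global_index(imap, "A", 99), "not in index map")
})

test_that("freeze definition leaves the C-terminal tail mobile", {
  # 547-residue monomer (author numbering 2..548, Met1 absent)
  atoms <- tibble::tibble(monomer = "A", resno = 2:548, resid = "ALA",
                          elety = "CA", element = "C",
                          x = seq(0, by = 3.8, length.out = 547), y = 0, z = 0,
                          mobile = TRUE)
  sys <- molecular_system(atoms)
  fr <- define_freeze(sys, 23, include_hinge = TRUE)
  expect_equal(nrow(fr), 523)           # N-terminal 523 residues frozen
  expect_equal(max(fr$resno), 524)      # hinge residue 525 left mobile
  fr2 <- define_freeze(sys, 23, include_hinge = FALSE)
  expect_equal(nrow(fr2), 524)
  sys2 <- apply_freeze(sys, fr)
  expect_equal(sum(!sys2$atoms$mobile), 523)
  expect_error(define_freeze(toy_two_chain_system(5), 5), "smaller than")
  expect_error(define_freeze(sys, 0), "positive")
})

test_that("score projection scales linearly to the B-factor range", {
  sys <- toy_two_chain_system(L = 5)
  sysA <- molecular_system(sys$atoms[sys$atoms$monomer == "A", ])
  path <- withr::local_tempfile(fileext = ".pdb")

  scores <- tibble::tibble(monomer = "A", resno = 1:5, score = 0:4)
  project_scores(sysA, scores, path)
  reread <- read_structure(path)
  expect_equal(reread$atoms$b, c(0, 25, 50, 74.99, 99.99), tolerance = 0.011)

  # degenerate range maps to the minimum
  scores$score <- 7
  project_scores(sysA, scores, path)
  expect_equal(read_structure(path)$atoms$b, rep(0, 5))

  # endpoints
  sc2 <- tibble::tibble(monomer = "A", resno = 2:3, score = c(0, 1))
  project_scores(sysA, sc2, path)
  b <- read_structure(path)$atoms$b
  expect_equal(b, c(0, 0, 99.99, 0, 0), tolerance = 0.011)

  expect_error(project_scores(sysA, tibble::tibble(monomer = "A", resno = 99,
                                                   score = 1), path),
               "99")
})

test_that("ring grouping enforces identical sequences and flags strays", {
  atoms <- toy_two_chain_system(5)$atoms
  atoms$resid[atoms$monomer == "B"] <- "GLY"
  sys <- molecular_system(atoms)   # differing sequences -> separate rings
  expect_equal(length(unique(sys$monomers$ring)), 2)
  bad <- atoms
  bad$monomer[1] <- "Z"
  bad <- bad[order(bad$monomer), ]
  expect_error(molecular_system(bad[bad$monomer != "Z" | TRUE, ],
                                monomers = tibble::tibble(monomer = c("A", "B"),
                                                          ring = "r", L = 5)),
               "absent from monomer table")
})
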