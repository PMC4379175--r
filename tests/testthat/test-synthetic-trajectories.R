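test_that("ring scaffold has exact Cn symmetry and expected bead counts", {
  sc <- make_ring_scaffold(7, 30, 5, 6, seed = 1)
  expect_equal(nrow(sc$atoms), 7 * 35)
  core <- sc$atoms[!sc$atoms$mobile, ]
  a <- as.matrix(core[core$monomer == "A", c("x", "y", "z")])
  b <- as.matrix(core[core$monomer == "B", c("x", "y", "z")])
  th <- 2 * pi / 7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  expect_equal(a %*% t(Rz), b, tolerance = 1e-9, ignore_attr = TRUE)

  sc1 <- make_ring_scaffold(1, 4, 2, 3, seed = 1)
  expect_equal(nrow(sc1$monomers), 1)
  expect_error(make_ring_scaffold(12, 4, 0, 0.5, seed = 1), "ring_radius too small")
})

test_that("unstable timesteps and bad parameters are rejected", {
  expect_error(sim_params(dt = 0.01, k_bond = 100), "unstable timestep")
  expect_error(sim_params(kT = 0), "kT")
  expect_error(sim_params(gamma = -1), "gamma")
})

test_that("frozen beads never move and all-frozen runs are static", {
  sc <- make_ring_scaffold(2, 4, 3, 2, seed = 2)
  all_frozen <- sc
  all_frozen$atoms$mobile <- FALSE
  p <- sim_params(n_steps = 500, seed = 4)
  seg <- run_langevin(all_frozen, p)
  for (f in seq_len(seg$n_frames)) {
    expect_identical(matrix(seg$coords[f, , ], ncol = 3),
                     matrix(seg$coords[1, , ], ncol = 3))
  }

  sc <- apply_freeze(sc, define_freeze(sc, 3, include_hinge = FALSE))
  seg2 <- run_langevin(sc, sim_params(n_steps = 2000, seed = 5))
  frozen_idx <- which(!sc$atoms$mobile)
  disp <- apply(seg2$coords[, frozen_idx, , drop = FALSE], c(2, 3),
                function(v) max(abs(v - v[1])))
  expect_identical(max(disp), 0)
  mobile_idx <- which(sc$atoms$mobile)
  expect_gt(max(abs(seg2$coords[seg2$n_frames, mobile_idx, ] -
                      seg2$coords[1, mobile_idx, ])), 0)
})

test_that("identical seeds give bit-identical trajectories", {
  sc <- make_ring_scaffold(2, 4, 3, 2, seed = 2)
  sc <- apply_freeze(sc, define_freeze(sc, 3, include_hinge = FALSE))
  p <- sim_params(n_steps = 1000, seed = 42)
  s1 <- run_langevin(sc, p)
  s2 <- run_langevin(sc, p)
  expect_identical(s1$coords, s2$coords)
  s3 <- run_langevin(sc, sim_params(n_steps = 1000, seed = 43))
  expect_false(identical(s1$coords, s3$coords))
})

test_that("a free bead diffuses at the Langevin rate 6kT/(gamma m)", {
  atoms <- tibble::tibble(monomer = "A", resno = 1, resid = "ALA",
                          elety = "CA", element = "C", x = 0, y = 0, z = 0,
                          mobile = TRUE)
  sys <- molecular_system(atoms)
  p <- sim_params(kT = 1, gamma = 1, mass = 1, dt = 0.01, k_bond = 1,
                  n_steps = 2e6, seed = 8)
  seg <- run_langevin(sys, p, n_frames = 20001)  # one frame per time unit
  x <- matrix(seg$coords[, 1, ], ncol = 3)
  lags <- seq(10, 40, by = 5)
  msd <- vapply(lags, function(lag) {
    d <- x[(lag + 1):nrow(x), ] - x[seq_len(nrow(x) - lag), ]
    mean(rowSums(d^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(msd ~ lags))[["lags"]]
  expect_equal(slope, 6, tolerance = 0.1)  # 6 kT / (gamma m) per unit time
})

test_that("harmonic dimer samples the Boltzmann bond-length distribution", {
  atoms <- tibble::tibble(monomer = "A", resno = 1:2, resid = "ALA",
                          elety = "CA", element = "C",
                          x = c(0, 1), y = 0, z = 0,
                          mobile = c(FALSE, TRUE))
  sys <- molecular_system(atoms)
  k <- 25
  p <- sim_params(kT = 1, k_bond = k, r0 = 1, dt = 0.002, n_steps = 1e6,
                  seed = 21)
  seg <- run_langevin(sys, p, n_frames = 100001)
  r <- sqrt(rowSums(matrix(seg$coords[, 2, ], ncol = 3)^2))
  r <- r[-seq_len(10000)]  # burn-in
  grid <- seq(1e-4, 3, length.out = 4000)
  dens <- grid^2 * exp(-k * (grid - 1)^2 / 2)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  ks <- max(abs(stats::ecdf(r)(grid) - cdf))
  expect_lt(ks, 0.05)
  expect_equal(seg$kinetic_temperature, 1, tolerance = 0.05)
})

test_that("segment schedules account for the full production total", {
  man <- schedule_segments(5, 10, 19, 10)
  expect_equal(attr(man, "total_production_ns"), 190)
  expect_equal(sum(man$nominal_ns[man$role == "production"]), 190)
  expect_equal(nrow(man), 24)
  g <- glance(man)
  expect_equal(g$total_production_ns, 190)
  expect_equal(g$n_production, 19)

  expect_equal(attr(schedule_segments(0, 0, 1, 10), "total_production_ns"), 10)
  empty <- schedule_segments(5, 10, 0, 10)
  expect_equal(attr(empty, "total_production_ns"), 0)
  expect_equal(sum(empty$role == "production"), 0)
})

test_that("designed attraction sites are recovered from the terminal profile", {
  # spot checks at the canonical conditions; the full 10-seed-per-mode
  # discrimination suite lives with the acceptance tests
  for (seed in 1:2) {
    prof_open <- recovery_run("open", seed)
    prof_closed <- recovery_run("closed", seed)
    expect_equal(prof_open$resno[which.max(prof_open$score)], 1)
    expect_equal(prof_closed$resno[which.max(prof_closed$score)], 3)
  }
})
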