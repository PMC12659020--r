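th_default <- two_level_theory()

test_that("the ideal monomer sits at the intramolecular minimum", {
  res <- evaluate_potential(th_default, ideal_monomer(), "LL")
  expect_equal(res$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(res$forces)), 0, tolerance = 1e-10)
})

test_that("the O-O pair term follows shifted-force Lennard-Jones", {
  # two bare oxygens with charges off isolate the LJ term
  th <- two_level_theory(qO = 0, qH = 0)
  eps <- th$eps; sig <- th$sigma; rc <- th$r_lj
  u <- function(r) 4 * eps * ((sig / r)^12 - (sig / r)^6)
  du <- function(r) -24 * eps * (2 * (sig / r)^12 - (sig / r)^6) / r
  usf <- function(r) u(r) - u(rc) - (r - rc) * du(rc)
  pair_at <- function(r) {
    cfg <- atoms(c("O", "O"), rbind(c(0, 0, 0), c(r, 0, 0)))
    evaluate_potential(th, cfg, "LL")$energy
  }
  # at r = sigma the bare LJ crosses zero: only the truncation terms remain
  expect_equal(pair_at(sig), usf(sig), tolerance = 1e-12)
  expect_equal(usf(sig), -u(rc) - (sig - rc) * du(rc), tolerance = 1e-15)
  # at the minimum the bare well is -eps
  rmin <- 2^(1/6) * sig
  expect_equal(pair_at(rmin), -eps - u(rc) - (rmin - rc) * du(rc),
               tolerance = 1e-12)
})

test_that("analytic forces match central finite differences", {
  cl <- rand_cluster(12, seed = 4)
  for (lev in c("LL", "HL", "delta")) {
    res <- evaluate_potential(th_default, cl, lev)
    err <- fd_force_error(cl, function(c)
      evaluate_potential(th_default, c, lev)$energy, res$forces, h = 1e-4)
    expect_lt(err, 1e-6)
  }
})

test_that("virial trace matches the numerical volume derivative", {
  dim <- water_dimer(3.1, cell = 13.0)
  topo <- identify_molecules(dim)
  for (lev in c("LL", "HL")) {
    res <- evaluate_potential(th_default, dim, lev, topo)
    expect_lt(max(abs(res$virial - t(res$virial))), 1e-10)
    eps <- 1e-6
    scale_all <- function(s) {
      atoms(dim$elements, dim$positions * s, cell = dim$cell * s)
    }
    dEdlnV <- (evaluate_potential(th_default, scale_all(1 + eps), lev)$energy -
               evaluate_potential(th_default, scale_all(1 - eps), lev)$energy) /
              (6 * eps)
    expect_equal(sum(diag(res$virial)), -3 * dEdlnV, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the high-low difference is strictly short-ranged", {
  # dimer beyond 4 A: difference exactly zero
  far <- water_dimer(4.6)
  expect_identical(evaluate_potential(th_default, far, "delta")$energy, 0)
  # compact trimer: three-body term present
  tri <- rand_cluster(3, seed = 2, spread = 2.6)
  expect_gt(abs(evaluate_potential(th_default, tri, "delta")$energy), 1e-6)
  # adding a remote molecule leaves the difference unchanged
  cl <- rand_cluster(5, seed = 6, spread = 3)
  d0 <- evaluate_potential(th_default, cl, "delta")$energy
  extra <- ideal_monomer()$positions + rep(c(30, 0, 0), each = 3)
  cl2 <- atoms(c(cl$elements, "O", "H", "H"), rbind(cl$positions, extra))
  expect_equal(evaluate_potential(th_default, cl2, "delta")$energy, d0,
               tolerance = 1e-10)
})

test_that("energies are invariant under rigid motion and obey Newton's third law", {
  cl <- rand_cluster(8, seed = 11)
  e0 <- evaluate_potential(th_default, cl, "HL")$energy
  withr::with_seed(13, {
    for (k in 1:5) {
      R <- rand_rotation()
      t <- runif(3, -5, 5)
      moved <- atoms(cl$elements, t(R %*% t(cl$positions)) + rep(t, each = nrow(cl$positions)))
      expect_equal(evaluate_potential(th_default, moved, "HL")$energy, e0,
                   tolerance = 1e-9)
    }
  })
  res <- evaluate_potential(th_default, cl, "HL")
  expect_lt(max(abs(colSums(res$forces))), 1e-8)
})

test_that("energy is continuous where pairs cross the cutoffs", {
  for (rc in c(4.0, 6.0)) {
    ds <- seq(rc - 5e-4, rc + 5e-4, by = 1e-4)
    E <- vapply(ds, function(d)
      evaluate_potential(th_default, water_dimer(d), "HL")$energy, 0)
    jumps <- abs(diff(E))
    # a discontinuity would show as one step far larger than its neighbours
    expect_lt(max(jumps), 3 * median(jumps) + 1e-8)
  }
})

test_that("the two-level force gap is an order of magnitude", {
  cl <- rand_cluster(50, seed = 21, spread = 7.5)
  fl <- evaluate_potential(th_default, cl, "LL")$forces
  fd <- evaluate_potential(th_default, cl, "delta")$forces
  expect_lt(median(sqrt(rowSums(fd^2))), 0.1 * median(sqrt(rowSums(fl^2))))
})

test_that("composite with a zero model is exactly the baseline", {
  cl <- rand_cluster(6, seed = 8)
  z <- zero_delta_model()
  base <- evaluate_potential(th_default, cl, "LL")
  comp <- evaluate_composite(cl, z, th_default)
  expect_identical(comp$energy, base$energy)
  expect_identical(comp$forces, base$forces)
})

test_that("composite energy is additive in its parts", {
  m <- model55()
  f <- source126()$frames[[25]]
  comp <- evaluate_composite(f, m, th_default)
  base <- evaluate_potential(th_default, f, "LL")
  corr <- predict(m, f)
  expect_equal(comp$energy - base$energy, corr$energy, tolerance = 1e-10)
})

test_that("the shipped calibration record satisfies the density-gap contract", {
  th <- calibrate_two_level()
  cal <- attr(th, "calibration")
  expect_false(is.null(cal))
  gap <- abs(cal$rho_HL - cal$rho_LL) / cal$rho_LL
  expect_gte(gap, 0.03)
  expect_lte(gap, 0.10)
})
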