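# build a minimal trajectory object from raw positions (for synthetic cases)
synth_traj <- function(pos_list, L, dt_fs = 100, ensemble = "nvt",
                       elements = NULL, series = NULL, n_mol = NULL) {
  n <- nrow(pos_list[[1]])
  if (is.null(elements)) elements <- rep("O", n)
  frames <- lapply(pos_list, function(p) atoms(elements, p, cell = L))
  tr <- trajectory(frames, dt_fs = dt_fs, ensemble = ensemble,
                   series = series)
  tr$meta$n_mol <- if (is.null(n_mol)) n else n_mol
  tr
}

test_that("an ideal gas has unit pair correlation", {
  L <- 20
  withr::with_seed(31, {
    frames <- lapply(1:40, function(k) matrix(runif(3 * 200, 0, L), ncol = 3))
  })
  g <- rdf(synth_traj(frames, L), "OO", dr = 0.25)
  sel <- g$table$r > 2 # tiny-shell bins carry few counts
  expect_lt(max(abs(g$table$g[sel] - 1)), 0.12)
  expect_gt(min(g$table$g[sel]), 0.8)
})

test_that("a single fixed pair lands in its distance bin and integrates to one", {
  L <- 30
  pos <- rbind(c(5, 5, 5), c(10, 5, 5)) # r = 5.00
  g <- rdf(synth_traj(list(pos, pos), L), "OO", dr = 0.1)
  hit <- which(g$table$g > 0)
  expect_length(hit, 1)
  expect_equal(g$table$r[hit], 5.05, tolerance = 0.011)
  # shell-count integral with exact shell volumes: one neighbour each
  rho <- 2 / L^3
  r1 <- g$table$r + g$dr / 2; r0 <- g$table$r - g$dr / 2
  integral <- sum(rho * 4 * pi / 3 * (r1^3 - r0^3) * g$table$g)
  expect_equal(integral, 1, tolerance = 1e-9)
})

test_that("the coordination integral reproduces brute-force neighbour counts", {
  # rho int 4 pi r^2 g dr over [0, R] equals the mean number of neighbours
  # within R (here R = 6 A < L/2), cross-checking the normalisation
  tr <- source126()
  frames <- tr$frames[seq(51, 151, 20)]
  g <- rdf(trajectory(frames, ensemble = "nvt"), "OO", dr = 0.05, r_max = 6)
  rho <- g$mean_density_n
  integral <- sum(rho * 4 * pi * g$table$r^2 * g$table$g * g$dr)
  brute <- mean(unlist(lapply(frames, function(fr) {
    topo <- identify_molecules(fr)
    po <- fr$positions[topo$o_index, ]
    vapply(seq_len(126), function(cc) {
      d <- minimum_image(sweep(po, 2, po[cc, ]), fr$cell)
      sum(sqrt(rowSums(d^2)) <= 6) - 1
    }, 0)
  })))
  expect_equal(integral, brute, tolerance = 0.02)
})

test_that("rdf is invariant to frame order and rigid translation", {
  tr <- source126()
  fr <- tr$frames[seq(100, 148, 12)]
  g1 <- rdf(trajectory(fr, ensemble = "nvt"), "OH")
  g2 <- rdf(trajectory(rev(fr), ensemble = "nvt"), "OH")
  expect_equal(g1$table$g, g2$table$g, tolerance = 1e-12)
  shifted <- lapply(fr, function(f)
    atoms(f$elements, f$positions + rep(c(3.3, -1.1, 7.7), each = nrow(f$positions)),
          cell = f$cell))
  g3 <- rdf(trajectory(shifted, ensemble = "nvt"), "OH")
  expect_equal(g3$table$g, g1$table$g, tolerance = 1e-12)
})

test_that("r_max beyond the minimum image range is rejected", {
  tr <- source126()
  expect_error(rdf(trajectory(tr$frames[1:2], ensemble = "nvt"), "OO",
                   r_max = 9), "exceeds")
})

test_that("a planted Gaussian peak is recovered to high accuracy", {
  r <- seq(0.025, 8, by = 0.05)
  g <- 1 + 1.8 * exp(-(r - 2.83)^2 / (2 * 0.18^2))
  fake <- structure(list(table = data.frame(r = r, g = g), pair = "O-O",
                         dr = 0.05, n_frames = 1, mean_density_n = 0.033),
                    class = "rdf_result")
  p <- first_peak(fake)
  expect_equal(p$height, 2.8, tolerance = 0.001)
  expect_equal(p$position, 2.83, tolerance = 0.01 / 2.83)
  # peak exactly on a bin centre
  g2 <- 1 + exp(-(r - 2.825)^2 / (2 * 0.2^2))
  fake2 <- fake; fake2$table$g <- g2
  expect_equal(first_peak(fake2)$height, 2, tolerance = 1e-6)
  # flat g has no peak
  fake3 <- fake; fake3$table$g <- rep(1, length(r))
  expect_error(first_peak(fake3), "no peak")
})

test_that("frozen particles do not diffuse", {
  pos <- matrix(runif(30, 0, 10), ncol = 3)
  tr <- synth_traj(replicate(60, pos, simplify = FALSE), 10, dt_fs = 100)
  d <- self_diffusion(tr, window_ps = c(0.5, 4))
  expect_equal(d$D_pbc, 0, tolerance = 1e-14)
  expect_equal(d$D_corrected, d$D_pbc + yeh_hummer_correction(298, 10, 0.896),
               tolerance = 1e-12)
})

test_that("a planted random walk returns its diffusivity", {
  D_true <- 0.2 # A^2/ps
  dt_ps <- 0.05; n <- 400; nf <- 2000
  withr::with_seed(35, {
    steps <- array(rnorm(nf * n * 3, sd = sqrt(2 * D_true * dt_ps)),
                   dim = c(nf, n, 3))
  })
  pos <- vector("list", nf); cur <- matrix(50, n, 3)
  for (k in 1:nf) { cur <- cur + steps[k, , ]; pos[[k]] <- cur }
  tr <- synth_traj(pos, 100, dt_fs = dt_ps * 1000)
  d <- self_diffusion(tr, window_ps = c(1, 10), eta = 0.896, T = 298)
  expect_equal(d$D_pbc, D_true, tolerance = 0.05)
})

test_that("the finite-size correction follows the hydrodynamic formula", {
  corr <- yeh_hummer_correction(298, 15.577, 0.896)
  expect_equal(corr, 0.044, tolerance = 0.01)
  expect_equal(0.200 + corr, 0.244, tolerance = 0.01)
  # infinite box limit
  expect_lt(yeh_hummer_correction(298, 1e8, 0.896), 1e-8)
  expect_error(yeh_hummer_correction(298, 15.577, -1))
})

test_that("fit windows outside the trajectory are rejected", {
  pos <- replicate(20, matrix(runif(30, 0, 10), ncol = 3), simplify = FALSE)
  tr <- synth_traj(pos, 10, dt_fs = 100)
  expect_error(self_diffusion(tr, window_ps = c(2, 50)), "exceeds")
})

test_that("density averaging blocks an NPT volume series correctly", {
  mk_npt <- function(V) {
    tr <- synth_traj(list(matrix(runif(9, 0, 10), 3, 3)), 10,
                     ensemble = "npt", n_mol = 64)
    tr$series <- data.frame(V_A3 = V)
    tr$meta$n_mol <- 64
    tr
  }
  # constant volume: exact density, zero error
  V0 <- 64 * 18.015 / (6.02214076e23 * 1e-24) / 1.0 # rho = 1 exactly
  d <- density_mean(mk_npt(rep(V0, 1000)), n_blocks = 10, equil_fraction = 0.2)
  expect_equal(d$mean, 1.0, tolerance = 1e-12)
  expect_equal(d$se, 0, tolerance = 1e-15)
  # AR(1) volume series: the 10-block error estimate is an unbiased but
  # noisy estimator, so average it over independent series and compare to
  # the analytic standard error of an AR(1) mean
  phi <- 0.9; nser <- 50000
  ses <- withr::with_seed(37, vapply(1:8, function(rep) {
    eps <- rnorm(nser)
    v <- stats::filter(eps, phi, method = "recursive")
    density_mean(mk_npt(V0 * (1 + 0.001 * v)), n_blocks = 10,
                 equil_fraction = 0)$se
  }, 0))
  sd_inf <- 1 / sqrt(1 - phi^2) # stationary sd of the AR(1) innovations
  se_true <- 0.001 * sd_inf * sqrt((1 + phi) / (1 - phi)) / sqrt(nser)
  expect_equal(mean(ses), se_true, tolerance = 0.25)
  # NVE trajectories cannot be density-averaged
  nve <- synth_traj(list(matrix(runif(9, 0, 10), 3, 3)), 10, ensemble = "nve")
  expect_error(density_mean(nve), "NPT")
  expect_error(density_mean(mk_npt(rep(V0, 5)), n_blocks = 10), "blocks")
})

test_that("isobar apex detection flags monotone tables and finds maxima", {
  expect_error(isobar_apex(280, 1.0), "at least 2")
  expect_error(density_isobar(NULL, temperatures = 298), "at least 2")
  mono <- isobar_apex(c(250, 270, 290, 310), c(1.00, 0.99, 0.97, 0.94))
  expect_false(mono$has_maximum)
  Tg <- seq(250, 330, by = 10)
  rho <- 1 - 5e-6 * (Tg - 277)^2
  apex <- isobar_apex(Tg, rho)
  expect_true(apex$has_maximum)
  expect_equal(apex$T_max, 277, tolerance = 10 / 277)
  expect_equal(apex$rho_max, 1.0, tolerance = 1e-3)
})
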