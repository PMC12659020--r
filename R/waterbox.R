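# local RNG scope: run code with a private seed, restoring the global state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# uniform random rotation matrix (quaternion method)
.rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Build a periodic water box
#'
#' Places `n_molecules` rigid water geometries (O-H 0.9572 A, H-O-H 104.52
#' degrees) on a jittered cubic lattice with random orientations, in a cubic
#' cell sized from the target mass density.  The result is an unequilibrated
#' but overlap-free starting structure for molecular dynamics; a short NVT
#' run equilibrates it.
#'
#' @param n_molecules number of water molecules
#' @param density target mass density, g/cm^3 (default: experimental 0.997)
#' @param seed integer seed controlling placement and orientations
#' @param jitter lattice jitter amplitude, fraction of the lattice spacing
#' @return a periodic [atoms()] configuration with 3 x `n_molecules` atoms
#'   ordered O, H, H per molecule
#' @export
water_box <- function(n_molecules, density = 0.997, seed = 1, jitter = 0.05) {
  stopifnot(n_molecules >= 1, density > 0)
  L <- box_edge_from_density(n_molecules, density)
  k <- ceiling(n_molecules^(1 / 3))
  a <- L / k
  r0 <- 0.9572; half <- 104.52 / 2 * pi / 180
  h1 <- r0 * c(sin(half), 0, cos(half))
  h2 <- r0 * c(-sin(half), 0, cos(half))
  .with_seed(seed, {
    grid <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1)))
    sites <- grid[sample.int(nrow(grid), n_molecules), , drop = FALSE]
    centres <- (sites + 0.5) * a +
      matrix(runif(3 * n_molecules, -jitter * a, jitter * a), ncol = 3)
    pos <- matrix(0, 3 * n_molecules, 3)
    for (m in seq_len(n_molecules)) {
      R <- .rand_rotation()
      o <- centres[m, ]
      pos[3 * m - 2, ] <- o
      pos[3 * m - 1, ] <- o + as.vector(R %*% h1)
      pos[3 * m, ]     <- o + as.vector(R %*% h2)
    }
    atoms(rep(c("O", "H", "H"), n_molecules), pos, cell = L,
          info = list(generator = "water_box", seed = seed,
                      target_density = density))
  })
}

# deterministic sub-seed derivation (kept below 2^31)
.derive_seed <- function(master, stage, k = 0L) {
  as.integer((as.double(master) * 100003 + stage * 10007 + k * 101 + 17) %%
               2147483647)
}

#' Relax a structure by damped steepest descent
#'
#' Removes close contacts from generated structures before dynamics: moves
#' atoms along the forces with a per-atom displacement cap and an adaptive
#' step that backtracks when the energy rises.  Not a production minimiser -
#' just enough to hand [run_md()] a clash-free starting point.
#'
#' @param cfg an [atoms()] configuration
#' @param theory a [two_level_theory()]
#' @param level potential level to relax on
#' @param steps maximum iterations
#' @param fmax stop when max |F| falls below this, eV/A
#' @param max_disp per-atom displacement cap per iteration, A
#' @return the relaxed [atoms()] configuration
#' @export
relax_structure <- function(cfg, theory = two_level_theory(), level = "LL",
                            steps = 200, fmax = 0.5, max_disp = 0.1) {
  topo <- identify_molecules(cfg)
  cur <- cfg
  alpha <- 0.01
  res <- evaluate_potential(theory, cur, level, topo)
  for (s in seq_len(steps)) {
    fm <- max(sqrt(rowSums(res$forces^2)))
    if (fm < fmax) break
    disp <- alpha * res$forces
    dn <- sqrt(rowSums(disp^2))
    over <- dn > max_disp
    if (any(over)) disp[over, ] <- disp[over, ] * (max_disp / dn[over])
    trial <- cur
    trial$positions <- cur$positions + disp
    tres <- evaluate_potential(theory, trial, level, topo)
    if (tres$energy < res$energy) {
      cur <- trial; res <- tres; alpha <- min(alpha * 1.25, 0.2)
    } else {
      alpha <- alpha * 0.4
      if (alpha < 1e-6) break
    }
  }
  cur$info$relaxed <- TRUE
  cur
}

#' Generate an equilibrated water box with the baseline potential
#'
#' Convenience wrapper: [water_box()] + [relax_structure()] + a short NVT
#' equilibration at the target temperature, returning the final
#' configuration (and velocities) ready for production runs.
#'
#' @param n_molecules,density,seed passed to [water_box()]
#' @param theory a [two_level_theory()]
#' @param T temperature, K
#' @param equil_steps NVT equilibration steps at `dt_fs`
#' @param dt_fs timestep, fs
#' @param potential level used for equilibration
#' @return list with `configuration` (final [atoms()]), `velocities`
#'   (A/fs) and the equilibration trajectory
#' @export
equilibrated_water_box <- function(n_molecules, density = 0.997, seed = 1,
                                   theory = two_level_theory(), T = 298,
                                   equil_steps = 10000, dt_fs = 0.5,
                                   potential = "LL") {
  wb <- relax_structure(water_box(n_molecules, density, seed), theory,
                        if (potential == "composite") "LL" else potential)
  tr <- run_md(wb, potential, theory, ensemble = "nvt", steps = equil_steps,
               dt_fs = dt_fs, stride = max(1L, equil_steps %/% 20),
               T = T, seed = .derive_seed(seed, 5L))
  list(configuration = final_frame(tr), velocities = final_velocities(tr),
       equilibration = tr)
}
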