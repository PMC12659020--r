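# Shared fixtures, built in code.  Expensive objects (equilibrated boxes,
# source trajectories, labelled datasets, trained models) are cached per
# session so test files can reuse them without re-running MD or carving.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# ideal gas-phase water monomer at the potential minimum
ideal_monomer <- function() {
  r0 <- 0.9572; half <- 104.52 / 2 * pi / 180
  atoms(c("O", "H", "H"),
        rbind(c(0, 0, 0),
              r0 * c(sin(half), 0, cos(half)),
              r0 * c(-sin(half), 0, cos(half))))
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# random open-boundary water cluster with O-O separation >= 2.4 A
rand_cluster <- function(n_mol, seed = 1, spread = 4.5) {
  mono <- ideal_monomer()$positions
  withr::with_seed(seed, {
    pos <- matrix(0, 3 * n_mol, 3)
    os <- matrix(0, 0, 3)
    for (m in seq_len(n_mol)) {
      repeat {
        o <- runif(3, -spread, spread)
        if (m == 1 ||
            min(sqrt(rowSums(sweep(os, 2, o)^2))) > 2.4) break
      }
      os <- rbind(os, o)
      R <- rand_rotation()
      blk <- t(R %*% t(mono)) + rep(o, each = 3)
      pos[(3 * m - 2):(3 * m), ] <- blk
    }
    atoms(rep(c("O", "H", "H"), n_mol), pos)
  })
}

# a water dimer with given O-O distance, oxygens along x
water_dimer <- function(d_oo, cell = NULL) {
  m <- ideal_monomer()
  pos <- rbind(m$positions, sweep(m$positions, 2, c(d_oo, 0, 0), "+"))
  if (!is.null(cell))
    pos <- sweep(pos, 2, c(cell / 2 - d_oo / 2, cell / 2, cell / 2), "+")
  atoms(rep(c("O", "H", "H"), 2), pos, cell = cell)
}

# central-difference force check over a sample of atoms
fd_force_error <- function(cfg, energy_fn, forces, h = 1e-5, n_atoms = 5,
                           seed = 7) {
  idx <- withr::with_seed(seed,
           sample(seq_along(cfg$elements), min(n_atoms, length(cfg$elements))))
  maxerr <- 0
  for (i in idx) for (k in 1:3) {
    p1 <- cfg; p1$positions[i, k] <- p1$positions[i, k] + h
    p2 <- cfg; p2$positions[i, k] <- p2$positions[i, k] - h
    fd <- -(energy_fn(p1) - energy_fn(p2)) / (2 * h)
    maxerr <- max(maxerr, abs(fd - forces[i, k]))
  }
  maxerr
}

# equilibrated 72-water box at the experimental density (cached)
box72 <- function() fixture("box72", function() {
  equilibrated_water_box(72, seed = 3, equil_steps = 8000)
})

# short 72-water LL source (for protocol tests at small scale)
source72 <- function() fixture("source72", function() {
  eq <- box72()
  run_md(eq$configuration, "LL", ensemble = "nvt", steps = 8000,
         stride = 100, seed = 41, velocities = eq$velocities)
})

# equilibrated 126-water box (cached)
eq126 <- function() fixture("eq126", function() {
  equilibrated_water_box(126, seed = 23, equil_steps = 16000)
})

# 126-water baseline source at the experimental density (cached; the
# workhorse for carving, occupancy and recovery experiments)
source126 <- function() fixture("source126", function() {
  eq <- eq126()
  run_md(eq$configuration, "LL", ensemble = "nvt", steps = 30000,
         stride = 200, seed = 71, velocities = eq$velocities)
})

# 126-water high-level source (training-set enrichment: clusters are carved
# from snapshots of both levels so the correction also sees the
# more-structured configurations the target ensemble visits)
sourceHL126 <- function() fixture("sourceHL126", function() {
  eq <- eq126()
  run_md(eq$configuration, "HL", ensemble = "nvt", steps = 24000,
         stride = 200, seed = 72, velocities = eq$velocities)
})

# labelled cumulative dataset {2.5, 3.5, 4.5, 5.5} carved from the mixed
# baseline + high-level source
dataset55 <- function() fixture("dataset55", function() {
  hl <- sourceHL126()
  mixed <- trajectory(c(source126()$frames, hl$frames[-(1:21)]),
                      ensemble = "nvt")
  label_delta(build_cluster_dataset(
    mixed, carve_spec(radii = c(2.5, 3.5, 4.5, 5.5),
                      counts = c(600, 600, 300, 100), seed = 11)),
    two_level_theory())
})

# delta models trained on cumulative subsets of dataset55
model25 <- function() fixture("model25", function()
  delta_fit(subset_dataset(dataset55(), 2.5)))
model35 <- function() fixture("model35", function()
  delta_fit(subset_dataset(dataset55(), 3.5)))
model55 <- function() fixture("model55", function()
  delta_fit(dataset55()))
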