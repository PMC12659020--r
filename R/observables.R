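.pair_species <- function(pair) {
  pair <- toupper(gsub("[^A-Za-z]", "", pair))
  if (!pair %in% c("OO", "OH", "HH", "HO"))
    stop("pair must be one of 'OO', 'OH', 'HH'")
  if (pair == "HO") pair <- "OH"
  c(substr(pair, 1, 1), substr(pair, 2, 2))
}

#' Radial distribution function
#'
#' Standard shell-count histogram of a periodic trajectory, normalised by
#' the ideal-gas expectation with each frame's own density (so NPT
#' trajectories are handled correctly).
#'
#' @param traj an `md_trajectory` with periodic frames
#' @param pair `"OO"`, `"OH"` or `"HH"`
#' @param dr bin width, A (default 0.05)
#' @param r_max histogram range, A; must not exceed L/2 (default: smallest
#'   L/2 over frames)
#' @param equil_fraction fraction of initial frames discarded
#' @return an object of class `rdf_result`: data.frame columns `r`
#'   (bin centres) and `g`, plus pair label, bin width and frame count
#' @export
rdf <- function(traj, pair = "OO", dr = 0.05, r_max = NULL,
                equil_fraction = 0) {
  frames <- traj$frames
  frames <- frames[seq.int(floor(equil_fraction * length(frames)) + 1,
                           length(frames))]
  Ls <- vapply(frames, cell_edge, 0)
  if (is.null(r_max)) r_max <- min(Ls) / 2
  if (r_max > min(Ls) / 2 + 1e-9)
    stop(sprintf("r_max %.2f exceeds L/2 = %.2f", r_max, min(Ls) / 2))
  sp <- .pair_species(pair)
  same <- sp[1] == sp[2]
  el <- frames[[1]]$elements
  ia <- which(el == sp[1]); ib <- which(el == sp[2])
  if (!length(ia) || !length(ib)) stop("no atoms of requested species")
  pos_a <- lapply(frames, function(f) f$positions[ia, , drop = FALSE])
  pos_b <- if (same) pos_a else
    lapply(frames, function(f) f$positions[ib, , drop = FALSE])
  nbins <- floor(r_max / dr)
  g <- rdf_accum_cpp(pos_a, pos_b, Ls, same, dr, nbins)
  structure(list(table = data.frame(r = (seq_len(nbins) - 0.5) * dr, g = g),
                 pair = paste(sp, collapse = "-"), dr = dr,
                 n_frames = length(frames),
                 mean_density_n = length(ia) / mean(Ls^3)),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("<rdf_result: %s, %d bins of %.3f A, %d frames>\n",
              x$pair, nrow(x$table), x$dr, x$n_frames))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$table$r, x$table$g, type = "l",
                 xlab = "r (A)", ylab = "g(r)", main = x$pair, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' First peak of a radial distribution function
#'
#' Locates the first local maximum with g > 1 and refines height and
#' position by a quadratic through the maximal bin and its neighbours:
#' three-point interpolation by default, or a least-squares parabola over
#' `2 * half_window + 1` bins for a lower-noise estimate when comparing
#' peaks between trajectories.
#'
#' @param x an [rdf()] result
#' @param half_window bins on each side of the maximum used in the fit
#' @return list with `height` and `position` (A)
#' @export
first_peak <- function(x, half_window = 1) {
  g <- x$table$g; r <- x$table$r
  n <- length(g)
  i <- NA_integer_
  for (k in 2:(n - 1)) {
    if (g[k] > 1 && g[k] >= g[k - 1] && g[k] >= g[k + 1]) { i <- k; break }
  }
  if (is.na(i)) stop("no peak: g(r) has no local maximum above 1")
  if (half_window == 1) {
    y0 <- g[i - 1]; y1 <- g[i]; y2 <- g[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (abs(denom) < 1e-14) return(list(height = y1, position = r[i]))
    d <- 0.5 * (y0 - y2) / denom
    return(list(height = y1 - 0.25 * (y0 - y2) * d,
                position = r[i] + d * x$dr))
  }
  idx <- max(1, i - half_window):min(n, i + half_window)
  u <- r[idx] - r[i]
  fit <- lm(g[idx] ~ u + I(u^2))
  cc <- coef(fit)
  if (!is.finite(cc[3]) || cc[3] >= 0)
    return(list(height = g[i], position = r[i]))
  umax <- -cc[2] / (2 * cc[3])
  list(height = unname(cc[1] + cc[2] * umax + cc[3] * umax^2),
       position = unname(r[i] + umax))
}

#' Yeh-Hummer finite-size correction for self-diffusion
#'
#' The hydrodynamic correction for diffusion in a cubic periodic box:
#' \eqn{D_\infty = D_{PBC} + \xi k_B T / (6\pi\eta L)} with
#' \eqn{\xi = 2.837297}.
#'
#' @param T temperature, K
#' @param L cubic box edge, A
#' @param eta shear viscosity, mPa s
#' @return the correction in A^2/ps
#' @export
yeh_hummer_correction <- function(T, L, eta) {
  if (eta <= 0 || L <= 0) stop("eta and L must be positive")
  xi <- 2.837297
  kB_J <- 1.380649e-23
  # SI: m^2/s, then to A^2/ps (1 m^2/s = 1e8 A^2/ps)
  xi * kB_J * T / (6 * pi * eta * 1e-3 * L * 1e-10) * 1e8
}

#' Self-diffusion coefficient from mean squared displacement
#'
#' Computes the molecular (oxygen-site) MSD over multiple time origins,
#' fits its slope by least squares over the stated time window, and reports
#' \eqn{D_{PBC} = slope/6} together with the Yeh-Hummer finite-size
#' corrected value.  Requires unwrapped coordinates, which [run_md()]
#' frames carry.
#'
#' @param traj an `md_trajectory` (typically NVT)
#' @param window_ps fit window (start, end), ps
#' @param eta viscosity used in the finite-size correction, mPa s
#'   (default 0.896, water at 298 K)
#' @param T temperature, K
#' @param equil_fraction initial fraction of frames discarded
#' @return an object of class `diffusion_result`: `D_pbc`, `D_corrected`
#'   (A^2/ps), fit window, slope standard error, box edge, viscosity, and
#'   the MSD table
#' @export
self_diffusion <- function(traj, window_ps = c(2, 10), eta = 0.896,
                           T = 298, equil_fraction = 0) {
  if (is.na(traj$dt_fs)) stop("trajectory has no frame spacing")
  frames <- traj$frames
  frames <- frames[seq.int(floor(equil_fraction * length(frames)) + 1,
                           length(frames))]
  nf <- length(frames)
  dt_ps <- traj$dt_fs / 1000
  max_lag <- floor(window_ps[2] / dt_ps)
  if (max_lag >= nf)
    stop(sprintf("fit window %.1f ps exceeds trajectory span %.1f ps",
                 window_ps[2], (nf - 1) * dt_ps))
  el <- frames[[1]]$elements
  io <- which(el == "O")
  pos <- lapply(frames, function(f) f$positions[io, , drop = FALSE])
  lags <- unique(pmax(1L, round(seq(1, max_lag, length.out = min(max_lag, 200)))))
  origin_stride <- max(1L, floor(max_lag / 2)) # 50% overlap of the longest lag
  msd <- msd_cpp(pos, as.integer(lags), origin_stride)
  t_ps <- lags * dt_ps
  sel <- t_ps >= window_ps[1] & t_ps <= window_ps[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 MSD points")
  fit <- lm(msd[sel] ~ t_ps[sel])
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  L <- mean(vapply(frames, cell_edge, 0))
  D <- slope / 6
  structure(list(D_pbc = unname(D),
                 D_corrected = unname(D + yeh_hummer_correction(T, L, eta)),
                 window_ps = window_ps, slope_se = unname(se / 6), L = L,
                 eta = eta, T = T,
                 msd = data.frame(t_ps = t_ps, msd = msd)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion: D_pbc = %.4f, D_corrected = %.4f A^2/ps (L = %.2f A, eta = %.3f mPa s)>\n",
              x$D_pbc, x$D_corrected, x$L, x$eta))
  invisible(x)
}

#' Mean density with block-averaged error
#'
#' Mass density of an NPT trajectory from its per-step volume series: the
#' post-equilibration mean and a standard error from non-overlapping block
#' means.
#'
#' @param traj an NPT `md_trajectory` from [run_md()]
#' @param n_blocks number of blocks (default 10)
#' @param equil_fraction initial fraction discarded (default 0.2)
#' @return an object of class `density_result`: `mean` (g/cm^3), `se`,
#'   `n_blocks`, `equil_fraction`
#' @export
density_mean <- function(traj, n_blocks = 10, equil_fraction = 0.2) {
  if (!identical(traj$ensemble, "npt"))
    stop("density_mean requires an NPT trajectory (no cell fluctuations to average otherwise)")
  V <- traj$series$V_A3
  n_mol <- traj$meta$n_mol
  rho <- n_mol * .water_molar_mass / (.avogadro * V * 1e-24)
  rho <- rho[seq.int(floor(equil_fraction * length(rho)) + 1, length(rho))]
  if (length(rho) < n_blocks) stop("fewer samples than blocks")
  bs <- floor(length(rho) / n_blocks)
  blocks <- vapply(seq_len(n_blocks), function(b)
    mean(rho[((b - 1) * bs + 1):(b * bs)]), 0)
  structure(list(mean = mean(rho), se = sd(blocks) / sqrt(n_blocks),
                 n_blocks = n_blocks, equil_fraction = equil_fraction,
                 n_samples = length(rho)),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density: %.4f (%.4f) g/cm^3, %d blocks>\n",
              x$mean, x$se, x$n_blocks))
  invisible(x)
}

#' Locate the density maximum of an isobar table
#'
#' Quadratic fit through the top three points when an interior maximum
#' exists; otherwise flags no maximum.
#'
#' @param T temperatures, K (length >= 2)
#' @param rho densities, g/cm^3
#' @return list with `has_maximum`, and `T_max`, `rho_max` when present
#' @export
isobar_apex <- function(T, rho) {
  if (length(T) < 2) stop("an isobar needs at least 2 temperatures")
  o <- order(T); T <- T[o]; rho <- rho[o]
  i <- which.max(rho)
  if (i == 1 || i == length(T)) return(list(has_maximum = FALSE))
  fit <- lm(rho[(i - 1):(i + 1)] ~ poly(T[(i - 1):(i + 1)], 2, raw = TRUE))
  cc <- coef(fit)
  T_max <- -cc[2] / (2 * cc[3])
  list(has_maximum = TRUE, T_max = unname(T_max),
       rho_max = unname(cc[1] + cc[2] * T_max + cc[3] * T_max^2))
}

#' Density isobar by NPT simulation
#'
#' Runs independent NPT simulations per (temperature, replica), returns the
#' isobar with replica standard errors, and locates an interior density
#' maximum when one exists.
#'
#' @param initial periodic starting [atoms()] configuration
#' @param temperatures temperatures, K (length >= 2)
#' @param P pressure, bar
#' @param replicas independent replicas per temperature
#' @param potential,theory,model passed to [run_md()]
#' @param steps,dt_fs,stride,equil_fraction,n_blocks run/analysis settings
#' @param seed master seed; per-run seeds are derived deterministically
#' @return list with `table` (T, rho, err) and `apex` (see [isobar_apex()])
#' @export
density_isobar <- function(initial, temperatures, P = 1, replicas = 3,
                           potential = "LL", theory = two_level_theory(),
                           model = NULL, steps = 20000, dt_fs = 0.5,
                           stride = 50, equil_fraction = 0.3, n_blocks = 10,
                           seed = 1) {
  if (length(temperatures) < 2) stop("an isobar needs at least 2 temperatures")
  rows <- lapply(seq_along(temperatures), function(i) {
    vals <- vapply(seq_len(replicas), function(k) {
      tr <- run_md(initial, potential, theory, model, ensemble = "npt",
                   steps = steps, dt_fs = dt_fs, stride = stride,
                   T = temperatures[i], P_bar = P,
                   seed = .derive_seed(seed, i, k))
      density_mean(tr, n_blocks = n_blocks,
                   equil_fraction = equil_fraction)$mean
    }, 0)
    data.frame(T = temperatures[i], rho = mean(vals),
               err = sd(vals) / sqrt(replicas))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, apex = isobar_apex(tab$T, tab$rho))
}
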