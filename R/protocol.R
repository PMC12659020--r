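#' Convergence thresholds for the radius protocol
#'
#' Relative tolerance on density (default 0.001, i.e. 0.1%), relative
#' tolerance on the diffusion coefficient (default 0.045) and absolute
#' tolerance on the O-O first-peak height (default 0.01).
#'
#' @param density relative density tolerance
#' @param diffusion relative diffusion tolerance
#' @param peak absolute g(r) peak tolerance
#' @return an object of class `convergence_thresholds`
#' @export
convergence_thresholds <- function(density = 0.001, diffusion = 0.045,
                                   peak = 0.01) {
  stopifnot(density > 0, diffusion > 0, peak > 0)
  structure(list(density = density, diffusion = diffusion, peak = peak),
            class = "convergence_thresholds")
}

# run one (potential, seed) NPT + NVT pair and measure (rho, peak, D)
.measure_observables <- function(initial, potential, theory, model, cfg, seed) {
  npt <- run_md(initial, potential, theory, model, ensemble = "npt",
                steps = cfg$npt_steps, dt_fs = cfg$dt_fs, stride = cfg$stride,
                T = cfg$T, P_bar = cfg$P, seed = .derive_seed(seed, 11L))
  rho <- density_mean(npt, n_blocks = cfg$n_blocks,
                      equil_fraction = cfg$equil_fraction)$mean
  # structure/dynamics at the fixed reference density, as in convergence tests
  nvt <- run_md(initial, potential, theory, model, ensemble = "nvt",
                steps = cfg$nvt_steps, dt_fs = cfg$dt_fs, stride = cfg$stride,
                T = cfg$T, seed = .derive_seed(seed, 13L))
  pk <- first_peak(rdf(nvt, "OO", dr = cfg$rdf_dr,
                       equil_fraction = cfg$equil_fraction))$height
  D <- self_diffusion(nvt, window_ps = cfg$msd_window_ps, eta = cfg$eta,
                      T = cfg$T,
                      equil_fraction = cfg$equil_fraction)$D_corrected
  c(rho = rho, peak = pk, D = D)
}

.replica_stats <- function(mat) {
  # mat: replicas x 3 (rho, peak, D)
  m <- colMeans(mat)
  se <- apply(mat, 2, sd) / sqrt(nrow(mat))
  c(rho = m[["rho"]], rho_se = se[["rho"]], peak = m[["peak"]],
    peak_se = se[["peak"]], D = m[["D"]], D_se = se[["D"]])
}

#' Self-consistent radius-convergence protocol
#'
#' The central workflow: for each cumulative radius set (all radii up to
#' r_c), carve and label a dataset from baseline-sampled frames, train the
#' delta model, run composite NPT and NVT simulations with independent
#' replicas, and measure density, O-O first-peak height and corrected
#' diffusion.  A direct high-level simulation provides the reference row -
#' available here because the synthetic high level is cheap to simulate,
#' whereas in practice the largest radius serves as its own reference.
#' Convergence verdicts use successive-radius differences: radius r_i is
#' converged for an observable when the step to r_{i+1} changes it by less
#' than the threshold.
#'
#' @param source an `md_trajectory` of baseline (LL) frames to carve from
#' @param spec a [carve_spec()] with the full radius/count schedule
#' @param theory a [two_level_theory()]
#' @param descriptor a [descriptor_spec()]
#' @param lambda ridge strength for [delta_fit()]
#' @param thresholds a [convergence_thresholds()]
#' @param replicas independent replicas per radius (errors are replica
#'   standard errors)
#' @param seed master seed; every stage seed derives from it
#' @param T,P thermodynamic conditions (K, bar)
#' @param npt_steps,nvt_steps,dt_fs,stride MD settings per run
#' @param equil_fraction,n_blocks,rdf_dr,msd_window_ps,eta analysis settings
#' @return an object of class `convergence_table`: `table` (one row per
#'   cumulative radius plus the reference row, with replica errors),
#'   `verdicts` (per-observable logical matrix of successive-difference
#'   convergence), `deltas_vs_reference`, `thresholds`, `models` (training
#'   reports per radius)
#' @export
converge_radius <- function(source, spec, theory,
                            descriptor = descriptor_spec(), lambda = 1e-6,
                            thresholds = convergence_thresholds(),
                            replicas = 3, seed = 1, T = 298, P = 1,
                            npt_steps = 20000, nvt_steps = 20000,
                            dt_fs = 0.5, stride = 40,
                            equil_fraction = 0.3, n_blocks = 10,
                            rdf_dr = 0.05, msd_window_ps = c(1, 4),
                            eta = 0.896) {
  stopifnot(inherits(spec, "carve_spec"))
  cfg <- list(T = T, P = P, npt_steps = npt_steps, nvt_steps = nvt_steps,
              dt_fs = dt_fs, stride = stride, equil_fraction = equil_fraction,
              n_blocks = n_blocks, rdf_dr = rdf_dr,
              msd_window_ps = msd_window_ps, eta = eta)
  initial <- source$frames[[length(source$frames)]]
  full <- label_delta(build_cluster_dataset(source, spec), theory)
  rows <- list(); reports <- list()
  for (i in seq_along(spec$radii)) {
    ds <- subset_dataset(full, spec$radii[i])
    model <- delta_fit(ds, descriptor, lambda = lambda,
                       seed = .derive_seed(seed, 3L, i))
    reports[[i]] <- model$report
    mat <- t(vapply(seq_len(replicas), function(k)
      .measure_observables(initial, "composite", theory, model, cfg,
                           .derive_seed(seed, 100L + i, k)),
      c(rho = 0, peak = 0, D = 0)))
    rows[[i]] <- c(r_max = spec$radii[i], .replica_stats(mat))
  }
  ref_mat <- t(vapply(seq_len(replicas), function(k)
    .measure_observables(initial, "HL", theory, NULL, cfg,
                         .derive_seed(seed, 999L, k)),
    c(rho = 0, peak = 0, D = 0)))
  ref <- c(r_max = NA_real_, .replica_stats(ref_mat))
  tab <- as.data.frame(do.call(rbind, c(rows, list(ref))))
  tab$row <- c(sprintf("composite<=%.1fA", spec$radii), "HL reference")
  nr <- length(spec$radii)
  verdict <- matrix(NA, nrow = nr, ncol = 3,
                    dimnames = list(sprintf("%.1f", spec$radii),
                                    c("density", "diffusion", "peak")))
  for (i in seq_len(nr - 1)) {
    verdict[i, "density"] <-
      abs(tab$rho[i + 1] - tab$rho[i]) / abs(tab$rho[i]) <= thresholds$density
    verdict[i, "diffusion"] <-
      abs(tab$D[i + 1] - tab$D[i]) / abs(tab$D[i]) <= thresholds$diffusion
    verdict[i, "peak"] <- abs(tab$peak[i + 1] - tab$peak[i]) <= thresholds$peak
  }
  ref_row <- nrow(tab)
  deltas <- data.frame(
    r_max = spec$radii,
    d_rho_rel = abs(tab$rho[seq_len(nr)] - tab$rho[ref_row]) / tab$rho[ref_row],
    d_peak_abs = abs(tab$peak[seq_len(nr)] - tab$peak[ref_row]),
    d_D_rel = abs(tab$D[seq_len(nr)] - tab$D[ref_row]) / abs(tab$D[ref_row]))
  structure(list(table = tab, verdicts = verdict,
                 deltas_vs_reference = deltas, thresholds = thresholds,
                 models = reports, replicas = replicas, seed = seed,
                 settings = cfg),
            class = "convergence_table")
}

#' @export
print.convergence_table <- function(x, ...) {
  cat("Radius-convergence table (replica means and standard errors)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nSuccessive-difference verdicts (TRUE = converged at this radius):\n")
  print(x$verdicts)
  cat("\nDeviations from the direct high-level reference:\n")
  print(x$deltas_vs_reference, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Force-scale diagnostic
#'
#' Compares per-atom force magnitudes of the baseline (LL), target (HL) and
#' trained delta model on periodic frames.  A well-posed delta correction
#' produces forces far smaller than the baseline - the signature that the
#' correction is a small, short-ranged perturbation.
#'
#' @param frames an `md_trajectory` or list of periodic [atoms()] frames
#' @param theory a [two_level_theory()]
#' @param model a fitted [delta_fit()] model
#' @return an object of class `force_scale_report`: per-model median and
#'   quantiles of |F|, and the delta/LL median ratio
#' @export
force_scale_report <- function(frames, theory, model) {
  if (inherits(frames, "md_trajectory")) frames <- frames$frames
  mags <- list(LL = numeric(0), HL = numeric(0), delta = numeric(0))
  for (f in frames) {
    topo <- identify_molecules(f)
    for (lev in c("LL", "HL"))
      mags[[lev]] <- c(mags[[lev]],
                       sqrt(rowSums(evaluate_potential(theory, f, lev,
                                                       topo)$forces^2)))
    mags$delta <- c(mags$delta, sqrt(rowSums(predict(model, f)$forces^2)))
  }
  qs <- t(vapply(mags, quantile, numeric(5),
                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  structure(list(quantiles = qs,
                 medians = vapply(mags, median, 0),
                 ratio_delta_ll = median(mags$delta) / median(mags$LL),
                 n_frames = length(frames)),
            class = "force_scale_report")
}

#' @export
print.force_scale_report <- function(x, ...) {
  cat(sprintf("Force-scale diagnostic over %d frames (|F|, eV/A):\n", x$n_frames))
  print(round(x$quantiles, 5))
  cat(sprintf("median|F_delta| / median|F_LL| = %.4f\n", x$ratio_delta_ll))
  invisible(x)
}

#' Two-point complete-basis-set extrapolation
#'
#' The standard inverse-power two-point formula
#' \eqn{E_{CBS} = (Y^\beta E_Y - X^\beta E_X) / (Y^\beta - X^\beta)}
#' for energies computed with basis sets of cardinal numbers X < Y
#' (e.g. TZ/QZ = 3/4), with exponent `beta` (default 3).  The result is
#' unit-agnostic and linear in both inputs; if the energies follow
#' \eqn{E_X = E_\infty + A X^{-\beta}} exactly, the extrapolation recovers
#' \eqn{E_\infty} exactly.
#'
#' @param e_x,e_y energies at the smaller and larger basis
#' @param x,y cardinal numbers, `x < y`
#' @param beta extrapolation exponent (> 0)
#' @return the extrapolated energy
#' @export
cbs_extrapolate <- function(e_x, e_y, x = 3, y = 4, beta = 3) {
  if (x == y) stop("cardinal numbers must differ (x < y)")
  if (x > y) stop("x must be smaller than y")
  if (beta <= 0) stop("beta must be positive")
  (y^beta * e_y - x^beta * e_x) / (y^beta - x^beta)
}
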