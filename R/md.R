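#' Run molecular dynamics
#'
#' Velocity-Verlet dynamics with optional canonical sampling through
#' velocity rescaling (CSVR) thermostat and isotropic stochastic
#' cell-rescaling barostat (molecular-centre scaling), for any of the
#' package's potentials: the LL baseline, the HL target, the composite
#' LL + delta model, or no interactions at all (`"none"`, an ideal gas).
#' One new force evaluation is performed per step; a Verlet neighbour list
#' with 0.5 A skin is rebuilt on a displacement trigger.  All randomness
#' (initial Maxwell-Boltzmann velocities, thermostat and barostat noise)
#' derives from `seed`; reruns are bitwise identical.
#'
#' Defaults follow common condensed-phase practice for flexible water:
#' 0.5 fs timestep, 298 K with a 0.1 ps thermostat relaxation time, 1 bar
#' with a 1 ps barostat relaxation time.  Centre-of-mass momentum is removed
#' at initialisation and preserved by the integrator and thermostat.
#'
#' @param initial periodic [atoms()] starting configuration
#' @param potential one of `"LL"`, `"HL"`, `"composite"`, `"none"`
#' @param theory a [two_level_theory()]
#' @param model a fitted [delta_fit()] model (required for `"composite"`)
#' @param ensemble `"nve"`, `"nvt"` or `"npt"`
#' @param steps number of MD steps (0 returns just the initial frame)
#' @param dt_fs timestep, fs
#' @param stride store a frame every `stride` steps
#' @param T target temperature, K
#' @param tau_T_ps thermostat relaxation time, ps
#' @param P_bar target pressure, bar (NPT)
#' @param tau_P_ps barostat relaxation time, ps (NPT)
#' @param kappa_per_bar barostat compressibility parameter, 1/bar
#' @param seed integer seed for all stochastic elements
#' @param velocities optional N x 3 initial velocities, A/fs (restart)
#' @param remove_com remove centre-of-mass momentum at initialisation
#' @param topology optional precomputed [identify_molecules()] result
#' @return an `md_trajectory`; frames hold unwrapped positions (image
#'   displacements accumulated, for mean-squared-displacement analysis) and
#'   the per-frame cell; `$series` holds per-step scalars (T, kinetic /
#'   potential / total energy, CSVR conserved quantity, instantaneous
#'   pressure, volume, edge); `$meta` holds the run settings and final
#'   state (`positions`, `velocities`, `L`) for restarts
#' @export
run_md <- function(initial, potential = c("LL", "HL", "composite", "none"),
                   theory = two_level_theory(), model = NULL,
                   ensemble = c("nvt", "nve", "npt"), steps = 1000,
                   dt_fs = 0.5, stride = 20, T = 298, tau_T_ps = 0.1,
                   P_bar = 1, tau_P_ps = 1, kappa_per_bar = 4.5e-5,
                   seed = 1, velocities = NULL, remove_com = TRUE,
                   topology = NULL) {
  potential <- match.arg(potential)
  ensemble <- match.arg(ensemble)
  stopifnot(dt_fs > 0, tau_T_ps > 0, tau_P_ps > 0, steps >= 0)
  if (!initial$periodic) stop("run_md requires a periodic configuration")
  if (potential == "composite" && !inherits(model, "delta_model"))
    stop("composite potential requires a trained delta model")
  topo <- .topology_for(initial, topology)
  L <- cell_edge(initial)
  masses <- .masses_of(initial$elements)
  mlpack <- if (potential == "composite") .model_pack(model) else NULL
  res <- md_run_cpp(initial$positions, .elem_codes(initial$elements), masses,
                    topo$mol, L, potential, .theory_list(theory), mlpack,
                    ensemble, dt_fs, as.integer(steps), as.integer(stride),
                    T, tau_T_ps * 1000, P_bar, tau_P_ps * 1000,
                    kappa_per_bar, as.integer(seed), velocities, remove_com)
  frames <- lapply(seq_along(res$frames), function(k) {
    atoms(initial$elements, res$frames[[k]], cell = res$frame_L[k],
          info = list(t_fs = res$frame_t[k], unwrapped = TRUE))
  })
  meta <- list(potential = potential, ensemble = ensemble, dt_fs = dt_fs,
               stride = stride, T = T, P_bar = P_bar, tau_T_ps = tau_T_ps,
               tau_P_ps = tau_P_ps, seed = seed, steps = steps,
               n_mol = topo$n_mol,
               final = list(positions = res$final_positions,
                            velocities = res$final_velocities,
                            L = res$final_L))
  trajectory(frames, dt_fs = dt_fs * stride, ensemble = ensemble,
             series = res$series, meta = meta)
}

#' Final configuration of a run, for restarts
#'
#' @param traj an `md_trajectory` from [run_md()]
#' @return the final [atoms()] configuration (unwrapped positions, final cell)
#' @export
final_frame <- function(traj) {
  fin <- traj$meta$final
  atoms(traj$frames[[1]]$elements, fin$positions, cell = fin$L,
        info = list(velocities_available = TRUE))
}

#' Final velocities of a run, A/fs
#' @param traj an `md_trajectory` from [run_md()]
#' @return N x 3 matrix of velocities in A/fs
#' @export
final_velocities <- function(traj) traj$meta$final$velocities

# wrap positions into [0, L)
.wrap <- function(pos, L) pos - L * floor(pos / L)
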