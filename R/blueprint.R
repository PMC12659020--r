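.blueprint_defaults <- function() {
  list(
    seed = 1,
    output_dir = "blueprint_run",
    system = list(n_molecules = 126, density = 0.997,
                  temperature = 298, pressure = 1),
    sampling = list(equil_steps = 20000, prod_steps = 40000, stride = 100,
                    temperatures = c(260, 298, 330), pressures = c(1, 1000)),
    carve = list(radii = c(2.5, 3.5, 4.5, 5.5), counts = c(1800, 1800, 1800, 1800),
                 val_fraction = 0.1, margin = 2.0, compact = FALSE,
                 compact_count = 100),
    train = list(lambda = 1e-6),
    md = list(npt_steps = 100000, nvt_steps = 100000, dt_fs = 0.5,
              stride = 100, replicas = 3),
    analysis = list(rdf_dr = 0.05, msd_window_ps = c(1, 4), eta = 0.896,
                    n_blocks = 10, equil_fraction = 0.3),
    thresholds = list(density = 0.001, diffusion = 0.045, peak = 0.01))
}

.deep_merge <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]))
      base[[k]] <- .deep_merge(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

.log_stage <- function(dir, stage, seed, t0, extra = list()) {
  rec <- c(list(stage = stage, seed = seed,
                wall_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
                time = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(dir, "run_ledger.jsonl"), append = TRUE, sep = "")
}

#' Run the delta-learning blueprint end to end
#'
#' Executes the full workflow from a single structured configuration:
#' generate and equilibrate a water box, sample baseline (LL) trajectories
#' over a grid of thermodynamic conditions, carve and label a cumulative
#' cluster dataset, train the delta model, run composite and direct
#' high-level MD, measure density / O-O RDF peak / diffusion, and emit a
#' radius-convergence report.  Every stage logs its seed and wall time to a
#' JSON-lines run ledger in the output directory, and stage outputs are
#' written as extended-XYZ / CSV / JSON so an interrupted run can resume
#' (stages whose outputs exist are skipped when `resume = TRUE`).
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list; unspecified entries fall back to package defaults
#'   (`deltamd:::.blueprint_defaults()`)
#' @param dry_run validate and print the execution plan without running
#' @param resume skip stages whose output files already exist
#' @return (invisibly) a list with the convergence table, the trained
#'   model paths and the output directory; the dry run returns the plan
#' @export
run_blueprint <- function(config, dry_run = FALSE, resume = TRUE) {
  cfg <- .blueprint_defaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  cfg <- .deep_merge(cfg, config)
  if (isTRUE(cfg$carve$compact)) {
    k <- length(cfg$carve$counts)
    cfg$carve$counts[k] <- min(cfg$carve$counts[k], cfg$carve$compact_count)
  }
  plan <- list(
    stages = c("generate", "sample", "carve", "label", "train",
               "md", "analyse", "report"),
    config = cfg)
  if (dry_run) {
    cat("Blueprint plan (dry run):\n")
    cat(" stages:", paste(plan$stages, collapse = " -> "), "\n")
    cat(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE), "\n")
    return(invisible(plan))
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  th <- two_level_theory()
  seed <- cfg$seed

  # generate + equilibrate
  t0 <- Sys.time()
  box_file <- out("box_equilibrated.xyz")
  if (!(resume && file.exists(box_file))) {
    eq <- equilibrated_water_box(cfg$system$n_molecules, cfg$system$density,
                                 seed = seed, theory = th,
                                 T = cfg$system$temperature,
                                 equil_steps = cfg$sampling$equil_steps)
    write_extxyz(eq$configuration, box_file)
    .log_stage(cfg$output_dir, "generate", seed, t0)
  }
  box <- read_extxyz(box_file)$frames[[1]]

  # baseline sampling over the condition grid (carving frames from the
  # ambient condition; the other conditions broaden the sampled state space)
  t0 <- Sys.time()
  src_file <- out("sampling_ambient.xyz")
  if (!(resume && file.exists(src_file))) {
    k <- 0L
    for (Ts in cfg$sampling$temperatures) for (Ps in cfg$sampling$pressures) {
      k <- k + 1L
      ens <- if (Ps == cfg$system$pressure) "nvt" else "npt"
      tr <- run_md(box, "LL", th, ensemble = ens,
                   steps = cfg$sampling$prod_steps,
                   stride = cfg$sampling$stride, T = Ts, P_bar = Ps,
                   dt_fs = cfg$md$dt_fs, seed = .derive_seed(seed, 20L, k))
      f <- out(sprintf("sampling_T%d_P%d.xyz", Ts, Ps))
      write_extxyz(tr, f)
      if (Ts == cfg$system$temperature && Ps == cfg$system$pressure)
        file.copy(f, src_file, overwrite = TRUE)
    }
    .log_stage(cfg$output_dir, "sample", seed, t0)
  }
  src <- read_extxyz(src_file)

  # carve + label + train
  t0 <- Sys.time()
  spec <- carve_spec(radii = cfg$carve$radii, counts = cfg$carve$counts,
                     seed = .derive_seed(seed, 30L),
                     val_fraction = cfg$carve$val_fraction,
                     margin = cfg$carve$margin)
  ds_file <- out("dataset.xyz"); man_file <- out("dataset_manifest.csv")
  if (!(resume && file.exists(ds_file))) {
    ds <- label_delta(build_cluster_dataset(src, spec), th)
    write_dataset(ds, ds_file, man_file)
    .log_stage(cfg$output_dir, "carve+label", spec$seed, t0,
               list(n_clusters = length(ds)))
  } else {
    ds <- label_delta(build_cluster_dataset(src, spec), th)
  }
  t0 <- Sys.time()
  model_file <- out("delta_model.json")
  model <- delta_fit(ds, lambda = cfg$train$lambda,
                     seed = .derive_seed(seed, 40L))
  write_delta_model(model, model_file)
  .log_stage(cfg$output_dir, "train", model$seed, t0,
             list(val_rmse_per_mol = model$report$rmse_per_mol_val))

  # convergence workflow (composite vs direct HL)
  t0 <- Sys.time()
  conv <- converge_radius(src, spec, th, lambda = cfg$train$lambda,
                          thresholds = do.call(convergence_thresholds,
                                               cfg$thresholds),
                          replicas = cfg$md$replicas,
                          seed = .derive_seed(seed, 50L),
                          T = cfg$system$temperature, P = cfg$system$pressure,
                          npt_steps = cfg$md$npt_steps,
                          nvt_steps = cfg$md$nvt_steps,
                          dt_fs = cfg$md$dt_fs, stride = cfg$md$stride,
                          equil_fraction = cfg$analysis$equil_fraction,
                          n_blocks = cfg$analysis$n_blocks,
                          rdf_dr = cfg$analysis$rdf_dr,
                          msd_window_ps = cfg$analysis$msd_window_ps,
                          eta = cfg$analysis$eta)
  write.csv(conv$table, out("convergence_table.csv"), row.names = FALSE)
  jsonlite::write_json(list(verdicts = as.data.frame(conv$verdicts),
                            deltas = conv$deltas_vs_reference,
                            thresholds = unclass(conv$thresholds)),
                       out("convergence_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(cfg$output_dir, "converge", conv$seed, t0)

  invisible(list(convergence = conv, model = model,
                 model_file = model_file, output_dir = cfg$output_dir,
                 config = cfg))
}
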