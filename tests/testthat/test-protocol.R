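test_that("two-point basis-set extrapolation is exact on its model form", {
  # fixed point
  expect_equal(cbs_extrapolate(-2.5, -2.5), -2.5)
  # planted X^-3 convergence is removed exactly
  E_inf <- -76.412; A <- 0.37
  e3 <- E_inf + A * 3^-3; e4 <- E_inf + A * 4^-3
  expect_equal(cbs_extrapolate(e3, e4, 3, 4, 3), E_inf, tolerance = 1e-12)
  # direct arithmetic on a TZ/QZ pair
  expect_equal(cbs_extrapolate(-1.000, -1.037, 3, 4, 3), -1.0640,
               tolerance = 1e-4)
  # linearity and monotonicity in E_Y
  ys <- seq(-1.2, -0.8, by = 0.1)
  vals <- vapply(ys, function(y) cbs_extrapolate(-1, y, 3, 4, 3), 0)
  expect_true(all(diff(vals) > 0))
  expect_lt(max(abs(diff(diff(vals)))), 1e-12) # exactly linear
  expect_error(cbs_extrapolate(-1, -1.1, 3, 3), "differ")
})

test_that("compact mode trims only the largest radius", {
  full <- carve_spec(counts = rep(1800L, 4), seed = 1)
  cmp <- compact_mode(full)
  expect_equal(cmp$counts, c(1800L, 1800L, 1800L, 100L))
  expect_equal(sum(cmp$counts), 5500)
  expect_warning(out <- compact_mode(carve_spec(radii = c(2.5, 3.5),
                                                counts = c(50L, 50L)), 100),
                 "clamp")
  expect_equal(out$counts[2], 50L)
})

test_that("a zero-weight delta model reports zero force scale", {
  frames <- source126()$frames[seq(50, 150, by = 50)]
  rep0 <- force_scale_report(frames, two_level_theory(), zero_delta_model())
  expect_equal(rep0$medians[["delta"]], 0)
  expect_gt(rep0$medians[["LL"]], 0.1)
})

test_that("training on a degenerate theory gives near-zero delta forces", {
  th0 <- two_level_theory(d_eps = 0, lambda3 = 0)
  ds <- label_delta(build_cluster_dataset(
    source72(), carve_spec(radii = c(2.5, 3.5), counts = c(80, 80),
                           seed = 13)), th0)
  m0 <- delta_fit(ds)
  frames <- source72()$frames[seq(20, 80, by = 30)]
  rep0 <- force_scale_report(frames, th0, m0)
  expect_lt(rep0$medians[["delta"]], 1e-8)
})

test_that("the radius protocol degenerates gracefully when HL equals LL", {
  th0 <- two_level_theory(d_eps = 0, lambda3 = 0)
  src <- source72()
  spec <- carve_spec(radii = c(2.5, 3.5), counts = c(60, 60), seed = 14)
  conv <- converge_radius(src, spec, th0, replicas = 2, seed = 5,
                          npt_steps = 1500, nvt_steps = 2500, stride = 25,
                          equil_fraction = 0.2, n_blocks = 5,
                          msd_window_ps = c(0.1, 0.5))
  # delta labels are all zero, so every composite row samples the same
  # potential as the reference; all rows agree within a few replica errors
  tab <- conv$table
  ref <- nrow(tab)
  for (i in 1:2) {
    expect_lt(abs(tab$rho[i] - tab$rho[ref]),
              4 * sqrt(tab$rho_se[i]^2 + tab$rho_se[ref]^2) + 1e-3)
  }
  expect_true(all(is.na(conv$verdicts[2, ]))) # last radius has no forward step
})

test_that("infinite thresholds mark the first radius converged", {
  th0 <- two_level_theory(d_eps = 0, lambda3 = 0)
  src <- source72()
  spec <- carve_spec(radii = c(2.5, 3.5), counts = c(40, 40), seed = 15)
  conv <- converge_radius(src, spec, th0,
                          thresholds = convergence_thresholds(1e9, 1e9, 1e9),
                          replicas = 2, seed = 6, npt_steps = 800,
                          nvt_steps = 1500, stride = 25,
                          equil_fraction = 0.2, n_blocks = 4,
                          msd_window_ps = c(0.1, 0.4))
  expect_true(all(conv$verdicts[1, ]))
})

test_that("the blueprint validates a dry run and executes a micro workflow", {
  cfgfile <- tempfile(fileext = ".yaml")
  outdir <- file.path(tempdir(), "bp_micro")
  writeLines(sprintf("
seed: 4
output_dir: %s
system: {n_molecules: 72, density: 0.997, temperature: 298, pressure: 1}
sampling:
  equil_steps: 1200
  prod_steps: 1600
  stride: 50
  temperatures: [298]
  pressures: [1]
carve: {radii: [2.5], counts: [120], val_fraction: 0.1}
md: {npt_steps: 800, nvt_steps: 1200, stride: 20, replicas: 1}
analysis: {msd_window_ps: [0.1, 0.4], equil_fraction: 0.2, n_blocks: 4}
", outdir), cfgfile)
  plan <- run_blueprint(cfgfile, dry_run = TRUE)
  expect_true(is.list(plan$config))
  expect_false(dir.exists(file.path(outdir, "nonexistent")))
  res <- run_blueprint(cfgfile)
  expect_true(file.exists(file.path(outdir, "delta_model.json")))
  expect_true(file.exists(file.path(outdir, "dataset_manifest.csv")))
  expect_true(file.exists(file.path(outdir, "convergence_table.csv")))
  expect_true(file.exists(file.path(outdir, "run_ledger.jsonl")))
  tab <- read.csv(file.path(outdir, "convergence_table.csv"))
  expect_equal(nrow(tab), 2) # one radius + reference row
  expect_true(all(is.finite(tab$rho)))
  # rerun with resume: identical manifest and model
  man1 <- readLines(file.path(outdir, "dataset_manifest.csv"))
  m1 <- jsonlite::fromJSON(file.path(outdir, "delta_model.json"))
  res2 <- run_blueprint(cfgfile)
  expect_identical(readLines(file.path(outdir, "dataset_manifest.csv")), man1)
  m2 <- jsonlite::fromJSON(file.path(outdir, "delta_model.json"))
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-12)
})
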