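# deltamd

Delta-learning pipeline for condensed-phase water: carve clusters from
periodic snapshots, learn the energy difference between a cheap baseline
potential and a high-level target on those clusters, compose the learned
correction with the baseline, run molecular dynamics, and verify that the
composite reproduces the high level's density, structure and diffusion.

## Who this is for

Simulators who want coupled-cluster-quality observables for liquid water
but can only afford the high-level method on gas-phase clusters.  The
delta-learning route trains a short-ranged correction ΔE = E_HL − E_LL on
clusters of cumulatively increasing radius and adds it to the baseline in
periodic simulations; convergence is verified self-consistently by growing
the carve radius until density, the first O–O RDF peak and the diffusion
coefficient stop changing.  `deltamd` implements the complete loop as a
tested R package with a compiled (Rcpp) core.  Because real
electronic-structure engines are out of scope, it ships a synthetic
two-level theory (an SPC/E-like flexible-water baseline "LL" plus a
strictly short-ranged perturbation defining the target "HL") whose high
level *can* be simulated directly — so the whole pipeline is validated
against ground truth.

## The model at the core

The correction is linear ridge regression on rotation- and
permutation-invariant atom-centred descriptors with a 4 Å cutoff
(Gaussian radial channels per element pair plus
(1 + λ cos θ)^ζ e^{−η(r_ij² + r_ik²)} angular channels), trained on
energy-only labels

  ΔE_i = E_HL(cluster_i) − E_LL(cluster_i),

with a per-molecule intercept absorbing the size-proportional part of the
label.  Forces and virials come from the analytic gradient of the fitted
model, so the composite potential E_LL + ΔE_model runs plain NVE/NVT/NPT
dynamics (velocity Verlet, CSVR thermostat, stochastic cell-rescaling
barostat with molecular-centre scaling).  See the methods vignette
(`vignettes/delta-learning-methods.Rmd`) for the full account.

## Worked example

```r
library(deltamd)
theory <- two_level_theory()

# 1. equilibrated baseline box at the experimental density, then sampling
eq  <- equilibrated_water_box(126, density = 0.997, seed = 23,
                              equil_steps = 16000)
src <- run_md(eq$configuration, "LL", theory, ensemble = "nvt",
              steps = 30000, stride = 200, seed = 71,
              velocities = eq$velocities)

# 2. cumulative cluster dataset, energy-difference labels, delta model
spec  <- carve_spec(radii = c(2.5, 3.5, 4.5, 5.5),
                    counts = c(600, 600, 300, 100), seed = 11)
ds    <- label_delta(build_cluster_dataset(src, spec), theory)
model <- delta_fit(ds)
model
#> <delta_model: 64 features/element, lambda = 1e-06>
#>   train: n = 1440, RMSE/molecule = 3.177e-05 eV
#>   val  : n = 160, RMSE/molecule = 3.476e-05 eV
#>   val RMSE by radius (A): 2.5: 1.55e-05, 3.5: 4.11e-05, 4.5: 4.79e-05, 5.5: 2.95e-05

# 3. composite dynamics: an 18 ps NPT run of a 72-water box
box <- equilibrated_water_box(72, seed = 3, equil_steps = 8000)
npt <- run_md(box$configuration, "composite", theory, model = model,
              ensemble = "npt", steps = 36000, seed = 3101,
              velocities = box$velocities)
density_mean(npt, equil_fraction = 0.25, n_blocks = 8)
#> <density: 1.0455 (0.0068) g/cm^3, 8 blocks>
```

The baseline alone equilibrates near 0.95 g/cm³ while the composite,
like the directly simulated high level, sits near 1.02–1.05 g/cm³
depending on the run — the learned correction recovers the ~7% density
gap between the two theories.  The fitted correction reproduces the bulk
energy difference of held-out periodic frames to ~5% of its fluctuation,
its forces are an order of magnitude below the baseline's, and paired
composite/high-level NPT and NVT runs agree in density, O–O first-peak
height and corrected self-diffusion — the recovery experiment run by
`tests/testthat/test-acceptance.R` and, at full protocol scale, by
`converge_radius()` / `run_blueprint()`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/deltamd` (subcommands `generate`, `carve`, `label`, `train`,
`md`, `analyze`, `blueprint`).

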