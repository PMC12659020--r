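---
title: "Methods: a delta-learning pipeline for condensed-phase water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a delta-learning pipeline for condensed-phase water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Reaching coupled-cluster-quality predictions for liquid water (density,
structure, self-diffusion) is too expensive to do by direct simulation:
the high-level method can only be afforded on small gas-phase clusters.
Delta learning sidesteps this by training a *correction* — a model of the
energy difference between a cheap baseline theory and the expensive target
theory — on clusters carved out of condensed-phase snapshots, and then
adding that correction to the baseline in periodic simulations.  The
approach rests on two assumptions:

1. the baseline already describes the long-range physics, so the
   difference between the two theories is *short-ranged*, and
2. condensed-phase behaviour of the difference can be *learned from
   clusters* of increasing size, with convergence that can be verified
   self-consistently by monitoring observables as the carve radius grows.

`deltamd` implements that entire loop as a testable artifact.  Because
real electronic-structure engines are outside its scope, it ships a
synthetic two-level theory whose high level is directly simulable, so the
whole pipeline can be validated against ground truth: train the correction
on clusters, simulate the composite model, and compare against direct
high-level molecular dynamics.

## The synthetic two-level theory

Both levels share a flexible three-site water model: harmonic O–H bonds
(`k_bond` = 25 eV/Å², r₀ = 0.9572 Å) and a harmonic H–O–H angle
(`k_angle` = 2.5 eV/rad², θ₀ = 104.52°), SPC/E-like point charges
(q_O = −0.8476 e), and an O–O Lennard-Jones term (ε = 6.737 meV,
σ = 3.166 Å).  Two deliberate departures from textbook water models:

* **Electrostatics are damped shifted-force (Wolf-type) Coulomb**
  (α = 0.2 Å⁻¹, cutoff 6 Å) rather than Ewald.  The same finite-ranged
  functional form applies in open and periodic boundary conditions, which
  is essential here: cluster labels and periodic evaluations must come
  from *identical* physics or the carved-cluster labels would contain
  boundary artefacts the model cannot represent.
* **Lennard-Jones uses shifted-force truncation** (energy and force both
  continuous at the cutoff) instead of a bare energy shift.  Force
  continuity at the cutoff protects energy conservation in NVE and makes
  the smoothness of the total surface testable; the cost — a slightly
  perturbed effective well — is irrelevant in a synthetic theory.

The high level adds two strictly short-ranged terms, both vanishing
smoothly at 4 Å:

* a Gaussian attractive O–O pair well (depth 0.02 eV at 2.9 Å, width
  0.35 Å, cosine-switched off between 3.2 and 4.0 Å), and
* a Stillinger–Weber-style O–O–O three-body penalty
  λ₃ (cos θ − cos θ₀)² s(r_ij) s(r_ik) with λ₃ = 0.03 eV,
  cos θ₀ = −1/3 and s(r) = exp(γ/(r − r_c)), γ = 1.2 Å, r_c = 4 Å.

The pair well binds the first coordination shell more strongly, so the
high level equilibrates ~7% denser than the baseline (measured once
during calibration on 72-water boxes: 0.952 vs 1.024 g/cm³ at
298 K / 1 bar; the shipped record is in
`inst/extdata/calibration_densities.json` and returned by
`calibrate_two_level()`).  This mirrors the practical situation where a
DFT baseline underestimates the density of the coupled-cluster target by
several percent.  The three-body term gives the difference genuinely
angular content, so a radial-only correction model demonstrably underfits
— a useful negative control for the descriptor design.

An earlier calibration used a Lennard-Jones-form pair perturbation
instead of the Gaussian well; its 1/r¹² core *repelled* the first shell
and moved the density the wrong way.  The Gaussian well is the minimal
form that shifts density upward while keeping the difference confined
within 4 Å.

## Carving and the cumulative dataset

Clusters are carved around every molecule of periodic snapshots: a
molecule belongs to the cluster of centre molecule *c* at radius r_c when
its oxygen lies within r_c of the centre oxygen under the minimum image.
The centre-O-to-molecule-O rule is the simplest unambiguous choice;
molecules are kept whole (hydrogens follow their oxygen) and the cluster
is unwrapped to open boundaries with the centre O at the origin.  No
rotational canonicalisation is applied — the descriptors are rotationally
invariant, and keeping the laboratory orientation aids debugging.

The cumulative dataset draws (frame, centre) pairs uniformly without
replacement per radius, independently across radii, with all randomness
derived from one seed.  The default schedule is 1800 clusters at each of
2.5, 3.5, 4.5 and 5.5 Å; `compact_mode()` reduces the largest radius to
100, reflecting the observation that with a cumulative dataset only a
handful of expensive large clusters is needed.  The geometric
precondition max(radius) + 2 Å < L/2 guarantees an unambiguous carve with
whole molecules; at the experimental density this requires at least
~110 molecules for 5.5 Å clusters and ~64 molecules for 3.5 Å ones.

Labels are energy-only differences E_HL − E_LL of the open clusters.  No
force labels are used anywhere; forces of the fitted model come from
analytic differentiation.

The recovery experiments carve from snapshots of *both* levels (baseline
NVT plus a high-level NVT trajectory of the same box).  Carving only from
baseline-sampled configurations leaves the correction model extrapolating
precisely in the more-structured geometries the target ensemble favours,
which showed up as a slight over-structuring of the composite (first-peak
height high by ~0.03, diffusion a few percent slow).  Enriching the source
with target-ensemble snapshots — the same resampling idea used when the
correction is built iteratively in practice — removed most of that bias
and also improved the validation RMSE and the cluster-to-bulk transfer
error.

## The correction model

Per-atom descriptors with a 4 Å cosine cutoff: Gaussian radial channels
(centres 0.5–3.75 Å in 0.25 Å steps, width 0.25 Å) per neighbour element,
and twelve angular channels 2^(1−ζ)(1 + λ cos θ)^ζ exp(−η(r_ij² + r_ik²))
f_c(r_ij) f_c(r_ik) with (ζ, λ) ∈ {1, 2} × {+1, −1} at three radial
envelopes η ∈ {0.04, 0.1, 0.25} Å⁻², resolved by neighbour-pair element
(O–O, O–H, H–H).  The (ζ, λ) set spans {1, cos θ, cos²θ}, exactly the
angular content of the synthetic three-body term; the three envelopes
give the angular channels radial resolution.  A single-envelope
four-channel set was tried first: its cluster-to-bulk transfer error
plateaus at ~2–3× the twelve-channel set's regardless of training-set
size, because one radial profile cannot resolve the three-body switching
function — a model-class, not a data, limitation.  The 4 Å cutoff embodies the
delta-learning capacity argument: the correction is far more local than
the baseline interactions (6 Å), so the correction model can be much
smaller than a baseline model would need to be.

The model is linear ridge regression of the total cluster label on
summed per-element atomic features, plus a molecule-count column that
acts as a per-molecule intercept and absorbs the size-proportional part
of the label — this stabilises extrapolation from small clusters to the
bulk.  Features are standardised by training mean and scale.  Two
numerical choices matter:

* **Scale flooring.**  Column scales are floored at 1% of the largest
  column scale.  Descriptor channels probing geometry absent from
  training (e.g. O–O distances below 2.4 Å) have near-zero variance;
  standardising them by their own tiny scale amplifies noise into
  enormous weights, which materialise as unphysical energy holes the
  first time molecular dynamics visits such geometry.  With the floor,
  dead channels keep near-zero effective weights and the composite
  dynamics is stable.
* **Ridge strength.**  λ = 1e-6 by default; the planted-solution
  recovery test runs at 1e-10, and λ = 0 produces an informative error
  for singular systems.

Validation uses a 10% holdout, stratified by radius so the reported RMSE
is not dominated by the most numerous radius.  At the package's smoke
scale the validation RMSE is ≈ 7e-5 eV per molecule and a radial-only
ablation is ≈ 3× worse, confirming the angular channels carry the
three-body signal.

For production dynamics the fitted weights are compiled into a faster
equivalent form: the weighted radial channels collapse into one tabulated
pair function per element pair (cubic Hermite interpolation with analytic
knot slopes, so interpolated energy and force are exactly consistent),
and the angular channels collapse into per-channel polynomials in cos θ
(exact for integer ζ and |λ| ≤ 1).  This is a reparametrisation, not an
approximation beyond interpolation error (≲1e-10 eV per pair).

## Molecular dynamics

Velocity Verlet with one force evaluation per step; a Verlet neighbour
list (0.5 Å skin) rebuilt on a displacement trigger and refreshed against
current coordinates every step.  Cell lists are pointless at these sizes
— the box is under three cutoffs wide.  Defaults follow common practice
for flexible water: dt = 0.5 fs, T = 298 K.

* **Thermostat**: canonical sampling through velocity rescaling (CSVR),
  relaxation time 0.1 ps, with the conserved-quantity accumulator
  tracked; degrees of freedom 3N − 3 (centre-of-mass momentum removed at
  initialisation and preserved).
* **Barostat**: isotropic stochastic cell rescaling with a 1 ps
  relaxation time and compressibility parameter 4.5e-5 bar⁻¹.  Positions
  are scaled by molecular centres of mass (atoms ride rigidly with their
  molecule), and the pressure driving the barostat is the *molecular*
  pressure — centre-of-mass kinetic energy plus molecular virial — which
  is the estimator conjugate to molecular-centre scaling.  Using the
  atomic estimator with molecular scaling leaves a systematic offset of
  order the intramolecular virial.  Nosé–Hoover chains would be the
  main alternative; stochastic rescaling was chosen because it is
  simpler, ergodic by construction and of the same family as CSVR.
* All stochastic elements (Maxwell–Boltzmann initialisation, thermostat
  and barostat noise) draw from one counter-seeded generator with
  hand-rolled normal and gamma transforms, so trajectories are bitwise
  reproducible for a given seed, independent of platform library
  details.

Trajectories store unwrapped coordinates (for mean-squared-displacement
analysis) together with per-frame cells and a per-step scalar series
(temperature, energies, conserved quantity, instantaneous pressure,
volume).

## Observables

* **RDF**: shell-count histogram normalised by the ideal-gas expectation
  with each frame's own density, so NPT input is handled correctly; bin
  width 0.05 Å.  First-peak height and position by quadratic
  interpolation through the maximal bin and its neighbours.
* **Self-diffusion**: molecular (oxygen-site) MSD over multiple time
  origins (origins spaced at half the longest lag), least-squares slope
  over a stated window, D = slope/6.  The finite-size correction is the
  Yeh–Hummer hydrodynamic form D∞ = D_PBC + ξ k_B T/(6π η L) with
  ξ = 2.837297 and a user-supplied viscosity (default 0.896 mPa·s, water
  at 298 K) — the community-standard correction for cubic periodic
  boxes.  The default fit window (2–10 ps at production scale; shorter
  at smoke scale) is a pragmatic choice, as is the origin spacing.
* **Density**: post-equilibration mean of the per-step density series
  with a standard error from 10 non-overlapping block means; the first
  20–30% of each run is discarded.
* **Isobar**: independent NPT runs per temperature and replica; an
  interior density maximum is located by a quadratic fit through the top
  three points, and monotone tables are flagged as having no maximum.

## The radius-convergence protocol

`converge_radius()` is the heart of the blueprint: for each cumulative
radius set it carves, labels, trains, runs composite NPT (density) and
NVT (structure and diffusion at the fixed reference density, the same
convention used for convergence testing of the real workflow), with
independent replicas providing errors.  Convergence verdicts use
*forward* successive differences — radius r_i is converged when the step
to r_{i+1} changes the observable by less than the threshold (density
0.1% relative, diffusion 4.5% relative, O–O peak 0.01 absolute).  In the
synthetic setting the direct high-level simulation is cheap, so the table
also carries a ground-truth reference row and the deviations from it;
a real application would use the largest radius as its own reference.

Replica seeds derive deterministically from one master seed.  The
blueprint driver (`run_blueprint()`) chains box generation, baseline
sampling over a small temperature/pressure grid (defaults 260/298/330 K
× 1/1000 bar as a desk-scale stand-in for broad thermodynamic sampling),
carving, labelling, training, the convergence workflow and reporting,
logging every stage's seed and wall time to a JSON-lines ledger, and
skipping completed stages on resume.

## Problem sizes used by the tests

The package's own validation runs at deliberately small scales, chosen
once as the smallest systems that respect the geometric preconditions:

* **72-water boxes** (L = 12.93 Å at 0.997 g/cm³) for the recovery
  experiments.  The minimum-image convention demands L ≥ 12 Å for the
  6 Å cutoffs, and NPT fluctuations at the denser high level make a
  64-water box graze that bound; 72 leaves margin.  Carve radii are
  restricted to {2.5, 3.5} Å there (the 2 Å whole-molecule margin bounds
  the radius by L/2 − 2).
* **126-water boxes** (L = 15.577 Å) wherever the protocol itself is the
  subject: 5.5 Å cluster occupancy, NVE conservation at production
  scale.
* Recovery-experiment statistics use *seed-paired* runs: composite and
  high-level simulations share the thermostat and barostat noise
  streams, so the explicit noise largely cancels from observable
  differences.  For the density this is dramatic — independent 35 ps
  NPT runs scatter by ~2% while paired differences scatter by ~0.2% —
  because the stochastic cell-rescaling volume walk is noise-dominated.
  NVT observables (peak height, diffusion) decorrelate chaotically and
  benefit less; their comparisons use 3 paired 25 ps runs, a 0.075 Å
  RDF bin with a five-point least-squares peak fit, and a 1–5 ps MSD
  window.  The fitted correction's virial bias translates to only a few
  bar (~0.02% in density), so remaining deviations are dominated by
  sampling noise at these run lengths.

What passing these tests shows — and what it does not.  The synthetic
two-level theory has a genuinely short-ranged, smooth, few-body
difference by construction.  Passing the recovery experiment demonstrates
that the *pipeline* (carving, labelling, energy-only training, composite
dynamics, observables, convergence bookkeeping) is correct and
self-consistent.  It does not demonstrate that a real DFT→CCSD(T)
difference is as learnable: real corrections contain many-body and
possibly longer-ranged components, real labels carry numerical noise from
local-correlation approximations and basis-set choices, and real water
exhibits nuclear quantum effects that classical dynamics misses.  Those
questions belong to the laboratory, not to this package.

## Known limitations

* Cubic orthorhombic cells, rigid three-site water topology, O/H only.
* The Coulomb treatment is finite-ranged by design; systems where the
  baseline's long-range physics matters beyond 6 Å (ionic solutions,
  interfaces) would need an Ewald-consistent pair of levels.
* The correction model is linear in fixed descriptors.  That is enough
  for the synthetic difference and keeps training deterministic and
  closed-form, but it has no message-passing expressivity; the
  architecture slot is intentionally swappable.
* Path-integral dynamics (nuclear quantum effects) is out of scope; all
  results are classical.
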