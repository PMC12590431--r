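---
title: "Methods: active-learning surrogate optimisation of probiotic tabletting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-learning surrogate optimisation of probiotic tabletting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

probitab identifies tabletting process conditions — compression speed,
precompression pressure and main compression pressure — that maximise the
survival of a freeze-dried probiotic (*Lactobacillus gasseri* KS-13 scale
formulation) during compaction. It couples three pieces: a reduced-order
compaction–thermal–viability simulator (the "oracle") that plays the role
of a full finite-element compaction model as the label source; a
Gaussian-process-regression (GPR) surrogate refined by active learning
(AL); and a procedure that extracts the near-optimal process region as a
3-D alpha shape. This vignette records the models, the tunable
parameters, the numerical choices, and the design decisions that were
genuinely open — and what the accompanying tests do and do not show.

## The process space

A process point is a triple (speed in mm/min, precompression pressure in
MPa, main compression pressure in MPa), subject to the press constraint
that precompression never exceeds the main pressure. The default space
covers speeds 0–5000 mm/min and main pressures 50–400 MPa — benchtop
through industrial presses; `design_space_lab()` is the benchtop window
(10–180 mm/min, up to 374 MPa).

Three generators are provided. `sobol_design()` maps a scrambled Sobol
sequence (Joe–Kuo direction numbers, random digital shift keyed by the
seed, index-0 point skipped so the unscrambled design never degenerates
to the all-lower-bounds corner) into the space; the precompression
coordinate is mapped measure-preservingly as `pre = u2 * main`, which
keeps the low-discrepancy structure while enforcing the constraint by
construction. `random_design()` instead draws uniformly in the box and
rejects constraint violations — the retain-after-sampling behaviour
wanted for the global candidate search. `slice_grid()` builds the regular
lattices used for survival maps. Inputs to the GP are normalised by a
fixed affine min–max map of the global bounds (precompression by the
global cap, not each point's own main pressure), so the kernel metric is
stationary in a fixed unit cube.

## The reduced-order oracle

The oracle condenses the three mechanisms of the full finite-element
treatment into a desk-scale model.

**Compaction work.** The Drucker–Prager Cap yield surfaces (shear failure
line, elliptical cap, smoothing transition) are implemented as
stress-space functions, `dpc_surfaces()`, and unit-tested; no
return-mapping elastoplastic solve is performed. Instead, densification
follows the exponential pressure law `RD(P) = RD_max − (RD_max − RD_0)
exp(−P/P_c)` (defaults `RD_0 = 0.45`, `RD_max = 0.95`, `P_c = 80` MPa),
and plastic work accumulates as `P dε_v` along that path. Punch travel
derives from mass conservation (6 mm die, 3.4 mm final compact height),
so every ramp duration is travel/speed: halving the speed doubles the
ramp time. A full schedule is: plastic ramp to the precompression
pressure, elastic unload (effective unloading modulus 8 GPa), a fixed
0.2 s inter-compression gap (press turnover; config-exposed), elastic
reload, plastic ramp to the main pressure, final unload. Unloading is
elastic by convention and generates no plastic heat. Speeds are clamped
to ≥ 1 mm/min internally so durations stay finite.

**Thermal response.** The energy balance ρC~p~ dT/dt = ∇(k∇T) + q̇~p~ +
q̇~f~ is solved on a 1-D radial finite-volume grid (default 50 shells,
backward-Euler, unconditionally stable; Rcpp implementation). Plastic
heating q̇~p~ = η~pl~ P |dε~v~/dt| is volumetric and uniform; frictional
heating q̇~f~ = μ K~rad~ P v~slip~ enters as a die-wall flux. The tooling
is an isothermal sink: Robin cooling at the die wall with a half-cell
resistance correction (so the 50-shell solution matches an 8× finer
reference to better than 1 % on core peak temperature and the survival
functional), plus a lumped axial Robin sink 2h/H for the punch-face
contact — the compact is thin axially, and without that term the
inter-compression gap cannot dissipate precompression heat from the
bulk, which would invert the experimentally motivated precompression
benefit. With an insulated wall the scheme conserves energy to well
under 0.5 %.

**Thermal tolerance.** Survival at a location is a log-linear (z-value)
function of the peak temperature it experienced: `S = s_max * 10^(−max(0,
T_peak − T_crit)/z_T)`, and tablet-level survival is the shell-volume
weighted average (the cylindrical-volume quadrature of the survival
field). The plateau `s_max` defaults to 1: low-pressure "activation"
above 100 % survival seen in some experiments is deliberately not
modelled. A time-integrated D–z variant was considered and rejected for
the default because the emulated finite-element model's tolerance law is
peak-exposure-based.

**Calibration.** The tolerance and transport parameters of the prior
finite-element work are not published, so four anchor statistics pin the
oracle to its reported behaviour: minimum survival ≈ 4 % on the 400 MPa
high-speed panel; ≈ 3 percentage points of precompression benefit at
250 MPa; ≈ 0.2 log-cycles of benefit from a 133 MPa precompression
before a 374 MPa main stroke at 180 mm/min; and ≥ 99 % survival at a
gentle benchtop condition. `calibrate_oracle()` adjusts `T_crit`, `z_T`,
`mu_fric` and `h_wall` by bounded least squares — a deterministic coarse
Sobol scan of the parameter box followed by a Nelder–Mead polish — and
the shipped parameter set (`inst/extdata/oracle_params.json`, loaded by
`oracle_params()`) reproduces all four anchors within 9 % relative
(gate: 15 %). The calibrated values (onset 44.9 °C, z = 3.0 K, μ = 0.02,
h = 312 W m^−2^ K^−1^) are physically plausible for a vegetative
lactobacillus and a lubricated die.

## The GPR surrogate

The surrogate is an exact GP with the isotropic squared-exponential
kernel k(x, x′) = σ² exp(−‖x−x′‖²/2l²) on normalised inputs, zero mean
on centred targets (the centring constant is stored and restored at
prediction). Fitting is Cholesky-based with jitter escalation
(10^−10^ → 10^−6^) and averaging of near-duplicate inputs; prediction
returns the latent-function standard deviation by default. Length-scale
and variance are tuned by maximising the log marginal likelihood with
Bayesian optimisation: 8 Sobol seed evaluations in the log10 box
(l ∈ [10^−2^, 10], σ² ∈ [10^−4^, 10^2^]), then 30 acquisitions of
expected improvement computed on an internal GP over the evaluated
points. Scores are winsorised at their median before standardisation —
the evidence falls off by orders of magnitude away from its optimum and
raw scores would flatten the acquisition model where it matters. The
"plus" modification guards against over-exploitation: when the internal
GP's predictive spread at the incumbent collapses below 10^−3^ of its
prior scale, its kernel variance is inflated five-fold for that
proposal. A multistart Nelder–Mead maximiser of the same evidence is the
independent cross-check; on well-conditioned (noisy-data) test problems
the two land within 0.5 likelihood units.

One design decision deliberately departs from tuning the noise variance
jointly: the oracle labels are noiseless, so `noise2` is a fixed small
stabiliser (10^−6^) rather than a free hyperparameter. Tuned jointly,
the evidence absorbs structural misfit as noise, the posterior standard
deviation at already-labelled points stays high, and the
maximum-uncertainty acquisition re-queries neighbourhoods instead of
covering the space — measurably degrading the surrogate below a plain
Sobol design of the same size. With the fixed stabiliser, labelling a
point collapses its posterior uncertainty to the 10^−3^ level and the
loop behaves as intended.

## The active-learning loop

Thirty Sobol points are labelled by the oracle and fit; then, per
iteration, a fresh constraint-respecting random pool of 4096 candidates
is scored, the point of maximum posterior standard deviation is labelled
and appended, hyperparameters are retuned (every iteration by default,
warm-started from the incumbent to keep successive retunes in the same
evidence basin), and R²/RMSE are recorded on a 100-point Sobol
validation set generated with a distinct scrambling seed. The default
budget is 78 iterations — 108 training points in total. Everything is
reproducible from a single seed via a fixed splitting rule (validation
seed + 10000, tuner seed + 20000, iteration-i pool seed + 30000 + i).
Validation size and pool mechanics are package choices; the source
study does not report them.

## Near-optimal region and survival maps

`find_optimal_region()` samples 5000 random candidates (optionally in
the benchtop window while normalising against the training space),
predicts survival, truncates posterior means at the physical plateau of
1 — a Gaussian posterior can overshoot a saturated response near sharp
features, and "within 99 % of the maximum" is only meaningful against
the physical maximum — and retains candidates with mean ≥ 0.99 × max
(inclusive). The retained cloud is wrapped in a 3-D alpha shape computed
in normalised coordinates: an in-package incremental Bowyer–Watson
Delaunay tetrahedralisation, tetrahedra kept while their circumradius is
below alpha, volume as the sum of kept tetrahedra, boundary as the
triangles owned by exactly one kept tetrahedron. `alpha = Inf` recovers
the convex hull (cross-checked against an independent qhull computation
to 10^−9^); the default `alpha = "auto"` binary-searches the observed
circumradii for the smallest value at which every retained point belongs
to one connected component. `survival_map()` evaluates the oracle or the
surrogate on fixed-main-pressure lattices (the 250/300/350/400 MPa
panels).

## Plate-count arithmetic

For laboratory validation data, `cfu_per_tablet()` implements the
standard dilution-plating count S = N~P~ V~I~/(r V~F~) — the printed
formula is precedence-ambiguous, and the conventional reading (dilution
fraction and plated volume in the denominator) is the one that
reproduces 10^7^-scale per-tablet counts — and `survival_rate()` the
percentage against the baseline loading of 3.9 × 10^7^ CFU/tablet.
Duplicate plates sharing a sample identifier are averaged after the
count formula (equivalent to averaging counts when duplicates share a
dilution, and robust when they do not).

## Problem sizes, runtime and known limitations

A single oracle call integrates ~700 implicit steps over 50 shells in
about 2 ms; a full AL run (108 labels, per-iteration retuning, 4096-point
pools) takes ~15 s, calibration ~2 min, and the five-seed convergence
study a few minutes on one CPU. These are the sizes used throughout the
tests and the reproduction script.

What passing tests show — and what they do not. The synthetic oracle
emulates the mechanisms the full finite-element model encodes (pressure-
driven densification work, tooling heat sink, z-value kill) and is pinned
to its printed summary statistics, but it is not that model: it has no
axial resolution, no elastoplastic stress field, no punch-geometry or
porosity effects, no strain-rate dependence of the material response
(speed enters through ramp kinematics only), and no pressure-only
(athermal) kill or repeated-compression damage. Consequences are
visible and documented: the calibrated response concentrates most of its
speed sensitivity below ~600 mm/min, which is sharper than the emulated
model's apparent behaviour — the 108-point surrogate reaches a median
validation R² of about 0.94 and RMSE of about 0.10 on the fraction
scale, short of the 0.96/0.06 reported for the original, smoother label
source; and the near-optimal region in the benchtop window is broader
than the reported 70–150 MPa band, because at benchtop speeds the
tooling sink rescues survival over much of the space, including the
high-precompression corner where splitting the work across two strokes
lets the gap dissipate the first dose. Conclusions about real tablets
should rest on the laboratory workflow, not on the oracle.
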