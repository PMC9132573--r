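---
title: "Two-step substrate engagement of eIF2B: models, fitting conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step substrate engagement of eIF2B}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eif2bkin)
```

## The biological problem

eIF2B is the decameric guanine nucleotide exchange factor (GEF) that loads
GTP onto the translation initiation factor eIF2. It is the control point of
the integrated stress response: phosphorylated eIF2 (eIF2-P) converts from
substrate to inhibitor, trapping eIF2B in an inhibited I-State
conformation. The βH160D point mutation in the eIF2Bβ subunit mimics that
inhibited conformation without any phosphorylation, which makes it a clean
system for asking *which* steps of substrate engagement the conformational
change actually damages.

This package implements the quantitative machinery for that question:
engagement kinetics from SPR, exchange enzymology, assembly titrations, and
conformational metrics from atomic models, plus a synthetic-data generator
that stands in for the raw instrument exports.

## The two-step engagement model

eIF2 contacts eIF2B through four interfaces. IF1–IF3 sit on one βγδε
tetramer half; IF4 sits on the δ' subunit of the *opposing* half. Binding
is modeled as

$$U + L \xrightleftharpoons[k_{-1}]{k_1 C} P \xrightleftharpoons[k_{-2}]{k_2} F$$

with $U$ free sites, $P$ the partially engaged complex (IF1–IF3) and $F$
the fully engaged complex (IF1–IF4). In fractional occupancies,

$$\frac{dP}{dt} = k_1 C\,U - (k_{-1} + k_2)\,P + k_{-2}\,F,
\qquad \frac{dF}{dt} = k_2 P - k_{-2} F, \qquad U = 1 - P - F.$$

Both bound states carry the same analyte mass, so the SPR response is
$(P + F)\,R_\mathrm{max}$: response units track bound mass, not
conformation. `simulate_sensorgram()` integrates this system with
`deSolve::lsoda` at absolute and relative tolerance $10^{-10}$, which keeps
mass conservation below $10^{-8}$ and lets the integrator be validated
against closed forms to $10^{-6}$ relative error.

### What happens when flow stops: two dissociation conventions

Once analyte flow stops ($C = 0$) the bound states evolve under the matrix
$\begin{pmatrix} -(k_{-1}+k_2) & k_{-2} \\ k_2 & -k_{-2} \end{pmatrix}$,
and the decay of $P + F$ is the biexponential built from its
eigen-decomposition (`dissociation_eigen_decay()` is the closed-form
oracle used in the tests).

This raises a real modeling fork. If $k_2$ stays active during
dissociation (`dissociation = "ode"`), partially engaged complexes keep
converting to fully engaged ones, and numerically the fast eigenmode
carries almost no amplitude: for the wild-type-like scheme the fitted fast
phase is under 1%, not the ~11% observed. The biphasic phenomenology of
the experiments is instead captured by the two-population reading
(`dissociation = "phase"`): the fast phase *is* the partially engaged
population leaving at $k_{-1}$, the slow phase *is* the fully engaged
population leaving at the composite rate $k_{-1} k_{-2}$ (on a 1 s⁻¹
scale, see below), with no interconversion after flow stops. Whether the
washout of free analyte justifies freezing $k_2$ is not experimentally
settled, so both conventions are exposed and the ODE form remains the
default for simulation; the variable-association analysis and the
reproduction pipeline use the phase mapping, because that is the reading
under which the fast-phase amplitude measures the partial-state
population.

### The k₋₂ relation

The slow phase is treated as dissociation that requires both retracting
IF4 and releasing IF1–IF3, summarized as $k_{-1} \cdot k_{-2} =
k_{d,\mathrm{slow}}$ with $k_{-1} = k_{d,\mathrm{fast}}$. Taken literally
the left side has units s⁻²; `derive_k_minus2()` therefore evaluates the
quotient on a 1 s⁻¹ scale, $k_{-2} = k_{d,\mathrm{slow}} /
k_{d,\mathrm{fast}}$, which reproduces the reference value 0.044 s⁻¹ from
(0.12, 5.3×10⁻³). A dimensionally consistent alternative is provided:
`derive_k_minus2_eigen()` solves for the $k_{-2}$ that makes the slow
eigenvalue of the dissociation matrix equal the observed slow rate,

$$k_{-2} = \frac{k_{s}\,(k_{-1} + k_2 - k_{s})}{k_{-1} - k_{s}},$$

where $k_s$ is the observed slow rate. Both are reported; the quotient
form is the default because it is the convention the reference values were
derived under.

### Occupancy ratios, k₂, and free energies

$k_2$ is not directly observable from a single cycle. It is fixed from the
variable-association plateau: if the plateau fast-phase percentage is $f$,
the equilibrium full:partial ratio is $(100 - f)/f$
(`occupancy_ratio()`), and $k_2 = \mathrm{ratio} \times k_{-2}$
(`reference_scheme()`). The wild-type plateau of ~11% gives a ratio of ~8;
the mutant's ~55% gives ~0.8 (reported as ~1) — the mutation leaves
IF1–IF3 kinetics untouched and selectively disfavors the second step.
State free energies follow as $-RT\ln$ of the step equilibrium constants
(`free_energy_profile()`), with the bimolecular step referenced to a
stated standard concentration (default 1 M) and optional Eyring barriers
with a configurable transmission prefactor; a ratio of 8 at 298 K
corresponds to a second-step stabilization of $-RT\ln 8 \approx
-5.15\ \mathrm{kJ/mol}$.

## Fitting conventions

* **Association** (`fit_association()`): global fit of
  $R(t) = R_{eq}(1 - e^{-k_{obs} t})$, $k_{obs} = k_a C + k_d$, across the
  titration with shared $k_a, k_d$ and per-cycle $R_{eq}$; per-cycle
  single-exponential $k_{obs}$ values are kept for diagnostics. A series
  whose response never clears three times the baseline noise is reported
  as *no binding* rather than an error, mirroring the tetramer + eIF2-P
  case.
* **Dissociation** (`fit_dissociation()`): Levenberg–Marquardt least
  squares of $A[f e^{-k_f t} + (1-f)e^{-k_s t}]$ with the plateau fixed at
  0 (fully reversible binding on a regenerated surface; configurable).
  Multi-start initialization seeds the fast rate from the first 10% of the
  decay and the slow rate from the last 50%; $f$ is constrained to
  $[0, 1]$; phases are relabeled post-fit so $k_f \ge k_s$; rates within
  5% of each other are declared degenerate and returned as a single phase
  with a warning. The residual-function optimizer is used deliberately:
  single-exponential data drive the optimum to the boundary $f = 1$,
  where formula-interface fitters fail on a singular Jacobian.
* **Variable association** (`variable_association_analysis()`): each
  cycle's dissociation is fit biphasically, then the fast-phase
  percentage versus association time is fit to
  $f_{eq} + (f_0 - f_{eq})e^{-\ln 2\, t/t_{1/2}}$. The plateau is compared
  against the analytic steady-state partial fraction
  $100\,k_{-2}/(k_2 + k_{-2})$. The single-exponential summary is itself
  an approximation (the underlying relaxation is not exactly exponential
  in association time), so plateau agreement is expected at the percent
  level while the *equilibrated* cycles agree with the analytic value to
  much better than 1%. Whether the published summary fits floated the
  plateau is unstated; here the plateau is always free.
* **Exchange kinetics** (`fit_exponential()`): first-order exponential
  with a floating baseline (baseline handling is unstated in the source
  protocols; floating is the conservative choice). Rates are reported per
  minute, $t_{1/2} = \ln 2 / \mathrm{rate}$ exactly. Loading and
  unloading phases are fit independently. Signal changes below three
  times the first-difference noise estimate are classified *no exchange*.
  Any plotting-style time binning must never feed the fitter; fits always
  use the raw cadence.
* **Initial velocities and calibration** (`initial_velocity()`,
  `build_calibration()`): linear fit over the 50–200 s window (the
  protocol's convention), converted to pmol/min through an endpoint-gain
  calibration line over the 31.5 nM–1 µM range; velocities without a
  calibration are returned explicitly unit-tagged as au/min.
* **Michaelis–Menten** (`fit_michaelis_menten()`): per-replicate nonlinear
  fits whose means give the reported $V_{max}$ and $K_M$, preserving the
  replicate structure the downstream t-tests need
  (`compare_replicates()`, Student by default, Welch by flag). The
  turnover convention (`kcat_from_vmax()`) counts two catalytic ε
  subunits per decamer: 10 nM decamer in 20 µL is 0.4 pmol of sites, so
  $V_{max} = 0.66$ pmol/min gives $k_{cat} = 1.65$ min⁻¹. The small
  discrepancy between a pooled-mean $k_{cat}$ (4.65 min⁻¹ from 1.86
  pmol/min) and a per-replicate-averaged one (4.70 min⁻¹) is inherent to
  averaging order and is not reconciled here.
* **Assembly EC50** (`fit_ec50()`): four-parameter logistic on
  $\log_{10}$ concentration with free Hill slope (fixable to 1).
  Zero-concentration anchors enter at one decade below the smallest
  positive concentration (the log-offset convention). *No assembly* is
  declared when the fitted dynamic range is under three times the
  residual noise **or** the fitted EC50 falls outside the tested range —
  the latter guard exists because a flat noisy series admits a
  shallow-Hill drift fit that a range-only rule misses.
* **Structure metrics** (`superpose()`, `hinge_angle()`,
  `pocket_distance()`): Kabsch superposition via SVD with determinant
  correction (implemented in-package because the rotation matrix itself
  is needed for the axis–angle conversion; it is cross-checked against
  bio3d in the tests). The hinge angle is the residual rotation of the
  mobile half after aligning on the reference half,
  $\theta = \arccos((\mathrm{tr}\,R - 1)/2)$. Pocket distances default to
  Cα atoms with a side-chain-tip rule selectable, because the atom
  convention behind published Å values is not stated; reproduction of
  published hinge/pocket numbers from deposited models is therefore
  selection-dependent and expected only within about a degree / half an
  Ångström. Chain-to-subunit mappings differ between depositions and are
  supplied by the caller as selections.

## What the synthetic data emulate — and what they do not

The generator reproduces the *designs* of the source experiments: 2-fold
SPR titrations with 60 s association and 600 s dissociation; variable
association from 5–480 s at 62.5 nM; exchange time courses sampled every
10 s for 60 min; Michaelis–Menten titrations over 0–4 µM substrate in
three replicates; FRET titrations averaging four technical replicates.
Noise is a single family: additive Gaussian, either absolute or relative
to trace amplitude, with explicit seeds (identical seed ⇒ byte-identical
data, and generators never disturb the caller's RNG stream).

Problem sizes and sampling used by the default tests and pipeline, chosen
once as realistic instrument settings: SPR recovery studies sample the
dissociation phase at 10 Hz (the data rate of T200-class instruments —
a 1 Hz grid under-samples a $t_{1/2} \approx 6$ s fast phase), association
titrations run six 2-fold dilutions from 500 nM, FRET titrations use
twelve 2-fold dilutions plus a zero anchor, and recovery statistics use
500 noisy replicates (SPR) or batches of 100 three-replicate experiments
(Michaelis–Menten, where "bias" means the mean error across experiments,
not a single realization).

Real sensorgrams additionally contain bulk refractive-index jumps, drift,
regeneration scars and mass-transport limitation; real plate reads
contain optical gain drift; none of these are modeled (deliberately — the
source data do not characterize them). Passing recovery tests therefore
demonstrates estimator correctness under the stated noise model, not
robustness to instrument artifacts.

## Numerical choices and degenerate inputs

Seconds and molar are the internal units everywhere; nM, minutes and
2-significant-figure KD displays happen only at reporting
(`compute_affinity()` keeps full precision internally). Integrator
tolerances are $10^{-10}$ with output on a fixed grid. Ties and
degeneracies are handled explicitly: equal fast/slow rates collapse to a
single phase; zero rates make free-energy differences infinite and are
rejected rather than returned as NaN; a fast-phase series with no
relaxation (no second step) short-circuits the plateau fit; missing
residues abort structural measurements with the offending selection
listed; alternate-location atoms resolve to the highest-occupancy
conformer.

## The pipeline

`run_all(default_config(seed))` regenerates every synthetic assay at the
reference conditions, runs all fitters, and emits a reproduction table
(value, units, reference, tolerance, pass) as TSV and JSON; identical
configs and seeds give byte-identical reports. The configuration is plain
YAML (`read_run_config()` / `write_run_config()`), and
`inst/cli/pipeline.R` wraps the same call for shell use. Known limitation:
the published variable-association half-times (10.4 s wild type, 20.7 s
mutant) parameterize the *approach* to equilibrium and cannot be
recomputed without the raw traces, so the pipeline checks the plateau
logic rather than those half-times; similarly the reproduction of
published hinge/pocket values from deposited coordinate files requires
downloading those models and is left to the user, with the toy-structure
fixtures providing exact ground truth instead.
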