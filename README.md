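# eif2bkin

Kinetic and structural analysis of how the decameric guanine nucleotide
exchange factor **eIF2B** engages its substrate **eIF2** — and how the
disease-associated βH160D point mutation, which biases eIF2B toward an
inhibited (I-State-like) conformation, changes that engagement.

The package is written for biochemists and structural biologists who work
with surface plasmon resonance (SPR), fluorescent-GDP nucleotide-exchange
assays, FRET assembly titrations and atomic models, and who want a tested,
scriptable alternative to point-and-click fitting.

## The model at the core

eIF2 engages eIF2B in two sequential steps across four interfaces:

```
            k1·C           k2
  U + eIF2 ⇌ P (IF1–IF3) ⇌ F (IF1–IF4)
            k-1            k-2
```

* `U` — free immobilized eIF2B; `P` — partially engaged complex using
  interfaces IF1–IF3 on one tetramer half; `F` — fully engaged complex that
  additionally docks IF4 on the opposing tetramer half.
* SPR dissociation is **biphasic**: the fast phase (rate `kd_fast = k-1`)
  reports `P`, the slow phase reports `F`. The second-step retraction rate
  follows the dissociation relation `k-2 = kd_slow / kd_fast` (1 s⁻¹ scale),
  and the equilibrium occupancy ratio `[F]/[P] = k2/k-2` falls out of the
  plateau fast-phase percentage `f` as `(100 − f)/f`.
* Nucleotide exchange follows Michaelis–Menten kinetics with the turnover
  number computed per catalytic site: `kcat = Vmax / (C_enzyme · V · sites)`,
  two catalytic ε subunits per decamer.
* Assembly titrations are four-parameter logistic fits of the FRET ratio
  E592/E516 against dimerizer concentration.
* Conformational comparisons use Kabsch superposition: the hinge angle is
  the residual rotation of one tetramer half after aligning the other, and
  pocket widenings are residue-pair distances between states.

All simulation is done by integrating the two-state ODE
(`dP/dt = k1·C·U − (k-1 + k2)·P + k-2·F`, `dF/dt = k2·P − k-2·F`) with a
stiff-capable adaptive integrator; every fitter is exercised against a
seeded synthetic-data generator, so the whole pipeline is testable without
any instrument export.

## Worked example

Simulate a wild-type-like engagement experiment and read the kinetic story
back off the trace:

```r
library(eif2bkin)

scheme <- reference_scheme(occupancy_ratio = 8)   # k1 = 7e5, k-1 = 0.12, k-2 = 0.044
scheme
#> Two-step engagement scheme
#>   k1      = 7e+05 M^-1 s^-1
#>   k-1     = 0.12 s^-1
#>   k2      = 0.352 s^-1
#>   k-2     = 0.044 s^-1
#>   K2 = k2/k-2 = 8 (full : partial at equilibrium)

sg  <- simulate_sensorgram(scheme, 62.5e-9, 480, 600, capacity = 100,
                           time_step = 0.5, dissociation = "phase")
fit <- fit_dissociation(sg, n_phases = 2)
fit
#> Dissociation fit (2 phases)
#>   kd_fast = 0.12 s^-1  (11.1% of amplitude)
#>   kd_slow = 0.00528 s^-1  (88.9% of amplitude)
#>   amplitude = 76.64 RU, rss = 1.32e-26

derive_k_minus2(fit$kd_fast, fit$kd_slow)   # 0.044 s^-1
occupancy_ratio(100 * fit$fraction_fast)    # 8: fully engaged outnumbers partial 8:1
kcat_from_vmax(0.66, 10e-9, 20e-6, 2)       # 1.65 min^-1 (mutant decamer turnover)
```

The 11.1% fast phase is the steady-state partially engaged population of a
scheme whose second step favors full engagement 8:1; dividing the fitted
slow rate by the fast rate returns the `k-2` the scheme was built with; and
0.66 pmol/min of maximal velocity over 0.4 pmol of catalytic sites (10 nM
decamer, 20 µL, 2 sites) is a turnover of 1.65 min⁻¹.

The full comparison — association fits across a 2-fold titration,
variable-association analysis, Michaelis–Menten and EC50 fits, free-energy
profiles, hinge/pocket metrics — runs as one call:

```r
report <- run_all(default_config(seed = 1))
report$table        # parameter, value, units, reference, pass
```

or from a shell via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pipeline.R",package="eif2bkin"))')" run --seed 1 --out out/
```

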