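---
title: "The double-cable model: methods, assumptions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double-cable model: methods, assumptions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axoncable)
```

## The circuit

A myelinated internode is modelled as two nested conductors. The axon core
carries an axial current limited by the axoplasmic resistivity
(`R_i`, Ω·cm); the thin periaxonal fluid between axolemma and innermost
myelin membrane carries a second axial current with per-length resistance
`r_pa` (Ω/cm), continuing through the paranodes with a higher per-length
resistance `r_pn` before reaching grounded extracellular space at the
nodal edges. Radially, the axolemma (`R_m` kΩ·cm², `C_m` µF/cm²) separates
core from periaxonal space, and the whole myelin sheath (`R_my`, `C_my`,
referred to the axolemma area) separates the periaxonal space from ground.
Unmyelinated domains (soma, dendrites, AIS, nodes, cut end) have only the
axolemma, facing ground directly.

The state vector is the core potential plus the periaxonal potential of
every myelinated compartment. Writing the system as `M x' = A x + b` keeps
`M` and `A` symmetric — the mass matrix couples core and periaxonal rows
through the axolemma capacitance — and makes the three experimental
potentials exact derived views: transaxonal `V_m` (core − periaxonal),
transmyelin `V_my` (periaxonal − ground) and transfiber
`V_mym = V_m + V_my`. With a uniform leak reversal at the resting
potential, rest (`V_my = 0` everywhere) is an exact equilibrium of the
discrete system.

Collapsing the periaxonal layer gives the classical single cable: the
axolemma and sheath combine in series per compartment (resistances add,
capacitances add reciprocally). The double cable therefore *nests* the
single cable: pushing `r_pa` to its upper bound and removing the paranodal
grounds reproduces the SC solution — a property the test suite checks to
0.5 %.

## Discretization and integration

Compartment counts per section follow the d-λ rule: the smallest odd
number of segments keeping each segment below `d_lambda` (default 0.1)
times the AC length constant at `f_m = 1/(2π τ_min)`, with `τ_min = 1 ms`
by default, matching the fastest membrane time constant expected in the
recordings. Discretization is frozen when the graph is built (from
reference parameters); re-parameterisations during fitting reuse the grid.
This mirrors the common practice of fixing the segment count per section,
and makes candidate evaluation a pure re-assembly of conductances on a
fixed topology.

Integration is implicit — backward Euler at `dt = 0.01 ms` by default
(robust, first order, L-stable), with Crank–Nicolson available for
convergence studies (second order, but its trapezoidal rule lets stiff
modes ring at coarse steps, which is why the test suite verifies its
order through absolute error against a matrix-exponential oracle rather
than signed Richardson ratios). Voltage clamp is implemented by row
substitution (an exact Dirichlet condition), not a large series
conductance, so the clamped node follows the command to machine precision
with no stiffness tuning. Piecewise-constant stimuli are aligned to step
intervals, which makes both integrators exact in the input term.

Active conductances use Hodgkin–Huxley-style gates with three parametric
rate families and Q10 temperature scaling (simulations run at 35 °C by
default). The kinetics shipped as defaults are deliberately generic — no published
allosteric sodium scheme or literature potassium/HCN parameterisation is
reproduced — so every channel-level conclusion the package draws is
sign-level (ordering,
monotonicity, presence of saltation), never quantitative kinetics. Gates
are integrated by exponential Euler against the lagged voltage; channel
conductances enter the linear solve implicitly. With zero densities the
active path reduces to the passive solver on the same code path.

## Parameter fitting

The estimation pipeline reproduces a physiology workflow:

1. **Trials** are baselined against the first 70 % of the pre-pulse delay
   (the rule's placement within the delay is not critical and is fixed
   here at the leading segment), then rejected if more than 5 % of their
   samples leave the pointwise across-trial mean ± 2 SD band, counting
   only excursions of at least 0.1 ms — shorter deviations are inside the
   acquisition filter's bandwidth and treated as false positives.
   Survivors are averaged.
2. **Windows** start 0.5 ms after the end of the current pulse for
   injecting/recording electrodes (pipette-discharge artifacts) and at
   pulse end for recording-only electrodes; that second rule is the
   package's choice — the +0.5 ms allowance is justified only by injection
   artifacts, which a voltage-follower electrode does not see.
3. **The objective** is the equally weighted mean of per-trace windowed
   mean-squared errors. The forward model exploits passive linearity: one
   unit-current simulation per candidate, scaled to each injection level.
4. **Search** runs in normalised log-parameter space (all bounds are
   positive and span decades): Latin-hypercube initialisation, tournament
   selection, uniform crossover, annealed Gaussian mutation and elitism;
   defaults population 64, mutation SD 0.1. Several mutually distant elite
   candidates are then refined by a Powell-style direction-set method
   whose pass exits as soon as the error improvement falls below `eta`
   (default 1) times the experimental noise floor — the variance of the
   pre-stimulus segment — followed by a Nelder–Mead polish. Independent
   restarts with derived seeds emulate the original strategy of selecting
   the lowest-error solution across many runs; the number of restarts is
   part of the budget.

Bounds default to an ultrastructural envelope: sheath resistance between
10 and 100 lamellae of the literature extremes for a single myelin
membrane; sheath capacitance from the axolemma bounds folded through the
same lamella range; the periaxonal axial resistance between a 35 Ω·cm
fluid (squid axoplasm) in a 300 nm space around a 0.5 µm axon and
deionised water (2 MΩ·cm) in a 1 nm (Debye-limited) space around a 2 µm
axon; the paranodal upper bound 100× higher.

### What is and is not identifiable

A finding the test suite documents deliberately: at physiological
parameter scales the paranodal seal, not the myelin radial branch, is the
dominant return path of the periaxonal layer (per internode end roughly
2×10⁸ Ω through the seal against ~10¹⁰ Ω radially through the sheath).
Consequently `r_pa` is strongly identified by axo-somatic transients
(halving or doubling it moves the combined error far above the noise
floor), `R_i`, `R_m`, `C_m` are recovered to within a few percent, and
`r_pn` to tens of percent — but `R_my` moves the objective by less than
1 % across a full decade, and `C_my` only somewhat more. Desk-scale fits
on synthetic recordings therefore recover `R_i`, `R_m`, `C_m` within 10 %
and `r_pa` within a factor of two, while the sheath resistance settles
anywhere on an almost exactly degenerate `(R_my, C_my, r_pa, r_pn)` valley
whose extent exceeds a factor of two (the sheath capacitance sits near the
edge of a ±30 % band and recovers only by seed). The 30 % sheath-recovery
expectation is asserted as stated and left failing, with this analysis as
the record;
the wide spread of per-membrane resistance estimates across real cells is
consistent with the same degeneracy. Circuit *ranking* is unaffected: on
double-cable-generated targets every single-cable variant leaves a large,
structured residual (concentrated in the first milliseconds of the axonal
rise) and the DC fit wins by an order of magnitude in error at small
budgets.

## The synthetic generators

The generator emulates the study conditions for thick-tufted L5 axons: up
to six internodes whose lengths scale as 100 µm per µm of core diameter
with the first two shortened; 2.3 µm paranodes and 1 µm nodes (nodal
length is not constrained by the available anatomy and is config-exposed);
core diameter 1.1 µm; g-ratio 0.698; 10.5 lamellae per µm of diameter;
periaxonal width 12.3 nm (truncated normal over 8.5–17.1 nm, SD back-
computed from the reported SEM at n = 195). Ground-truth cable parameters
derive from printed ultrastructure means: single-membrane values
R_mm = 8.56 kΩ·cm² and C_mm = 1 µF/cm² folded through the lamella count,
periaxonal/paranodal fluids of 53.7 and 550 Ω·cm. The axolemma and
axoplasm values (R_i = 100 Ω·cm, R_m = 15 kΩ·cm², C_m = 1 µF/cm²) are
field-typical choices, since per-cell optima are not published as reusable
numbers.

Recording sets follow the electrophysiology protocol: ±300–600 pA, 2 ms
pulses, 50 kHz sampling, 100 trials per level (within the reported 30–180
range), Gaussian noise of 0.1 mV SD shaped by a 4-pole 10 kHz low-pass
(the acquisition filter is applied to the noise; the simulated signal is
already band-limited by the solver, which keeps zero-noise trials exactly
equal to the clean simulation), per-trial baseline jitter at half the
noise SD, and occasional square artifact trials built to trip the
rejection rule. Traces default to 50 ms, which covers three time
constants of every passive relaxation in the model at a quarter of the
raw protocol's duration.

The dendritic load is a stylised pair of equivalent cylinders. It shapes
somatic transients realistically enough for recovery experiments but is
*not* a reconstruction: passing tests says nothing about fits to real
arbors, reconstruction errors (addressed separately through
`perturb_morphology()`, which jitters internodal diameters at the 300 nm
optical resolving distance), electrode drift, or channel kinetics beyond
sign level. Electrodiffusion and potassium accumulation under the sheath
are out of scope entirely.

## Numerical choices and edge cases

* Units are fixed per field (Ω·cm, kΩ·cm², µF/cm², Ω/cm, µm, nm); the
  solver works internally in mV/ms/nA/µS/nF.
* Lamella counts are continuous in the algebra; rounding to integers
  happens only in the generator and in reporting. The inverse relations
  (width ↔ resistivity, sheath ↔ membranes) are exact algebraic inverses
  and are property-tested to 10⁻¹⁰ relative.
* All ultrastructure functions reject non-positive inputs uniformly; the
  periaxonal width formula's discriminant is non-negative for positive
  inputs, so no complex roots arise.
* The pipette is 200 tapering cylinders (1 → 530 µm over 2 mm) whose wall
  has fixed specific resistance (50 GΩ·cm²) and a capacitance either tied
  to the fitted `C_pip` or set from the conical-capacitor geometry; the
  published uncompensated reference value could not be re-derived from the
  stated geometry, so the geometric value is reported, never asserted. The
  axial profile follows the taper and is scaled so the total equals the
  bridge balance (a per-section formula built from bridge balance and summed
  cross-sectional areas is dimensionally ambiguous); per-edge resistances are floored at 1 kΩ to
  keep the system well conditioned at zero bridge balance.
* The periaxonal layer is grounded at *both* ends of every myelinated
  chain (configurable), the reading most consistent with a seal at every
  paranodal edge.
* The periaxonal-width sensitivity sweep moves `r_pa` and `r_pn` together
  at fixed fluid resistivities: the paranodal gap is contiguous with the
  periaxonal space, so widening one widens the other while the seal
  remains a seal through its ~10× higher resistivity. This reproduces both
  limiting behaviours: a 1 nm space conducts in a near-binary saltatory
  mode and speeds up, a 1 µm space shunts the sheath and decelerates to
  the unmyelinated model's velocity.
* Onset latencies interpolate linearly between samples; derivatives use
  central differences; the recorded-mode conduction-velocity threshold
  (3 SD of pre-stimulus dV/dt noise) requires three consecutive
  supra-threshold samples so single noise excursions cannot fire the
  detector.
* Regenerative internodal spiking under raised internodal Na density is a
  kinetics-dependent phenomenon that the generic gates do not reproduce at
  any density; the spiking flags are exercised through sustained-current
  repetitive firing instead.

## Problem sizes

The shipped tests run everything at desk scale by choice: oracle systems
of ≤ 20 compartments; 2–6-internode morphologies (≈ 40–200 unknowns);
recovery fits with population 64 over ≈ 150 generations across three
restarts; twenty-seed circuit rankings with population 24 over 12
generations on 2-internode cells; sensitivity sweeps of 3–4 points on a
5-internode cell. The evolutionary machinery scales to cluster-sized searches unchanged; it
is simply given smaller budgets here.
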