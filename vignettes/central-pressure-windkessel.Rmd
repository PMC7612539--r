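---
title: "Estimating central blood pressure from aortic flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating central blood pressure from aortic flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpkit)
```

## The problem

Central (ascending-aortic) blood pressure differs from cuff pressure measured
at the arm — systolic values can disagree by tens of mmHg through pulse
amplification — and is the pressure the heart and major organs actually see.
Direct measurement requires catheterization. `cbpkit` reconstructs the
central pressure wave from data obtainable noninvasively: a single-cycle
aortic flow wave (from phase-contrast MRI or Doppler ultrasound) plus either
a peripheral pressure wave (tonometry; the `carotid+` scenario) or only cuff
DBP/SBP values (`carotid-`).

## Forward models

Both forward models are lumped (zero-dimensional) Windkessels. The
two-element model treats the arterial tree as a compliant reservoir
\(C_T\) draining through a resistance \(R_T\) toward an outflow pressure
\(P_{out}\):

\[
\frac{dP}{dt} + \frac{P - P_{out}}{R_T C_T} = \frac{Q_{in}}{C_T}.
\]

The three-element model inserts the aortic characteristic impedance \(Z_0\)
in series, \(R = R_T - Z_0\):

\[
\frac{dP}{dt} + \frac{P - P_{out}}{R C_T}
  = Z_0 \frac{dQ_{in}}{dt} + \frac{(Z_0 + R)\,Q_{in}}{R C_T}.
\]

Assumptions worth keeping in mind: pressure is spatially uniform (no wave
propagation, hence no dicrotic notch and no early-systolic shoulder in the
simulated waves), parameters are constant over the cycle, and the inflow
wave is exactly periodic.

### Numerical treatment

The substitution \(y = P - P_{out} - Z_0 Q_{in}\) reduces either model to the
scalar linear ODE \(y' = -y/\tau + Q_{in}/C_T\) with
\(\tau = (R_T - Z_0) C_T\). The solver advances this with an exponential
integrator — trapezoid quadrature on the exponentially weighted forcing —
with the decay factor \(e^{-\Delta t/\tau}\) assembled inside each step, so
no exponential of a large positive argument is ever formed (the textbook
integrating-factor formula, taken literally, overflows for small \(\tau\)).
The step is a linear recurrence evaluated by `stats::filter`, so a cycle at
the default 1 kHz sampling costs microseconds.

Periodicity is imposed in closed form: the one-cycle map is affine in the
initial value, so the unique fixed point \(P(0) = P(T)\) is solved directly
rather than by cycle iteration. A transient mode (`wk_settings(mode =
"transient")`) iterates cycles from a supplied \(P_0\) instead, converging
geometrically with ratio \(e^{-T/\tau}\); it exists mainly as a
cross-check.

`solve_wk_rk4()` provides an independent reference: classic fixed-step RK4
applied to the pressure ODE with the flow supplied as a function of time.
For a scalar linear ODE the RK4 step is itself an affine recurrence whose
coefficients involve only the forcing at \(t\), \(t + h/2\), \(t + h\); the
implementation evaluates that recurrence exactly, so the result is the RK4
trajectory to machine precision at a fraction of the cost of a time-stepping
loop. The test suite requires closed-form/RK4 agreement within 0.05 mmHg at
1 kHz output over randomly drawn physiological parameter sets; observed
agreement is typically below 0.01 mmHg.

Discretization choices: trapezoid quadrature with periodic closure
everywhere (on a uniform single-cycle grid the periodic trapezoid mean is
the sample mean); default sampling interval 1 ms, which keeps the
discretization error of the periodic solution well below 0.1 mmHg; waves
must carry at least 32 samples per cycle.

## The virtual population

`generate_dataset()` builds the validation population. Each subject is
defined by six parameters; five factorial levels
\(\mu, \mu \pm 0.5\sigma, \mu \pm \sigma\) per parameter give \(5^6 =
15{,}625\) combinations (so the grid SD of each parameter is
\(\sigma\sqrt{0.5}\)). Defaults, chosen once to represent healthy adults and
exposed in `cv_parameter_spec()`:

| parameter | mean | sigma | units |
|---|---|---|---|
| HR | 68.8 | 16.0 | beats/min |
| SV | 88.4 | 17.3 | mL |
| R_T | 0.51 | 0.12 | mmHg·s/mL |
| C_T | 1.3 | 0.4 | mL/mmHg |
| Z_0 | 0.0255 | 0.01 | mmHg·s/mL |
| P_out | 32.3 | 8.0 | mmHg |

The impedance mean is 5% of the resistance scale (the usual clinical rule of
thumb) and the outflow pressure mean is half a typical diastolic pressure,
so that the corresponding fixed-fraction estimators (Z3, OP3) are
near-unbiased on this population by construction.

The aortic flow wave is a skewed half-sine: \(Q(t) = Q_{max}
\sin(\pi (t/\mathrm{LVET})^{a})^{m}\) during ejection and zero in diastole,
with \(Q_{max}\) scaled so the wave integrates exactly to the stroke volume,
and \(\mathrm{LVET} = 0.293\,T\). The ejection fraction of the cycle is a
configurable shape constant; 0.293 places the fixed-fraction rule
\(0.37\,T\) about 26% high, the documented bias of that estimator on
lumped-model data. Subjects whose simulated pressures fall outside
physiological bounds (cSBP > 220, cDBP < 44, cPP < 18 or > 109 mmHg —
strict inequalities, values exactly on a bound retained) are flagged
excluded, not deleted, with the reason recorded.

What the generator does **not** emulate: wave reflection and propagation
(no notch, no systolic shoulder), measurement noise, beat-to-beat
variability, and heart-rate differences between the pressure and flow
acquisitions. Passing the analytic-recovery tests therefore demonstrates
correctness of the algorithms on model data — a lower bound on clinical
error, not a clinical validation.

## Parameter estimation methods

Estimators are selectable by the codes used across the method-comparison
literature. The choices that were genuinely open, and how they are resolved
here:

- **Diastolic fit windows.** The two diastolic-decay variants are
  distinguished by window: OP1/AC2 fit from LVET + 0.02 s to the end of the
  cycle; OP2/AC3 fit the final two-thirds of diastole. The three-parameter
  exponential \(P = P_{out} + (P_1 - P_{out}) e^{-(t-t_1)/\tau}\) is fitted
  by variable projection: for fixed \(\tau\) the model is linear, so the
  profiled residual is minimized over \(\log\tau\) with a golden-section
  search. This is deterministic, needs no starting values, and cannot
  converge to a local optimum of the two linear parameters. A fitted
  \(P_{out} < 0\) or a non-decaying amplitude raises a typed error rather
  than being clipped.
- **Decay-constant denominators.** AC1–AC4 return \(\tau/R_T\) by default,
  since \(Z_0\) is unknown at that pipeline stage; the exact
  \(\tau/(R_T - Z_0)\) is used when the caller supplies \(Z_0\) (as dataset
  validation against known truth does).
- **Optimized three-element fit** (AC9/Z6): bounded derivative-free search
  (Nelder–Mead in a logit-transformed box, \(Z_0 \in (10^{-4}, 0.5) R_T\),
  \(C_T \in (0.05, 10)\) mL/mmHg) minimizing whole-cycle unweighted RMSE
  with \(R_T\) and \(P_{out}\) fixed; four starts (one heuristic, three from
  a fixed-seed internal generator, so results are reproducible and the
  caller's RNG is untouched), best run polished by a restarted
  Nelder–Mead. The objective is smooth and, on model data, has a
  zero-residual global minimum; a 40×40 log-grid brute-force search is used
  as the oracle in the tests.
- **Z1 harmonic range.** The input-impedance modulus is averaged over
  harmonics 4–10 (configurable), the standard compromise: low harmonics
  carry the compliant-reservoir response, very high harmonics carry little
  flow energy. On lumped-model data this estimator retains an upward bias
  of order 25% — the reservoir response has not fully decayed by the 10th
  harmonic — which the tests assert as a property rather than hide.
- **Foot detection.** The intersecting-tangent rule: the tangent at the
  point of maximum upstroke derivative, intersected with the baseline
  (diastolic minimum for pressure, zero for flow). The wave and its
  derivative are smoothed by a periodic Savitzky–Golay filter (default
  40 ms window) before locating the argmax — raw central differences at
  1 kHz make the argmax noise-dominated at 1% additive noise — and the
  tangent's slope and anchor are then re-estimated by a short raw-data line
  fit on the rise side of the argmax, which removes the attenuation the
  filter introduces at the onset corner. Ties resolve to the earliest
  qualifying sample; the search is restricted to the upstroke (pre-peak
  minimum to peak) so filter ringing around falling edges elsewhere in the
  cycle cannot capture the argmax.
- **LVET from flow (LV4).** From the flow foot to the first time after peak
  flow at which flow drops below 2% of its peak (sub-sample crossing by
  linear interpolation) or the first local minimum, whichever is earlier.
  The 2% floor, rather than a zero crossing, keeps the rule usable on waves
  with diastolic noise.
- **Cuff-only surrogates.** Under `carotid-`, MBP is taken as
  DBP + 0.4·PP wherever a method needs a mean pressure (AR2's form; also
  used by Z4). The fixed-fraction rule LV3 is implemented literally as
  0.37·T, with an optional square-root variant (0.37·√T) behind a flag.

Failures anywhere in the catalogue raise classed conditions
(`cbpkit_error_*`), never silent `NaN`; `evaluate_dataset()` counts them per
method. Degenerate inputs — flat waves, notchless waves for LV1, unbracketed
root searches for AC6/AC7, non-positive pressure drops — each have a
dedicated error class.

## The two-stage pipeline

`run_cbp_pipeline()` estimates parameters in the fixed dependency order
LVET → P_out → R_T → C_T → (PWV) → Z_0 — each stage feeding the next, no
joint or iterative re-estimation — then simulates the periodic Windkessel
wave. Method selection defaults to the set found optimal on
physiologically richer wave-propagation validation data (`profile = "1D"`:
LV4/OP1/AR1/AC9/PV1/Z2 for `carotid+`, LV4/OP3/AR2/AC8/PV1/Z4 for
`carotid-`); the `"0D"` profile swaps in the methods that are exact on
lumped-model data (AC2 or an AC9 override, Z6, and AC7/Z3 for `carotid-`).
Incompatible selections — any wave-requiring method under `carotid-` — are
rejected at selection time as configuration errors.

For coupling to a 1-D arterial network solver,
`build_1d_outlet_params()` distributes the systemic parameters over the
terminal outlets: water-hammer impedance \(\rho\,\mathrm{PWV}/A_{out}\) per
outlet, outflow distribution from measured outlet flows or, failing that, an
area-proportional split of the supra-aortic flow deficit, peripheral
resistance \(R_T/\mathrm{OD} - Z_0\), and compliance
\((C_T - C_{T,art}) R_T / R_{Wk}\) with the 1-D segment compliance
\(C_{T,art} = \sum_k \bar{A}^k L^k / (\rho\,\mathrm{PWV}^2)\). Geometry
enters in SI units and results leave in clinical units
(1 Pa·s/m³ = 7.5006×10⁻⁹ mmHg·s/mL). The parallel-conductance identity
\(\sum_j (R_{Wk}^j + Z_{0}^j)^{-1} = \sum_j \mathrm{OD}^j / R_T\) holds by
construction and is property-tested.

## Assessment conventions

Percentage errors put the reference in the denominator; σ is the sample
standard deviation (n − 1) of the signed percentage errors. Bland–Altman
limits of agreement are bias ± 1.96·SD of the paired differences. Waveform
RMSE aligns both waves at their systolic foot (clinical waves share no
clock), resamples to a common 1 kHz grid over the shorter period, and
compares sample-wise; periods disagreeing by more than 10% are declared
incomparable.

## Problem sizes

The validation suite runs the full 15,625-subject grid for the closed-form
estimators (AR1, OP1), a deduplicated zero-impedance grid (3,125 subjects)
for the diastolic-decay compliance, a 500-subject seeded subsample for the
optimized fit (about 0.2 s per fit), 100-subject subsamples for the
closed-loop and scenario-ordering checks, and 20 random parameter draws for
the RK4 cross-check. These sizes make the whole suite run in a few minutes
while keeping subsampling error an order of magnitude below the tolerances
being asserted.

## Known limitations

- Lumped pressure waves lack reflection features; methods that depend on
  them (LV1's dicrotic notch) are structurally inapplicable to generated
  data and are exercised through their error paths.
- The diastolic-window methods assume the wave starts at the systolic foot,
  as all generated waves do; clinical waves should be rotated to the foot
  first (the alignment used by `rmse_waves`).
- Parameters are estimated independently, in one pass; interdependence
  (e.g. between R_T and P_out) is not exploited.
- The 1-D outlet construction ends at a validated parameter set; no 1-D
  hemodynamics solver is bundled.
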