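---
title: "Simulating and individualizing eculizumab dosing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and individualizing eculizumab dosing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecudose)
```

# The model

## Pharmacokinetics

Eculizumab, like many therapeutic monoclonal antibodies, is eliminated by
two parallel routes: non-specific proteolytic clearance, linear in
concentration, and binding to its target C5 followed by complex
internalization, which saturates. Both are captured by a one-compartment
model with parallel first-order and Michaelis–Menten elimination:

$$\frac{dA}{dt} = \mathrm{in}(t) - \frac{CL_{i,occ}}{V_i} A -
\frac{V_{max,i}\, C}{K_m + C}, \qquad C = A/V_i .$$

The population parameters (defaults of `pk_parameters()`) are:

| parameter | meaning | typical value (70 kg) | variability |
|---|---|---|---|
| CL | linear clearance | 0.163 L/day | IIV 43.4% CV, IOV 34.4% CV |
| V | volume of distribution | 6.42 L | IIV 37.1% CV |
| V~max~ | maximal saturable elimination rate | 29.6 mg/day | — |
| K~m~ | half-saturation concentration | 37.9 mg/L | — |

Residual (observation) error is proportional + additive for concentrations,
with an assay-specific proportional term (0.0247 for the Radboudumc ELISA,
0.248 for the Sanquin ELISA) and additive SD 4.33 mg/L. The proportional
terms are interpreted as **variances** (σ²), the usual convention in
nonlinear mixed-effects reports; `prop_err_is_variance = FALSE` switches to
the SD reading. K~m~ matters only between roughly 10 and 100 mg/L — at the
high concentrations maintained by label dosing the saturable route
contributes a nearly constant ~30 mg/day.

Body weight enters by fixed allometric scaling referenced to 70 kg:
exponent 0.75 on the clearance-like parameters (CL, V~max~) and 1.0 on V.
The study that estimated these parameters reports weight as a covariate on
CL and V but the functional form only in unpublished supplementary
material, so standard theory-based exponents are used; they are arguments
of `pk_parameters()` and alternates can be explored. Whether V~max~ should
scale with weight at all is genuinely open; scaling it like CL is the more
conservative choice for paediatric extrapolation.

Interindividual and interoccasion variability are multiplicative
lognormal: a CV of c% maps to $\omega = \sqrt{\ln(1 + (c/100)^2)}$
(`cv_to_omega()`), individual parameters are
$\theta_i = \theta_{typ}(w_i) e^{\eta_i}$, and the occasion-specific
clearance multiplier $e^{\kappa}$ is redrawn at every dose — an *occasion*
is a dosing interval, beginning at each administration. No correlations
between random effects are modelled (none are reported), and no IIV is
placed on V~max~, K~m~, I~max~ or the Hill coefficient.

## Pharmacodynamics

Classical complement pathway (CP) activity, in % of control sera, follows
an inhibitory sigmoid E~max~ model of free drug concentration:

$$E = Base_i \left(1 - \frac{I_{max} C^{\gamma}}{IC_{50,i}^{\gamma} +
C^{\gamma}}\right)$$

with Base = 100.7% (IIV 23%), I~max~ = 0.96, IC~50~ = 22.0 mg/L
(IIV 38.5%), γ = 5.42, and a proportional residual error (variance 0.089).
The Hill coefficient of 5.42 makes the curve steep: CP activity collapses
from near-baseline to near-maximal inhibition over roughly a two-fold
concentration range. Complete complement blockade is defined as CP < 10%;
inverting the model for the typical subject puts the crossing at
≈ 36.3 mg/L (`cp_threshold_conc()`, verified against a numerical root
solve in the tests). Because I~max~ < 1, subjects whose baseline exceeds
250% could never reach the target; with a 23% CV baseline this is
essentially impossible, but the inversion returns `Inf` for such cases
rather than extrapolating.

# The virtual population

The dosing simulations run on a cohort emulating the NHANES-derived
simulation population: 2000 subjects, ages 1–79, 48% female, median weight
61.6 kg (range 8.3–155.6), median height 159 cm. Only these printed
summaries are available, so `generate_cohort()` is a parametric emulator:

- **age**: a mixture of a paediatric stratum (uniform on 1–18 y, weight
  0.40) and an adult stratum (Beta(1, 1.5)-shaped on 18–79 y, front-heavy
  like a survey age pyramid), calibrated to the published median of
  24.8 y;
- **weight**: lognormal around sex- and age-conditional growth-curve
  medians (anchors at ages 1, 2, 5, 10, 15, 18, 30, 60, log-linear in
  between), CV 20% for adults and 15% for children, truncated to the
  printed range;
- **height**: lognormal (CV 4%) around growth-curve medians.

The emulator matches the printed *marginals*; it does not reproduce the
real cohort's joint age–weight–height structure, its oversampling design,
or the heavy right tail of US adult body weight (a truncated CV-20%
lognormal is lighter-tailed than NHANES adults). Endpoints driven by heavy
adults on flat milligram dosing — notably day-7 attainment under the label
regimen — are therefore expected to come out one or two percentage points
more optimistic than with the real cohort, and the maintenance-phase
attainment similarly. Passing tests on this cohort demonstrate fidelity of
the machinery to the stated summaries, not equivalence to the original
NHANES extract.

# Dosing strategies and simulation design

## Regimens

Three weight-banded tables are encoded (and transcribed as plain-text
fixtures that the tests compare cell-for-cell): the approved label
schedule (900 mg weekly ×4 then 1200 mg q2w for ≥40 kg, paediatric bands
down to 300 mg q3w at 5–10 kg), the single weight-based loading dose
(300–2400 mg on day 1, second dose day 15, label maintenance thereafter)
and the fixed 4-week-interval maintenance doses (900–3000 mg q4w). Band
edges are half-open, `[lo, hi)`, with "≥40 kg" including 40.0 exactly.
"Day d" of a table maps to t = d − 1 days, so day-7 endpoints are
evaluated at t = 6 days. Doses are instantaneous boluses by default: the
label's <1 h infusion time is negligible against 7–28-day intervals; a
zero-order infusion mode is retained for generality.

Costs count whole 300-mg vials at US$6523. Fixed regimens are annualized
fractionally, (365.25/interval) × vials-per-dose × $6523, for smooth
comparability across 14/21/28-day intervals (an integer mode exists); the
TDM strategy is costed from its realized dose events over the simulated
year.

## The trough-guided (TDM) policy

Before the 2nd and before the 3rd maintenance dose the trough is measured
and the regimen adjusted: below 100 mg/L (2nd) or 50 mg/L (3rd) the dose
rises 300 mg; at or above 200 mg/L the interval extends 7 days; otherwise
nothing changes. Thresholds are half-open as printed; extensions compound
to a 28-day cap; after the 3rd dose the regimen is frozen. Troughs are
noise-free model predictions by default (`measure_with_error = TRUE`
applies the Radboudumc assay-error model instead).

## Maintenance studies start drug-free

The one genuinely contentious design choice is the state in which the
maintenance-phase studies (standard maintenance, TDM, 4-weekly) begin.
Simulated after the full induction phase, the typical 70-kg adult's
trough is ~280 mg/L at every maintenance dose — the accumulation implied
by the PK parameters — and nearly every subject would hit the ≥200 mg/L
extension rule, which is inconsistent with the published outcome classes.
Simulated as a standalone maintenance course from a drug-free start
(first maintenance dose at t = 0), the typical checkpoint troughs are
~87 and ~146 mg/L and the second-checkpoint extension probability falls
where the published 3-week class sits. This package therefore simulates
maintenance strategies standalone over one year (t ∈ [0, 365.25 d], 0.1-d
grid), with the TDM checkpoints at the 2nd and 3rd doses of that course;
attainment is the time-averaged fraction of subjects with CP < 10%, and
4-weekly interval attainment is read 14/21/28 days after the last complete
interval's dose. The post-induction variant remains reachable by
constructing schedules with `standard_regimen()` and solving directly.

A related consequence: at the first checkpoint most simulated troughs sit
below 100 mg/L, so the dose-increase arm of the policy fires in roughly
two-thirds of subjects. The published results imply a first-checkpoint
trough median some 40% higher than any reading of the printed model
reproduces; the realized-cost and double-extension endpoints inherit that
discrepancy, and the package reports them as computed rather than
absorbing the difference into the generator.

## Attainment classification

Attainment uses error-free individual CP predictions. The smoothness of
published attainment curves and a 99.95% day-7 figure at n = 2000 imply
model-prediction-based classification; adding PD residual noise barely
moves the numbers anyway, because the steep Hill curve puts most subjects
far from the 10% boundary on either side.

# Numerical choices

The ODE core is an adaptive embedded Dormand–Prince 5(4) integrator
written in C++ (relative tolerance 10⁻⁸, absolute 10⁻¹⁰ mg), advancing
segment-by-segment between dose events; occasion-specific clearance takes
effect at each dose. It is cross-checked in the tests against the
linear-case closed form (<10⁻⁶ relative), an explicit-Euler reference at
dt = 10⁻⁴ day, and `deSolve::lsoda` on the nonlinear model. A compiled
integrator is what makes a 2000-subject year at a 0.1-day grid run in
seconds rather than hours; the grid itself (0.1 day) resolves the
fastest time scale in the system (the ~5%/day initial decline of a
loading dose) with ~3 significant digits of attainment timing.

Values stored at grid times that coincide with a dose are **pre-dose left
limits**, so troughs are read directly off the grid and 28-day windows
include the day-29 dose (t = 28) — reproducing the printed "five vs three
infusions" accounting for the first 28 days. Amounts are clamped at zero
(the model cannot go negative; the clamp guards floating-point wobble),
observed values after residual error are truncated at zero, and every
random stream derives from one master seed: subject i uses a
deterministically derived substream, stable under cohort reordering.
Streams discard eight warm-up draws after seeding — the first draw after
`set.seed()` is measurably biased across arithmetically related seeds.

## MAP estimation

Individual fits estimate η = (η~CL~, η~V~) — the two random effects the
population model supports — by minimizing the penalized weighted residual
sum of squares

$$\sum_j \frac{(y_j - \hat{y}_j(\eta))^2}{\hat{y}_j^2\sigma_p^2 +
\sigma_a^2} + \sum_k \frac{\eta_k^2}{\omega_k^2},$$

with the residual variances entering as *known weights*; the
log-determinant term of the full Gaussian likelihood is deliberately
omitted because, with a prediction-dependent variance, it rewards
shrinking predictions and visibly biases fits to noise-free data. Under a
flat prior and additive-only error the objective reduces to ordinary
weighted least squares (verified in the tests against a direct
least-squares fit). Optimization is L-BFGS-B on η with bounds ±4ω,
multi-started from 0 and ±1ω, objective tolerance ~10⁻⁸; interoccasion
variability is fixed at zero during fitting. Even noiseless data leave a
few percent of shrinkage toward the population value — the prior never
switches off — which `recover_population()` quantifies (bias, RMSE,
shrinkage) under rich and trough-only designs.

## Method comparison

`passing_bablok()` implements the original rank-based procedure: slopes of
all C(n,2) point pairs, slopes of exactly −1 discarded, the median index
offset by the count of slopes below −1 (making the fit invariant to
swapping the methods), distribution-free confidence intervals from the
same ranking, and intercept = median(y − b·x). The tests pin it to an
independently coded brute-force oracle. `bland_altman()` is the standard
bias ± 1.96·SD of differences. The fixed CP-scale conversion
(`convert_cp_inhouse_to_wieslab()`) inverts the published cross-validation
line CP~in-house~ = 6.33 + 1.05·CP~Wieslab~, clipping negative results at
zero.

# Problem sizes

The shipped tests exercise the full 2000-subject cohort for the headline
endpoints (about two minutes of integration in total) and smaller cohorts
(8–60 subjects) for behavioural properties; random-effect calibration uses
10⁵ draws, where the Monte Carlo standard error of a sample CV is ~0.4%
relative, so calibration is asserted at 1.5% (≈4 SE) to be seed-robust.
`recover_population()` defaults to 50 subjects, well under a minute.

# Known limitations

- The cohort emulator matches printed marginals only (see above); endpoint
  sensitivity to the adult weight tail is the main consequence.
- The maintenance-phase simulation design (drug-free start, checkpoint
  indexing) is reconstructed from results, not from a published protocol;
  endpoints tied to the first-checkpoint trough distribution (dose-increase
  fraction, double extensions, realized TDM cost) are the least certain.
- C5 turnover is not modelled mechanistically: the PD link is static, so
  transient target-pool changes (infection, proteinuria) appear only
  through interoccasion variability on clearance.
- Population parameters are taken as given; re-estimating them from
  patient data is out of scope, as are multi-compartment disposition and
  non-drug (administration) costs.
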