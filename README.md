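# ecudose

Population pharmacokinetic–pharmacodynamic (PK–PD) simulation of
**eculizumab** dosing in atypical haemolytic uraemic syndrome (aHUS), for
clinical pharmacologists and PK modellers who want to compare dosing
strategies in silico or individualize doses from trough measurements.

Eculizumab is an anti-C5 monoclonal antibody. Its disposition is described
here by a one-compartment model with parallel first-order and
Michaelis–Menten (target-mediated) elimination,

$$\frac{dA}{dt} = \mathrm{in}(t) - \frac{CL}{V}\,A - \frac{V_{max}\,C}{K_m + C}, \qquad C = A/V,$$

with population values (70-kg reference) CL = 0.163 L/day, V = 6.42 L,
V<sub>max</sub> = 29.6 mg/day, K<sub>m</sub> = 37.9 mg/L, allometric weight
scaling (exponent 0.75 on CL and V<sub>max</sub>, 1 on V), lognormal
interindividual variability (CL 43.4%, V 37.1% CV), interoccasion
variability on CL (34.4% CV) and combined proportional + additive residual
error. The pharmacodynamic readout, classical complement pathway (CP)
activity, follows an inhibitory sigmoid E<sub>max</sub> model

$$E = Base\left(1 - \frac{I_{max}\,C^{\gamma}}{IC_{50}^{\gamma} + C^{\gamma}}\right)$$

with Base = 100.7%, I<sub>max</sub> = 0.96, IC<sub>50</sub> = 22.0 mg/L and
γ = 5.42. CP activity **< 10%** defines complete complement blockade, the
efficacy target; for the typical subject the corresponding concentration
threshold is ≈ 36.3 mg/L.

On top of the model the package provides:

- a **virtual population generator** emulating the NHANES-derived
  simulation cohort (2000 subjects, ages 1–79, 48% female, median weight
  61.6 kg);
- **weight-banded regimens**: the approved label schedule, a single
  weight-based loading dose, and a fixed 4-week-interval regimen;
- a **trough-guided TDM policy** (dose +300 mg below 100/50 mg/L; interval
  +1 week at ≥200 mg/L, checked before the 2nd and 3rd maintenance doses);
- a **Monte Carlo trial engine** computing attainment curves,
  interval-extension fractions, trough-band fractions and vial-based drug
  costs (US$6523 per 300-mg vial);
- **MAP estimation** of individual CL and V from sparse levels, the
  primitive for model-informed precision dosing;
- **Passing–Bablok** and **Bland–Altman** method-comparison statistics and
  the fixed CP assay-scale conversion.

## Worked example

```r
library(ecudose)

cohort <- generate_cohort(500, seed = 42)
trial  <- run_trial(trial_spec(cohort, "alt_loading", seed = 42))
trial
#> <virtual eculizumab trial: strategy 'alt_loading' (loading phase), n = 500>
#>   mean fraction of time with CP < 10%: 0.993
#>   mean cost (first 28 days): $76 006
attainment_at(trial, 6)   # day-7 target attainment
#> [1] 0.998
```

99.8% of this 500-subject cohort reach complete complement blockade on
day 7 (t = 6 days) under the single weight-based loading dose, at a mean
drug cost of $76,006 for the first 28 days; `autoplot(trial)` draws the
attainment curve. Individual dose forecasting from two observed troughs:

```r
fit <- map_fit(data.frame(time = c(14, 28), conc = c(95, 160)),
               data.frame(time = c(0, 14), amount = 1200), weight = 82)
fit
#> <MAP individual fit (2 observations)>
#>   eta_CL -0.2720, eta_V -0.1948 -> CL 0.1398 L/day, V 6.19 L
forecast_profile(fit, times = seq(14, 42, 7))
```

The subject clears eculizumab ~14% slower than a typical 82-kg adult
(CL 0.140 vs 0.163 × (82/70)^0.75 L/day); the forecast gives the expected
trough and CP activity at upcoming doses. Assay cross-validation:

```r
passing_bablok(x = method_a, y = method_b)
#> <Passing-Bablok regression, n = 8>
#>   slope 0.995 (95% CI 0.9364 to 1.085)
#>   intercept 12.57 (95% CI 0.717 to 20.58)
```

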