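# trastupk

Population pharmacokinetics and exposure–response analysis for trastuzumab
given either as a fixed 600 mg subcutaneous (SC) dose or as weight-based
intravenous (IV) infusions, in the setting of HER2-positive early breast
cancer. The package is aimed at pharmacometricians who want a tested,
self-contained implementation of the published SC/IV population-PK model —
for regimen simulation, for re-estimation on event-record data, and for
methodological work on covariate selection and predictive checking — without
needing NONMEM.

## The model

Serum trastuzumab follows a two-compartment model with parallel linear and
saturable (Michaelis–Menten) elimination from the central compartment and
first-order absorption from a subcutaneous depot:

```
dA_d/dt = −Ka · A_d
dA_c/dt = Ka · A_d + R(t) − (CL/Vc) · A_c − Vmax · C/(Km + C)
          − (Q/Vc) · A_c + (Q/Vp) · A_p
dA_p/dt = (Q/Vc) · A_c − (Q/Vp) · A_p,     C = A_c/Vc
```

where `R(t)` is the IV infusion rate and SC doses enter the depot as
`F · dose`. The saturable pathway reflects target-mediated drug disposition:
total clearance `CL + Vmax/(Km + C)` falls from about 0.24 L/day at trough to
0.17 L/day at peak concentrations. The shipped final model
(`reference_model()`) carries the published typical values (F = 0.771,
Ka = 0.404/day, CL = 0.111 L/day, Vmax = 11.9 mg/day, Km = 33.9 mg/L,
Vc = 2.91 L, Q = 0.445 L/day, Vp = 3.06 L), power-law covariate effects of
body weight on CL, Vc and Vp and of ALT on CL
(`CL_i = 0.111 · (WT/68)^1.04 · (ALT/19)^0.144`), log-normal between-subject
variability on F, CL, Vc and Vp, and a combined proportional (23.9 %) plus
additive (4.48 µg/mL) residual error.

Estimation uses a first-order conditional (FOCE-with-interaction)
approximate marginal likelihood with analytic ODE sensitivities, two-step
covariate selection (univariate screening at p < 0.01, backward elimination
at p < 0.001), a stratified nonparametric bootstrap, weighted-residual
(WRES/CWRES) outlier screening, and visual/numerical predictive checks.
Exposure–response uses multiple logistic regression of pathologic complete
response on the steady-state trough and of grade ≥3 adverse events on the
steady-state AUC, with body weight, arm, and arm interactions.

## Worked example

```r
library(trastupk)
model   <- reference_model()
patient <- individual_covariates(weight = 68, alt = 19)
params  <- apply_covariates(model, patient)

total_clearance(params, c(75, 148))
#> [1] 0.2202746 0.1764206

exposure_metrics(params, regimen_sc_600_q3w(20))
#> Steady-state exposure: Cmin 75.0 ug/mL, Cmax 148.8 ug/mL (tmax 3.5 d),
#>   AUC 2337 ug*day/mL, 90% of steady state by day 126
exposure_metrics(params, regimen_iv_8_6_q3w(68, 20))
#> Steady-state exposure: Cmin 56.7 ug/mL, Cmax 182.3 ug/mL (tmax 0.5 d),
#>   AUC 1994 ug*day/mL, 90% of steady state by day 105
```

Total clearance at the SC trough/peak (75/148 µg/mL) is 0.22/0.18 L/day —
the concentration dependence of the saturable pathway. The fixed SC dose
gives a higher steady-state trough (75 vs 57 µg/mL) and a lower peak than
the weight-based IV regimen, with similar 3-week AUC; the SC trough reaches
90 % of its plateau by day 126 (cycle 6).

A synthetic trial exercises the whole pipeline without patient data:

```r
trial <- generate_trial(model, trial_design(n_subjects = 60, seed = 1))
trial
#> Event dataset: 60 subjects, 780 dose records, 1799 observations in the
#>   analysis set (1 below LLOQ 0.156 mg/L excluded)

fit_logistic(er_records(trial), outcome = "pcr", exposure = "cmin_ss")
#> Logistic exposure-response model: pcr ~ (cmin_ss + weight) * arm
#>            term estimate     se     z     p
#> 1   (Intercept) -0.83570 2.5000 -0.33 0.738
#> 2       cmin_ss -0.02716 0.0249 -1.09 0.275
#> ...
```

Under the default (null) outcome model no exposure term is significant —
the qualitative conclusion supporting fixed SC dosing. Model fitting,
covariate search, bootstrap and predictive checks follow the same pattern;
see `?fit_poppk`, `?covariate_search`, `?predictive_check` and the methods
vignette (`vignettes/trastupk-methods.Rmd`).

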