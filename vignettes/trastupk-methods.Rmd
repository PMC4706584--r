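---
title: "Methods: population PK and exposure-response of SC/IV trastuzumab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK and exposure-response of SC/IV trastuzumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trastupk)
```

## The structural and statistical model

Trastuzumab serum kinetics are described by a two-compartment disposition
model with two parallel elimination pathways from the central compartment: a
linear pathway with clearance `CL_lin` and a saturable Michaelis-Menten
pathway `Vmax * C / (Km + C)` that represents target-mediated disposition
(binding to shed and membrane HER2). Subcutaneous doses pass through a
first-order absorption depot with rate constant `Ka` and bioavailability
`F`; intravenous doses are zero-order infusions into the central
compartment. Units are fixed throughout: amounts in mg, volumes in L, time
in days, concentrations in mg/L (numerically identical to ug/mL). Infusion
durations quoted in minutes are converted exactly (90 min = 0.0625 day).

The shipped final model (`reference_model()`) is read from a plain-text
configuration and carries:

* typical values `F` 0.771, `Ka` 0.404 /day, `CL_lin` 0.111 L/day, `Vmax`
  11.9 mg/day, `Km` 33.9 mg/L, `Vc` 2.91 L, `Q` 0.445 L/day, `Vp` 3.06 L;
* power-law covariate effects
  `CL_i = 0.111 (WT/68)^1.04 (ALT/19)^0.144`,
  `Vc_i = 2.91 (WT/68)^0.443`, `Vp_i = 3.06 (WT/68)^0.500`
  (body weight in kg, ALT in IU/L, references 68 kg and 19 IU/L);
  categorical covariates would enter as `exp(k * x)`;
* log-normal between-subject variability on `F`, `CL_lin`, `Vc`, `Vp` with
  standard deviations 0.130, 0.300, 0.191, 0.504 on the log scale;
* a combined residual error `sd = sqrt(0.239^2 pred^2 + 4.48^2)` ug/mL.

Two conventions in the variability block deserve comment. First, published
CV percentages are interpreted as `100 * omega` (the small-omega
convention); the variance-explained arithmetic on CV pairs (31.3 to 30.0
percent giving 8 percent for clearance) is consistent only with this
reading, so it is the default, with the log-normal alternative
`100 * sqrt(exp(omega^2) - 1)` available through `cv_convention`. Second,
bioavailability is a fraction: a log-normal draw at `omega_F = 0.13` exceeds
`F = 1/0.771` for roughly 2 percent of subjects. Sampling
(`draw_eta()`) rejects and redraws those; the deterministic
`realize_individual()` truncates at 1. A logit-normal model was considered
and rejected: it changes the meaning of the published omega and the mass
above 1 is small.

## Regimen simulation and steady-state conventions

The named regimens are the fixed 600 mg SC dose every 21 days (the 5-minute
manual injection is treated as an instantaneous depot bolus - absorption,
with a 1.7-day half-life, is rate-limiting), the IV 8 mg/kg loading /
6 mg/kg q3w maintenance regimen (90- then 30-minute infusions), and the IV
4/2 mg/kg weekly regimen. The solver is a compiled adaptive Dormand-Prince
RK45 with exact event handling (integration restarts at every dose time and
infusion boundary); the exported `pk_rhs()` allows any external integrator,
and the test suite cross-checks the compiled solver against deSolve's lsoda
to about 1e-10 relative error.

Steady-state metrics are reported on the cycle-7 window, days 126-147 after
the first dose, matching the published seven-cycle simulation; weekly
regimens use the same 21-day window, with the trough taken as the
end-of-window pre-dose value. The cycle-7 trough still sits 3-5 percent
below the day-420 asymptote (the nonlinear pathway makes troughs approach
steady state slowly), so `exposure_metrics()` carries a convergence check
that warns when the window trough differs from the day-420 trough by more
than 2 percent - with these parameters the warning fires by design and
records the convention ambiguity rather than an error.

The reported peak concentration is read from the profile sampled on a
half-day reporting grid. This is a deliberate convention choice: for the
30-minute IV infusion the concentration falls by more than 1 ug/mL per hour
after the end of the infusion, so the "peak" depends strongly on when one
looks. The half-day grid reproduces the reference peak values for all three
regimens simultaneously (IV q3w 182, IV qw 116, SC 149 ug/mL); the exact
refined end-of-infusion maximum (about 7 percent higher for the q3w IV
regimen) is available via `peak = "exact"`. For the slowly absorbed SC dose
the two conventions agree to well under 1 percent.

The time to 90 percent of steady state compares end-of-cycle troughs with
the day-420 trough and reports the first cycle reaching 90 percent of it,
in days (126 for SC, 105 for IV at the reference covariates).

## Estimation

`ofv_focei()` implements the first-order conditional approximation with
interaction: for each subject the conditional mode of the random effects is
located, the model is linearized there, and the subject's contribution is
the Gaussian -2 log-likelihood under `V = G Omega G' + diag(sigma^2(f))`
with the residual variance evaluated at the conditional predictions. The
objective is exact for models linear in the random effects, which the test
suite exploits twice: a closed-form linear-mixed-model oracle and a direct
numerical-quadrature oracle for a nonlinear toy model (agreement within 0.1
OFV units). A plain-R engine (`ofv_focei_generic()`) accepts arbitrary
prediction functions and doubles as the reference implementation against
which the compiled engine is verified on PK data.

The inner optimization integrates analytic forward sensitivities of the ODE
system with respect to the active random effects (the base three states are
augmented with one 3-state block per active effect), so a single adaptive
integration yields both predictions and the exact linearization Jacobian;
a damped Gauss-Newton iteration with the Fisher information of the
heteroscedastic Gaussian (mean and variance terms) then converges in a few
steps to an inner gradient tolerance of 1e-6. Subjects without SC doses
carry no information on bioavailability, so their `eta_F` stays at its
conditional mode of zero. The search is clamped to +/-6 log-units - far
outside any plausible individual - because more extreme values only make the
system needlessly stiff.

The outer problem (`fit_poppk()`) estimates positive-scale parameters on
the log scale and covariate coefficients unconstrained, by BFGS with
finite-difference gradients (relative step 1e-4). Conditional modes are
carried between outer iterations as warm starts, updated only at the best
objective seen so far to keep finite-difference gradients path-independent.
Standard errors come from a finite-difference Hessian at the optimum,
transformed to the natural scale, or from the bootstrap
(`bootstrap_poppk()`, resampling subjects with replacement within treatment
arm). Observations below the 0.156 ug/mL quantification limit are flagged
and excluded from the likelihood - a censored-data likelihood is not
warranted for a multiple-dose design whose concentrations sit orders of
magnitude above the limit.

Covariate selection (`covariate_search()`) follows the two-step procedure:
univariate screening against the base model keeps candidates with a
chi-square(1) p below 0.01 (delta OFV 6.63); backward elimination from the
full model then removes the least significant candidate until every
survivor is below 0.001 (delta OFV 10.83). Every fitted submodel is cached
by its candidate subset, so the elimination step never refits a model the
screening step already produced.

## Diagnostics

`compute_residuals()` reports WRES (first-order linearization at eta = 0)
and CWRES (linearization at the conditional modes) side by side - the
published screening rule mentions both, and which linearization the original
software used is version-dependent - plus IWRES. Both are decorrelated by
the Cholesky factor of the model-implied marginal covariance. Outlier
screening (`flag_outliers()`) uses an initial model with the saturable
pathway removed (`Vmax = 0`), flags absolute WRES or CWRES above 3, removes
the flagged observations, and excludes any subject with more than ten
flagged samples. Two properties of this rule are worth knowing. On clean
self-simulated data the flagged fraction exceeds the nominal two-sided
normal tail (0.27 percent) by a factor of 2-4: the linearization of strongly
skewed log-normal effects (omega_Vp = 0.504) has genuinely heavier tails,
and the screening model is deliberately misspecified. And a subject whose
troughs and peaks are swapped every cycle is only partially flagged: a
coherent swap mimics a plausible low-clearance individual, so the marginal
covariance absorbs part of the error. The per-subject exclusion rule
therefore fires reliably for gross corruption but sits near its threshold
for the pure swap artifact.

`predictive_check()` simulates replicate datasets at the observed design
(same subjects, covariates, doses and nominal sampling times - the time
bins are the nominal times, because the design is nominal-time), and
reports observed 5/50/95 percentiles per stratum and bin against the
simulated percentile bands, plus a numerical check: the fraction of
observations below the 5/25/50/75/95 percentiles of each bin's predictive
distribution, flagged when more than 10 points from nominal.

## The synthetic trial generator

`generate_trial()` emulates the phase III SC-versus-IV design so that every
pipeline stage is testable without patient data: about 595 subjects
randomized 1:1; SC arm with fixed 600 mg q3w doses and trough sampling;
IV arm with weight-based 8/6 mg/kg infusions, trough and end-of-infusion
peak sampling; 13 sampled cycles with richer profiles around cycles 7 and
12. The rich post-dose times default to {4 h, 1, 2, 4, 7, 14 d}, trimmed so
the planned per-subject totals are exactly 24 (SC) and 36 (IV) - the
published totals are the binding constraint, the exact rich times are not
public. Body weight is log-normal with median 68 kg and log-scale SD 0.20,
chosen once so the empirical quartile breaks land near the published
58/68/79 kg; ALT is log-normal with median 19 IU/L and log-scale SD 0.50, a
typical right-skewed spread for a liver enzyme in this population (the
analysis only uses ALT through a weak power effect, so this choice is not
load-bearing). The assay limit is 0.156 ug/mL; values below it are flagged,
never fabricated. A configurable fraction of IV-arm subjects has trough and
peak values swapped each cycle - the gross-error artifact the screening rule
is designed for - and covariate missingness can be injected to exercise the
median/reference imputation rule (which refuses above 10 percent
missingness). Binary outcomes are drawn from a logistic model whose default
is null (no exposure, weight or arm effect) with intercepts giving the
observed base rates, about 43 percent pathologic complete response and 53
percent grade >=3 adverse events.

What the generator does not emulate: concomitant chemotherapy phases,
immunogenicity dynamics, dropout, inter-occasion variability, or the true
(unpublished) joint covariate distribution. Passing tests therefore
demonstrate internal consistency of the methods under the stated design,
not agreement with the original patient-level data.

## Numerical choices and problem sizes

* Solver: RK45 with relative tolerance 1e-10 (simulation) or 1e-8 to 1e-6
  (estimation), absolute tolerance 1e-8 mg; step counts capped at 2e4 per
  segment so that absurd parameter proposals fail fast instead of grinding.
* The outer objective returns a large penalty outside a 5-log-unit box
  around the starting values.
* Quantile rule everywhere: linear interpolation between order statistics
  (R type 7). Quartile bins are half-open, lower bound inclusive, matching
  the published ">= a, < b" table convention.
* Likelihood-ratio tests use 1 df per covariate coefficient.
* Test and validation problem sizes are chosen to make the checks sharp but
  quick on a single core: parameter recovery on a 150-subject generated
  trial (estimates of CL and Vc within a few percent of the generating
  values), covariate selection on 150 subjects with a true weight effect
  and a pure-noise marker (delta OFV near 60 versus under 1), a
  100-replicate bootstrap on a reduced 24-subject design, 100-200-replicate
  predictive checks, and 200-replicate null coverage for the
  exposure-response model.

## Limitations

The estimation engine implements one estimator (linearized FOCE with
interaction); SAEM or importance sampling are out of scope, as are
off-diagonal random-effect covariances and inter-occasion variability.
Standard errors from the finite-difference Hessian inherit the usual
fragility of that approach near flat directions - the bootstrap is the
robust alternative. Reported shrinkage and relative standard errors depend
on the (unavailable) original dataset and are not reproduced as fixed
numbers anywhere in the package.
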