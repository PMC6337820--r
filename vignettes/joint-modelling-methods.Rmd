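---
title: "Joint modelling of survival and a bone-turnover biomarker: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of survival and a bone-turnover biomarker: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bonejm` analyses cohorts of bone-metastatic cancer patients in which a
bone-resorption biomarker (such as urinary NTX, in nmol BCE/mmol
creatinine) is measured on a short fixed schedule — months 0, 1, 3, 6, 9
and 12 after the start of bone-targeted treatment — while patients are
followed for survival over a longer horizon. The scientific question is
whether the *current level* of the biomarker trajectory carries prognostic
information beyond baseline covariates, and how the answer depends on how
missing biomarker visits are handled and how the trajectory is modelled.

## The models

**Longitudinal sub-model.** The log-biomarker of patient $i$ follows a
linear mixed-effects model
$$y_i(t) = x_i^T(t)\,\beta + z_i^T(t)\,b_i + \varepsilon_i(t), \qquad
b_i \sim N(0, D),\ \varepsilon_i(t) \sim N(0, \sigma^2),$$
with the *shared-basis convention* $z_i(t) = x_i(t)$: every fixed effect
has a patient-level random counterpart, giving each patient a fully
flexible deviation from the population curve. Three mean structures are
supported, all on the natural-log scale of the biomarker:

| kind | basis $x(t)$ | tuning |
|------|--------------|--------|
| rational | $(1,\ (t+\delta)^{-\eta})$ | $\delta>0,\ \eta>0$ |
| exponential | $(1,\ e^{-\delta t})$ | $\delta>0$ |
| natural cubic spline | intercept + $k{+}1$ natural-spline functions | knots |

The natural cubic spline uses $k = 2$ interior knots. Knot locations are
not part of the mean-structure definition here; the default places them at
months 1 and 6 — the 33rd/67th percentiles of the default measurement
schedule — with boundary knots at months 0 and 12, so the basis dimension
is 4. The spline is linear beyond the boundary knots, which is also how it
extrapolates when the survival follow-up extends past the last scheduled
measurement.

The nonlinear tuning parameters $\delta$ (and $\eta$) are profiled:
`profile_tuning()` maximizes the `fit_lme()` marginal log-likelihood over
a log-spaced grid on $[10^{-2}, 10^2]$ and refines the winner with a
bounded local search, breaking ties toward the smaller $\delta$. The
one-parameter exponential profile uses 25 grid points; the two-parameter
rational profile uses a 13-point-per-parameter grid. A denser 25×25
rational grid was tried and selects the same refined optimum while costing
an order of magnitude more likelihood fits — the local search, not the
grid density, determines the final value, so the coarser grid is the
package default. A profile that is flat to within $10^{-4}$ across the
whole grid (slope-free data) is reported with the boundary flag and
$\delta$ at the lower bound.

`fit_lme()` maximizes the exact marginal Gaussian likelihood by
quasi-Newton iterations on the Cholesky factor of $D$ (log diagonal) and
$\log\sigma$, with $\beta$ profiled out by generalized least squares and
an analytic gradient obtained from the envelope theorem. Estimation is
plain maximum likelihood, not REML, because the joint model below needs
ML-comparable log-likelihoods and uses these fits as starting values.
Patients sharing a measurement-time pattern share the marginal covariance
$X D X^T + \sigma^2 I$, so the likelihood collapses to a handful of small
matrix operations per pattern.

**Survival sub-models.** Static covariates (age at diagnosis, sex,
extra-skeletal metastases) are screened by log-rank tests (categorical)
and univariate Cox Wald tests (continuous), then combined in multivariate
Cox models, one per biomarker snapshot variant (the raw and log month-3
and month-12 values, and the clinical elevation indicators raw value
$>100$ at month 3 and $>64$ at month 12). The extended Cox model treats
the measured log-biomarker as a step function with jumps at the
measurement times, on counting-process intervals $(t_r, t_{r+1}]$ — a row
is at risk for an event at $t$ iff $\text{start} < t \le \text{stop}$. The
left-open convention matters: it makes the fit provably identical whether
missing visits are omitted or carried forward, because both produce the
same step-function path. Ties are handled by the Efron correction.

**Joint model.** The shared-parameter model links the two processes
through the *current true level* $m_i(t) = x_i^T(t)(\beta + b_i)$:
$$h_i(t) = h_0(t)\,\exp\{\gamma^T w_i + \alpha\, m_i(t)\},$$
with a piecewise-constant baseline hazard $h_0$. Only the current-value
parameterization is implemented (no slope or cumulative association). The
marginal likelihood integrates, per patient, the longitudinal density, the
survival density and the random-effects prior over $b_i$.

## Numerical strategy

* **Outer integral** (over $b_i$): adaptive Gauss–Hermite quadrature,
  centered and scaled at the per-patient posterior mode and curvature,
  with 9 nodes per dimension for the two-dimensional parametric bases and
  5 nodes per dimension for the four-dimensional spline basis. A
  stability check in the test suite verifies that moving from 9 to 15
  nodes changes the likelihood by less than $10^{-4}$.
* **Inner integral** (cumulative hazard): 15-point Gauss–Legendre per
  baseline-hazard piece, exact to high order for the smooth
  $\exp\{\alpha m_i(s)\}$ integrand. The synthetic-data generator uses the
  same rule through an independent code path, and the two are tested
  against brute-force trapezoid integration rather than against each
  other.
* **Baseline hazard**: 6 intervals with bounds at the observed event-time
  sextiles, so each piece sees a comparable number of events. An event
  falling exactly on an interval bound belongs to the interval *ending*
  there, matching the counting-process convention of the piecewise
  exponential initializer.
* **Optimization**: L-BFGS-B on transformed parameters ($\beta$, $\alpha$,
  $\gamma$, log hazard heights, $\log\sigma$, Cholesky factor of $D$ with
  log diagonal), initialized from the separate `fit_lme()` and a
  piecewise-exponential fit with $\alpha = 0$. The quadrature rule is
  frozen during each inner optimization and re-centered between them;
  convergence is declared when the re-adapted log-likelihood changes by
  less than $10^{-7}$ in relative terms. Hazard covariates are
  standardized internally (and estimates mapped back exactly) because raw
  age on a scale of ~60 years otherwise dominates the curvature and slows
  the quasi-Newton iterations severely. Box bounds keep the variance
  parameters away from the degenerate boundary during line searches.
* **Standard errors**: central finite differences of the analytic
  gradient at the optimum (step $10^{-4}$ on the transformed scale),
  inverted to a covariance matrix; Wald tests are two-sided normal with
  significance flagged at 5%. If the Hessian is singular, standard errors
  are reported as missing rather than fabricated.
* **Degenerate inputs**: patients with zero longitudinal records (possible
  under omission) contribute a survival-only likelihood with $m_i(t)$
  integrated over the random-effects prior; a cluster that loses all
  membership weight keeps its previous prototype; an exactly-zero
  clustering distance assigns full membership to the first such cluster.

## Missing-data strategies

The biomarker grid (patients × schedule) supports three strategies,
applied upstream of the survival/joint models:

* **Omission** — use the observed rows as they are; the mixed model
  tolerates unbalanced designs natively.
* **LOCF** — each missing entry takes the most recent earlier observation;
  entries before a patient's first observation remain missing.
* **FSTS + OCS** — fuzzy c-means on the *slope representation* of the
  series: the distance between two series is the Euclidean distance
  between their segment-slope vectors, so level shifts are invisible and
  the clustering groups patients by trajectory *shape*. Defaults are
  $c = 6$ clusters and fuzzifier $m = 1.3$. The optimal completion
  strategy treats missing entries as free variables of the clustering
  objective; each cycle updates memberships, prototypes, and the missing
  values by exact coordinate minimization (a small linear solve per
  patient), which guarantees a monotone non-increasing objective.

Two design choices here were genuinely open. First, the slope distance is
invariant to vertical shifts, so prototypes are only determined up to a
level; each prototype is anchored so its mean level equals the
membership-weighted mean level of its series, which keeps prototypes and
imputed values on the data's scale. Second, initialization uses a
deterministic farthest-point traversal on slope vectors with canonical
(lexicographic) tie-breaks instead of a random seeding — this makes the
whole procedure exactly invariant to patient ordering, which is asserted
as a property test.

## The synthetic cohort generator

No clinical data ships with the package; `simulate_cohort()` generates
cohorts with the structure the analysis assumes, with known truth, so
every stage is testable end to end. The generator emulates:

* the measurement schedule 0, 1, 3, 6, 9, 12 months;
* right-skewed, strictly positive biomarker values, simulated and
  modelled on the natural-log scale (raw values are `exp(y)`);
* a decaying population trajectory under bone-targeted treatment
  (default: exponential, $\beta = (3.4, 1.0)$, $\delta = 0.35$/month,
  i.e. raw levels falling from ≈ 80 to ≈ 30 nmol BCE/mmol creatinine),
  with random intercept and decay-amplitude effects
  ($D = [[0.25, 0.05], [0.05, 0.16]]$) and residual SD $\sigma = 0.35$;
* event times drawn by inverse-transform sampling from the
  biomarker-dependent hazard itself ($\alpha = 0.2$ per log unit,
  $\gamma = (0.02/\text{yr}, 0.3, 0.7)$, piecewise-constant baseline
  around 0.004–0.005 events/month), solved by bisection on a
  Gauss–Legendre cumulative hazard to $10^{-10}$ months, with a search
  horizon of ten times the censoring time;
* administrative censoring at 36 months — the cohort design does not
  state a censoring distribution, so a fixed horizon is assumed — giving
  roughly 60–70% events;
* monotone dropout of the biomarker series (per-visit probability 0.15,
  baseline never dropped) plus occasional isolated missing visits
  (probability 0.05). Together with death-truncation this reproduces the
  qualitative attrition of such cohorts, where under a quarter of
  patients still contribute a month-12 measurement.

These defaults are the package's definition of a realistic cohort of this
kind and are used unchanged by the tests and the acceptance script. What
the generator deliberately does **not** emulate: multiple primary-cancer
strata with different trajectory families, competing risks, and
outcome-dependent (informative) missingness. Passing tests therefore show
that the estimators recover the truth under the stated data-generating
mechanism — not that real cohorts satisfy that mechanism.

## Problem sizes used by the test suite

The test suite chooses sizes that make its statistical assertions sharp
but keep a full run on one CPU modest: likelihood-oracle checks on 2–3
patients against dense-grid integration; parameter recovery on ten cohorts
of 300 patients (each estimate within three standard errors of truth);
Wald-test calibration of the association on 200 null cohorts of 200
patients; the attenuation comparison on 50 cohorts of 150 patients; the
full 3-imputation × 3-basis grid on one 120-patient cohort; and
mask-and-recover imputation on 20 replicates of 60 smooth series with 20%
of entries hidden.

## Known limitations

* Estimation is direct quasi-Newton maximization; an EM algorithm is not
  implemented.
* Bayesian/MCMC estimation, dynamic subject-specific prediction,
  multivariate longitudinal outcomes, and Weibull or B-spline baseline
  hazards are out of scope; the piecewise-constant baseline is the one
  option provided.
* The longitudinal sub-model is a function of time only (no longitudinal
  fixed-effect covariates) and assumes independent residuals.
* Standard errors for the elements of $D$ are not reported; the Wald
  table covers the fixed effects, the hazard covariates and the
  association.
* The association uses the current-value parameterization only; slope or
  cumulative-effect links would require new basis derivative code.
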