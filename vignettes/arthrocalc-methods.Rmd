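---
title: "Models and methods behind arthrocalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arthrocalc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arthrocalc)
```

arthrocalc is the computational engine of a decision-support tool for
patients considering hip or knee replacement. Given a patient's biometrics
(age, sex, BMI, ASA grade), their pre-operative outcome score, and the
planned surgery group, it predicts three quantities: the expected
post-operative patient-reported outcome measure (PROM) score, the risk of
death within the years after surgery, and the risk of revision surgery.
This vignette describes the models, the numerical choices, and what the
synthetic cohorts used for testing do and do not establish.

## The survival model

Mortality and revision are each modelled cause-specifically with a
flexible parametric proportional-hazards model. The cumulative hazard for
covariates $x$ at time $t$ (years since surgery) is

$$\Lambda(x, t) = \Lambda_0(t)\, e^{\beta x},$$

and the baseline is represented through a natural cubic spline in log
time, $y = \log t$:

$$s(y) = \gamma_0 + \gamma_1 y + \sum_{j=1}^{m} \gamma_{j+1} \nu_j(y),$$

where the $\nu_j$ are restricted cubic basis functions: piecewise cubic
between knots, with continuous second derivative at every knot, and
linear beyond the boundary knots. With $m = 0$ internal knots the model
reduces to a Weibull distribution, which anchors several exact checks in
the test suite.

### The scale convention

Two readings of the baseline are possible, and the package supports both:

* **log-cumulative-hazard scale** (the default):
  $\Lambda_0(t) = \exp s(\log t)$. This is the Royston–Parmar
  formulation. It is the only variant that is a valid probability model
  for arbitrary $\gamma$ (the baseline is always positive), so it is the
  default for fitting and for all bundled models.
* **additive scale**: $\Lambda_0(t) = s(\log t)$ literally. This variant
  cannot guarantee positivity or monotonicity and is provided behind the
  `scale` flag for fidelity experiments only; fitted models on this scale
  must pass the post-fit monotonicity check to be trusted.

### Knots

Knot placement is derived from the data alone: boundary knots at the
minimum and maximum of the observed log event times, internal knots at
the equally spaced quantiles between them. The internal knot count `m`
defaults to 2 — enough curvature for registry-scale baselines while
keeping $m + 2$ baseline parameters identifiable in modest cohorts — and
is configurable; no automatic selection by information criteria is
attempted. Inside cross-validation the knots are re-derived on each
training fold, so no information about held-out event times leaks into
the fit. Events falling exactly on a boundary knot are evaluated with the
same closed form as any other time point.

### Likelihood and optimisation

Under right censoring the log likelihood is
$\sum_i [d_i \log h(t_i|x_i) - \Lambda(x_i, t_i)]$ with
$h = d\Lambda/dt$ computed from the exact derivative of the spline basis.
Both events are continuous-time, so tied event times need no special
treatment. $\beta$ and $\gamma$ are maximised jointly by BFGS with the
analytic gradient. The start is deterministic: $\gamma$ from a least
squares fit of the log Nelson–Aalen cumulative hazard on the spline basis
at the event times, $\beta = 0$; identical data and settings therefore
reproduce identical parameters bit for bit. If BFGS reports
non-convergence or the relative gradient norm (gradient norm divided by
$|\ell|$) stays above $10^{-4}$, the search restarts once with
Nelder–Mead followed by a BFGS polish. A parameter point whose hazard is
non-positive at any event is assigned $-\infty$ likelihood; the gradient
near that boundary is evaluated with the hazard slope clamped at
$10^{-12}$ so the line search can retreat. After fitting, the baseline
cumulative hazard is verified to be non-decreasing on a 100-point grid
over the observed range; a violation (possible in principle on either
scale under extreme $\gamma$) raises a warning and is recorded on the
fit object.

Death and revision are competing events. Each model is cause-specific:
when fitting one event, records where only the other occurred are
censored at that time (`recode_competing_event()`), never inside the
likelihood. The reported ten-year revision risk is therefore the
censoring-based quantity $1 - \exp(-\Lambda_{rev})$, not a
conditional-on-survival probability; under the independence assumption
already made by the censoring convention the two differ only through
mortality before revision.

## The PROM model

The post-operative score is a linear regression on the pre-operative
score, age, age squared, and any further covariates, fitted by ordinary
least squares. Two presentation choices:

* **Intercept**: included by default. A strictly interceptless score
  regression is almost certainly a notational elision rather than a
  substantive constraint, but `intercept = FALSE` preserves the literal
  reading.
* **Score range and rounding**: the instrument is treated as an opaque
  bounded integer score, default range 0–48 (the Oxford Hip/Knee Score
  scale), configurable per bundle. Predictions are rounded half-up —
  any deterministic rule would do; this one is least surprising when a
  score is displayed to a patient — then clamped to the range.

## Filters

Records with incomplete required fields, ASA outside {1, 2, 3}, age
outside [30, 100] years, or BMI outside [15, 55] kg/m² are excluded
before fitting. The bounds are read as closed intervals (a 30-year-old or
a BMI of exactly 55 is clinically valid and kept). When a record fails
several rules, the reason code reports the first failing rule in the
order completeness, ASA, age, BMI. Which fields count as "required" is
bundle metadata, since community and clinic models need different inputs;
the default list is the core biometrics plus the pre-operative score.

## The calculation pipeline

`calculate()` selects the (surgery group, model type, dataset version)
bundle — latest version by natural order when none is requested —
validates the request under exactly the filter rules above (a failing
request produces field-level errors and never a partial result), predicts
the PROM score, and evaluates both cumulative hazards at whole years 1–10,
converting each to a probability with $1 - e^{-\Lambda}$. Headline
figures are mortality within one year and revision within ten years.
Bundles serialise to JSON with 17 significant digits, which round-trips
IEEE doubles exactly — auditable coefficients matter in a clinical tool,
and bit-exact round trips make model provenance testable.

## Validation protocol

`repeated_cv()` implements 50 repetitions of 5-fold cross-validation:
fresh random partition each repetition, metrics computed on each held-out
fold, fold values averaged per repetition, and the 50 repetition means
summarised by their mean and a 95% confidence interval. The CI uses the
normal approximation $\bar{x} \pm 1.96\, s/\sqrt{R}$ across repetition
means (a percentile bootstrap is available via `ci_method`); repetition
means are near-Gaussian at these sizes, and the method is recorded in the
report so results are self-describing. The metrics are RMSE for the PROM
model and Harrell's concordance plus a fixed-horizon Brier score for the
survival models; concordance counts only usable pairs (the earlier time
is an event, times distinct) and scores ties as 0.5, and the Brier score
excludes records censored before the horizon, whose status is unknown. A
fold whose fit fails marks the repetition failed; more than 20% failed
repetitions aborts the run.

## The synthetic cohort generator

No registry or national PROM data are redistributable, so the package
ships a generator that emulates the *structure* the models assume:

* covariates drawn independently — age truncated normal (mean 68, SD 10)
  on [30, 100], resembling an arthroplasty population; BMI truncated
  normal (29, 5) on [15, 55]; ASA 1/2/3 with probabilities
  0.15/0.65/0.20; 60% female; surgery mix dominated by hip (43%) and
  total knee (51%) with small unicompartmental (5%) and patellofemoral
  (1%) shares, mirroring the relative volumes seen in joint-replacement
  registries;
* death and revision times drawn independently from true
  proportional-hazards models by inverse transform — solve
  $\Lambda(x, t) = -\log u$ for $t$, closed-form for Weibull baselines
  and monotone root-finding otherwise — with administrative censoring at
  12 years and min-time logic producing one observed follow-up time and
  both indicators;
* default true baselines sized for clinically plausible risks (about 1%
  mortality in year one, about 5% revision by year ten), with modest age
  and sex effects on the log-hazard scale;
* PROM outcomes from the quadratic-age linear model plus Gaussian noise
  (SD 4 score points), rounded and clamped.

Everything is reproducible from a single seed, with the generator's
sub-draws on separate derived seeds so covariates and event times share
no random stream.

What passing tests on these cohorts show: the estimator recovers the
parameters of its own generating model (including under 30% censoring),
the pipeline is internally consistent, and the validation harness
measures what it claims — the cross-validated concordance of a fitted
model agrees with the generating model's true concordance computed by
brute-force Monte Carlo. What they do not show: performance on real
registry data, where censoring can be informative, death and revision are
correlated through frailty, covariates are dependent, and proportional
hazards is at best an approximation. The generator deliberately matches
the model's own assumptions — independent competing processes rather than
correlated frailty — because its job is to verify the machinery, not to
rehearse model misspecification.

## Problem sizes and numerical tolerances

The test suite fits at $n$ between 500 and 5,000 (10 seeds for the
censored recovery check), runs the full 50×5 cross-validation protocol on
a 2,000-row cohort, and uses $10^5$–$10^6$ draws for distributional
oracles; these sizes give sampling error comfortably below the asserted
tolerances while keeping the whole suite under a minute. Key tolerances:
OLS against the normal equations at $10^{-8}$; spline second-derivative
continuity at $10^{-4}$ via one-sided finite differences of the exact
first derivative (step $10^{-6}$); closed-form pipeline risks at
$10^{-9}$; covariate recovery at $\pm 0.1$ per component, which is about
three standard errors at $n = 5{,}000$ with 70% events. The 30%-censoring
recovery condition is realised by a baseline rate of 0.12/year against
12-year administrative censoring, calibrated by forward simulation of the
generating model before any estimator ran.

## Known limitations

* Cause-specific censoring, not a subdistribution (Fine–Gray) model: the
  revision risk ignores the competing reduction from prior death.
* No uncertainty intervals on predictions; coefficient bundles carry
  point estimates only.
* No proportional-odds or time-varying-coefficient variants, no frailty,
  no interval censoring.
* The additive baseline scale is unpenalised and can produce invalid
  hazards; it exists for comparison, not production use.
* Missing covariates are excluded, never imputed.
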