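---
title: "Evaluating a new predictor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a new predictor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskmetrics)
```

## The problem

A risk prediction model assigns each person a probability of an event — a
cardiovascular event, say — within a fixed horizon, here ten years. When a
new predictor is proposed, the extended model is compared with the base
model on the same cohort, and the comparison is summarised by statistics of
three families:

* **predictive ability** — sensitivity, specificity and the binary
  c-statistic at a risk cutpoint, and Harrell's c over the whole risk scale;
* **reclassification** — the continuous, categorical and binary net
  reclassification improvement (NRI);
* **clinical utility** — net benefit, and event-free life years (EFLY)
  gained per person evaluated.

All of these depend not only on the models but on the *population*: when
the treatment cutpoint is fixed (20% ten-year risk in UK-style CVD
guidance) while the mean risk of the population varies, each measure traces
its own curve against mean risk. This package computes all of the measures
under right-censoring and provides a simulation engine that maps those
curves.

## Counting events under censoring

Every binary-outcome quantity ("event by ten years") is estimated through
the Kaplan–Meier (product-limit) estimator rather than by raw counting, so
subjects censored before the horizon contribute what is actually known
about them. For a group of $n_g$ subjects, the number of events by $t$ is
$n_g\,(1 - \mathrm{KM}_g(t))$; these KM-weighted counts are generally
non-integer, and no rounding is applied anywhere. Cells of a
reclassification table with subjects but no observed events contribute
event probability 0; empty cells contribute 0 subjects. Ties between event
and censoring times are resolved events-first, the standard convention.

The classification measures at a cutpoint $p_t$ are

$$\text{sens} = \frac{n_{\text{high}}\,(1-\mathrm{KM}_{\text{high}}(t))}
{n\,(1-\mathrm{KM}(t))}, \qquad
\text{spec} = \frac{n_{\text{low}}\,\mathrm{KM}_{\text{low}}(t)}
{n\,\mathrm{KM}(t)},$$

with *high risk* meaning predicted risk **strictly greater** than $p_t$; a
risk exactly at the cutpoint is classified low. The same strictness is used
for "reclassified up" (any positive risk change, no epsilon floor, though
`nri_continuous()` accepts a `min_change`) and for treatment assignment in
the utility measures. The binary c-statistic is
$(\text{sens}+\text{spec})/2$; the binary NRI is
$\Delta\text{sens}+\Delta\text{spec}$, identically twice the binary-c
difference, and the package computes it that way so the identity holds to
the bit.

## Harrell's c at a horizon

Follow-up is truncated at the horizon before pairing: events after ten
years count as censored at ten. A subject with an event is paired with
every other subject; the pair is usable when the observed times differ and
the partner was still under observation at the index event time, concordant
when the earlier-event subject has the higher predicted risk, tied when the
predictions are equal, and

$$c = \frac{\text{concordant} + 0.5\,\text{tied}}{\text{usable}}.$$

The implementation counts pairs with a Fenwick tree over risk ranks in
$O(n \log n)$, so a dataset of 10,000 subjects evaluates in well under a
second; the tests pin it to an exhaustive $O(n^2)$ pair enumeration (exact
equality on random datasets with tied risks and tied times) and
cross-check it against `survival::concordance()`.

## Model fitting

`fit_model()` wraps `survival::coxph()` with Efron tie handling (the
lower-bias default; the choice matters little at continuous event times)
and extracts a Breslow-type baseline cumulative hazard at covariate value
zero (`survfit(..., ctype = 1)`). Predicted horizon risk is the continuous
exponential transform $1 - \exp(-H_0(t)e^{\beta'x})$ rather than a
product-limit evaluated only at event times; the difference is second order
in the step size. Collinear covariates and non-convergence raise errors
with the offending covariates named; the study runner converts such errors
into flagged-missing record fields rather than aborting a sweep.

## The odds-ratio diagnostic

With a constant hazard ratio, the odds ratio for "event by ten years"
is *not* constant across populations: it approaches the hazard ratio when
events are rare and inflates as the mean risk grows. This mechanism is why
rank-based measures (Harrell's c, NRI(>0)) drift upward with mean risk even
though the hazard ratio never changes. `ten_year_odds_ratio()` quantifies
it by logistic regression of horizon status on the predictor, scaled to one
sample standard deviation.

Two conventions are supported for subjects censored event-free before the
horizon, whose status is unknown: keep them as non-events (default) or
exclude them. The default also adjusts for the baseline covariate when the
study runner calls it, because the diagnostic accompanies a two-covariate
model comparison; with light censoring (2.5–10% here) the conventions
differ modestly at low mean risk but the kept-as-non-event, adjusted form
is the one whose averages reproduce the classical inflation pattern
(roughly 2.1 at 5% mean risk rising to 3.2 at 90% for a generating hazard
ratio of 2 under a medium-strength baseline model).

## Clinical utility

**Net benefit** at threshold $p_t$ is
$TP/n - (FP/n)\,p_t/(1-p_t)$, with $TP$ and $FP$ counted by KM within the
high-risk group. It is reported per person and per 1000 evaluated.

**EFLY.** Treatment is assumed to reduce the ten-year risk by a relative
fraction $\rho$ (default 20%, a meta-analytic statin-scale effect), acting
on the risk scale: $r \mapsto (1-\rho)r$. A risk $r$ is mapped to a
constant-hazard survival curve $h = -\log(1-r)/T$, the treated hazard is
back-derived from the treated risk, and the per-person benefit is the gain
in restricted mean event-free time over $[0, T]$:

$$b(r) = \frac{1-e^{-h'T}}{h'} - \frac{1-e^{-hT}}{h},
\qquad h' = -\tfrac{1}{T}\log\!\big(1-(1-\rho)r\big).$$

The treatment threshold is taken to be the *optimal* cutpoint — benefits
equal costs for a person exactly at the threshold — so the per-treated cost
is $C(T) = b(p_t)$ (0.2139 EFLY at $p_t = 0.2$, $\rho = 0.2$, $T = 10$,
verified against numeric integration). The EFLY gain per person evaluated
is $P\,[B(T) - C(T)]$ with $P$ the treated fraction.

The open design question is what $B(T)$, the realized benefit per treated
person, should be estimated from. Scoring each model by $b(\cdot)$ applied
to its *own predicted risks* lets a model reward itself: a better-separated
risk distribution inflates the benefit through the convexity of $b$
regardless of whom the model actually selects, and in simulation this
produced between-model EFLY differences an order of magnitude larger than
the other utility measures. The package therefore scores benefit against
*observed outcomes*: $B(T) = b(\hat r_{\text{obs}})$, where
$\hat r_{\text{obs}}$ is the treated group's Kaplan–Meier event probability
at the horizon. This keeps all three EFLY operations on a single benefit
map, is well-defined under censoring, preserves the break-even property
exactly (a treated group observed at threshold risk nets zero), and makes
the measure penalizable: a model that stops treating genuinely high-risk
people loses benefit it cannot argue back through its own predictions.
One consequence is worth stating plainly: when the extended model is the
data-generating truth, its expected EFLY difference is non-negative at
every mean risk — deselecting people whose true risk is below the
break-even threshold cannot hurt — so the EFLY-vs-mean-risk difference
curve approaches zero from above at high mean risk rather than dipping
below it. The monetary value of an EFLY (default £20,000) is carried as
metadata only and never enters a measure.

## The simulation engine

Event times follow the Cox-exponential model
$T = -\log U / (\lambda e^{\beta_1 x_1 + \beta_2 x_2})$ with $x_1, x_2$
independent standard normal; censoring times are exponential, calibrated so
the probability of being censored by ten years is 10%. There is no
administrative cap on follow-up — the horizon-based measures truncate at
ten years themselves — and the *censored fraction* reported per dataset is
the fraction censored within the horizon, the quantity that actually
degrades the ten-year measures. Baseline hazard ratios of 1.5/3/6 and
new-predictor hazard ratios of 1.2/2/3 define weak/medium/strong cells.

`solve_baseline_hazard()` inverts the population mean-risk equation
$E[1 - \exp(-\lambda T e^{\beta_1 x_1 + \beta_2 x_2})]$ by 101-point
Gauss–Hermite quadrature over the linear predictor plus a root solve on
$\log\lambda$, accurate to better than $10^{-6}$ on the risk scale. The
default sweep is a 60-point log-spaced $\lambda$ grid spanning mean
ten-year risks from 1% to 92%: below 1% a 10,000-subject dataset carries
too few events to estimate the measures stably, and above ~92% essentially
every subject has an event within the decade, residual within-horizon
censoring falls below ~2.4%, and the two models treat everyone — the
comparison degenerates. Replicate seeding is hierarchical: the master seed
draws one integer substream seed per (cell, grid point, replicate), so runs
are bit-reproducible and replicates are disjoint; the per-record seed is
stored in the output.

Smoothing of measure-vs-mean-risk scatters uses a cubic smoothing spline
(`stats::smooth.spline`) with its smoothing parameter chosen by generalized
cross-validation; duplicated abscissae are aggregated with weights, and the
reported peak location is the argmax on a 512-point grid. Because lines lie
in the null space of the spline penalty, exactly linear inputs are
reproduced to numerical precision. One caveat from the package's own
simulations: the net-benefit difference traces a broad, flat plateau
(roughly constant over mean risks 0.18–0.35 for the medium/medium cell), so
the *location* of its smoothed maximum is intrinsically unstable within
that plateau even though the curve itself is stable; peak locations should
be read with that flatness in mind.

Problem sizes: the full study profile (60-point grid, 1,000 replicates of
$n = 10{,}000$ per cell) reproduces the published scale;
`desk_study_config()` (11-point grid, 50 replicates, $n = 2{,}000$,
medium/medium cell) exercises every code path in about two minutes and is
what the test suite uses. Reducing replicates changes Monte-Carlo error
only, never a point definition.

## The synthetic cohort generator

The empirical pipeline is exercised on synthetic cohorts emulating classic
sex-specific CVD cohorts: continuous age, total cholesterol, HDL and
systolic blood pressure and binary smoking, diabetes and antihypertensive
treatment, with sex-specific hazard ratios (e.g. SBP 1.30 per 20 mmHg for
men, 1.48 for women), cohort sizes 3969 (men) and 4522 (women), target mean
ten-year risks of 15.6% and 8.2%, and administrative censoring at twelve
years. Event times are exponential proportional-hazards in the centred
covariates; the baseline hazard is calibrated on the realized cohort so the
mean generated risk hits the target. Covariate marginals (means, SDs,
prevalences) are typical mid-century community-cohort values chosen once;
covariates are independent by default, with an optional correlation matrix
for the continuous block since real risk factors correlate (age with blood
pressure, notably). What these cohorts do *not* emulate: covariate
measurement error, non-proportional hazards, secular trends in treatment,
or competing mortality — so tests passing on them certify the pipeline's
arithmetic and calibration, not transportability to any real cohort.

## The empirical pipeline

`compare_models()` fits nested Cox models, computes the full measure panel
on the complete data (point estimates are never bootstrap aggregates), and
attaches percentile bootstrap 95% intervals from nonparametric resampling
of subjects (default $B = 2000$), unstratified; resamples in which a fit or
measure fails are dropped and counted. Percentile intervals were chosen
over BCa for transparency and because the measure panel contains
non-smooth functionals (cutpoint indicators) for which BCa's acceleration
estimate is unreliable. Sex-stratified analyses are run as separate calls
per subgroup rather than via interaction terms. Measures use the ten-year
horizon even when cohort follow-up extends to twelve years.

## Numerical details and edge cases

* KM at $t$ beyond the last observed time carries the last value forward.
* A dataset with no events before the horizon makes the c-statistic,
  sensitivity and the NRIs undefined — these raise errors, which the study
  runner records as flagged-missing fields with the reason in `note`.
* `treated_risk(1, rho)` is defined, but a predicted risk of exactly 1
  implies an infinite hazard and `efly_benefit_per_subject()` refuses it;
  the observed-risk path clamps a KM estimate of exactly 1 just below it.
* Risk-category boundaries are right-closed: a risk equal to a cutpoint
  belongs to the lower category everywhere, so no measure can change when
  a prediction moves onto a boundary from below.
* All comparisons of classification summaries verify that cutpoint and
  horizon match before differencing.

## Known limitations

Non-exponential baseline hazards, time-varying effects, informative
censoring, competing risks, IDI and weighted NRI variants, case-control
reweighting, and decision-curve sweeps over thresholds are out of scope.
The EFLY estimator is one defensible operationalization of a
threshold-calibrated life-years framework; alternatives (per-subject
predicted-risk benefits, hazard-scale treatment effects) change its
between-model differences materially, which is precisely why the choice is
documented here and isolated behind `efly_gain()`.
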