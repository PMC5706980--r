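---
title: "Discrete-time survival analysis of build-up identification experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time survival analysis of build-up identification experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dthaz)
```

## The problem and the model

In a build-up (repeated presentation) identification experiment, a fragmented
object outline is shown over and over with progressively more contour until
the observer names it correctly. The natural response variable is not
accuracy at a single exposure but a *waiting time*: the presentation number
at which identification first succeeds, right-censored when it never does
within the 10-presentation horizon. `dthaz` analyses such data with
discrete-time survival (event-history) methods.

Two functions summarize the distribution of the identification time $T$:

* the discrete-time hazard, $h(t) = P(T = t \mid T \ge t)$ — the conditional
  probability of first correct naming after presentation $t$;
* the survivor function,
  $S(t) = P(T > t) = \prod_{j \le t} \{1 - h(j)\}$.

Because $h(t)$ is a probability, regression modelling works on the
complementary log-log scale,
$\operatorname{cloglog}[h(t)] = \ln(-\ln(1 - h(t)))$, the natural choice when
the underlying processing time is continuous but observed in discrete bins:
an additive shift on this scale is a proportional shift of the underlying
continuous-time hazard, so exponentiated coefficients read as hazard ratios.
The model is

$$\operatorname{cloglog}[h(t)] =
  \underbrace{\alpha_0 + \alpha_1 (t - c) + \dots + \alpha_d (t - c)^d}_{\text{baseline}}
  + \beta_1 X_1 + \beta_2 X_2 + \dots$$

where the $X_j$ are 0/1 stimulus and participant covariates, possibly
multiplied by powers of centred time $(t - c)^p$ so that covariate effects
may grow or fade across presentations. With centring presentation $c = 1$,
every coefficient without a time power describes the effect *after the first
presentation*.

Fitting works on the person-period expansion of the trial data
(`expand_person_period()`): one row per presentation at risk, with an
`EVENT` indicator that is 1 only on the row where identification occurred.
A trial identified at presentation $k$ contributes $k$ rows; a censored
trial contributes the full horizon. The Bernoulli likelihood of `EVENT`
given the linear predictor is then exactly the discrete-time survival
likelihood.

## What the simulator emulates — and what it does not

`buildup_config()` defaults encode the emulated study design:

* 7 control participants plus one patient (200 trials each);
* 100 object outlines, 51 manmade and 49 natural; each shown twice per
  participant, once MP-fragmented (fragments around midpoints) and once
  SP-fragmented (fragments around salient points), with the second showing
  flagged as a trial repetition;
* presentation order randomized per participant under the constraint that an
  object never occupies two consecutive trials (constrained shuffle with
  local swap repair; the original scheduling algorithm is not published, so
  any scheduler satisfying the constraint is acceptable);
* a geometric fragmentation schedule, $100 \alpha^{(10 - x)}$ percent of
  contour at level $x$ with $\alpha = 0.77$: 10, 12, 16, 21, 27, 35, 46, 59,
  77, 100 (rounded half-up, so $100 \times 0.77^9 = 9.52$ prints as 10);
* symmetry drawn Bernoulli(0.51) for manmade and Bernoulli(0.31) for natural
  outlines, matching the published composition of the stimulus set;
* complexity drawn Bernoulli(0.5) independently of category. This is a
  stand-in: the original dichotomization of the outline-homogeneity measure
  cannot be reconstructed from published summaries, and no claim is made
  that it reflects the real stimulus set.

Outcomes are generated from the model itself: presentations are visited in
order and an event occurs at $t$ with probability $h(t)$ from the generating
coefficient vector (by default the transcribed published final model, see
`final_model()`). The patient effect is carried entirely by the `Patient`
dummy and its interactions — there is no separate generative mechanism. One
random stream is seeded per dataset and consumed in trial order, so equal
seeds give byte-identical output files.

What passing simulation-based tests therefore shows is that the estimation
machinery is correct *under the model*: they cannot detect features of real
data the generator omits — genuine between-participant heterogeneity beyond
the patient dummy, semantic confusability of specific objects, learning or
fatigue across the session, or scoring ambiguity.

## Estimation choices

`fit_hazard_model()` maximizes the cloglog-binomial likelihood by
Newton–Raphson with step-halving, declaring convergence when the relative
log-likelihood change drops below $10^{-10}$ (at most 100 iterations). The
observed information is used for the Newton step and, inverted at the
optimum, as the model-based covariance; when a step direction is not an
ascent direction the iteration falls back to Fisher scoring weights for that
step. Iterates with any $|\beta| > 15$ on the cloglog scale abort with a
separation error — on this scale $|\eta| = 15$ already corresponds to
hazards numerically indistinguishable from 0 or 1. Hazards are evaluated
with `expm1`/`log1p` so that the likelihood stays finite over the whole
usable range.

Repeated-measurements dependence is handled by a cluster-robust sandwich
covariance whose meat sums score contributions within clusters. The default
cluster is the participant — the conservative standard when trials share an
observer — and `cluster = "trial_id"` selects trial-level clustering. No
small-sample factor is applied by default (`cadjust = TRUE` adds
$G/(G-1)$); the unadjusted form satisfies the exact identity that with
singleton clusters and a saturated model the sandwich equals the
model-based covariance. Per-term inference is reported as
$\chi^2(1) = (\hat\beta/SE)^2$ with a two-sided $p$, using the robust
standard error.

Two caveats on clustering, both visible in this package's own simulation
studies. First, with only 8 participants the participant-level sandwich is
noisy and intervals undercover (about 84% achieved coverage for a nominal
95% in the recovery study below). Second, for a covariate that varies in a
single cluster — the patient dummy, present in exactly one participant —
participant-level robust variance is degenerate and severely anticonservative.
For simulated data, whose person-period draws are independent given the
covariates, the trial is the exchangeable unit, and the package's recovery
and selection studies therefore cluster on trials; for real data
participant-level clustering remains the default, with the few-cluster
caveat applying.

`recenter()` re-expresses the fitted polynomial around another presentation
by the exact binomial-expansion reparameterization
$\beta^{(c_2)}_{(C,j)} = \sum_{p \ge j} \binom{p}{j} (c_2 - c_1)^{p-j}
\beta^{(c_1)}_{(C,p)}$, applied per covariate product $C$; the
log-likelihood and all predicted functions are unchanged to machine
precision, while main effects now describe the new presentation. This
requires the term set to contain all lower time powers within each product
group — guaranteed for hierarchically closed models — and refuses otherwise
rather than silently refitting.

`backward_select()` removes one term per step: the removable term (no
retained term with a superset covariate product and equal-or-higher time
power contains it) with the largest robust Wald $p$ above the criterion
(default $\alpha = 0.05$; the original analysis states no threshold). Ties
break deterministically — higher time power first, then name order. The
hierarchical principle is thus enforced by construction and every decision
is recorded in the trace.

## The baseline time polynomial

The model equation in the source analysis prints a cubic baseline, but the
published coefficient table fits a quartic (a `PT^4` term). The package
keeps the degree configurable and defaults to 4, matching the table that
all replication targets come from.

## Replication of the published model

`final_model_coefficients()` ships the transcribed 61-term final model.
`replicate_printed_values()` recomputes every published derived quantity
from it:

```{r replication}
rep <- replicate_printed_values()
head(rep, 12)
```

Probabilities and hazard ratios are matched at their printed precision (2
decimals); recentred coefficients, being reconstructed from inputs printed
to 4 decimals, are matched within ±0.005. One published value fails by any
reading: the baseline survivor after presentation five evaluates to
`r round(subset(rep, name == "baseline S(5)")$computed, 4)` from the printed
coefficients, which rounds to 0.04, not the published .05. Propagating the
printed rounding of the coefficients moves this value by less than 0.001,
so the package flags the row rather than correcting either side. A
mutation test guards the transcription itself: perturbing any single
coefficient by more than 0.05 breaks at least one replication target.

On the "hazard ratio" label: on the cloglog scale $e^{\beta}$ is a ratio of
increments of the underlying continuous-time cumulative hazard, not of the
discrete per-presentation hazards themselves; the package reports it under
the customary name without reinterpreting it.

## Numerical and degenerate-input conventions

* Fragmentation percentages round half-up; a schedule whose rounded
  percentages are not strictly increasing (very small $\alpha$ with many
  levels) warns rather than errors.
* Life-table bins with an empty risk set report a missing hazard with a
  warning — never zero — and survivor estimation stops at the last
  estimable presentation.
* Collinear design columns, events beyond the horizon, unknown term or
  covariate names, and inconsistent event/censoring flags raise immediate
  errors naming the offender.
* When every event lands on the first presentation the fitted hazard
  saturates at 1: the cloglog likelihood flattens double-exponentially, so
  the iteration halts at a numerically certain event instead of diverging.

## Study sizes used by the packaged simulation checks

The package's own stochastic checks run at the emulated design size — 8
participants × 200 trials (≈ 5–6 thousand person-periods after expansion) —
with 50 replicates for the coefficient-recovery study and 100 replicates
for the selection study; oracle comparisons against an independent
derivative-free optimizer use instances of at most 30 person-periods, where
both routes are exact to $10^{-6}$.

At that design size, maximum likelihood shows a small genuine finite-sample
bias in the patient coefficient (about −0.02 on the cloglog scale, driven
by the ~50 identification events the single patient contributes per
dataset). This is a property of ML at the study's scale, not of the
implementation — the estimates agree with `stats::glm` to $10^{-6}$ — and
it sits at the edge of what a 50-replicate bias check can resolve. Firth-type
penalization would reduce it but is deliberately out of scope.

## Limitations

* No random-effects (frailty) structure: participant heterogeneity beyond
  the patient indicator is not modelled, matching the original analysis.
* No continuous-time methods, left truncation, or competing risks; the
  horizon is a hard censoring point.
* Hazard-ratio confidence intervals for covariates varying in very few
  clusters should not be trusted under participant-level clustering (see
  above); this mirrors a general limitation of sandwich estimators, not a
  package choice.
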