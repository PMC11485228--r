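---
title: "Methods: two-era natural-experiment survival analysis with RMTL inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-era natural-experiment survival analysis with RMTL inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design

A step-change natural experiment arises when clinical practice switches
abruptly — here, one vaccine replacing another within a single month —
so that people treated just after the switch (the *primary* era) can be
compared with people treated just before it (the *comparator* era).
Assignment to era is driven by calendar time, not by health or
health-seeking behaviour, which removes the main selection biases of
vaccinated-versus-unvaccinated designs. What remains is *drift*: the
treated population's composition changes slowly over calendar time, so
the two eras are balanced explicitly by matching on covariates measured
at baseline.

`natexp` implements that full design: simulate (or read) a two-era
cohort table, match, align follow-up if requested, landmark, estimate,
and test. Every estimator is also exported on its own.

## Estimators and their assumptions

### Kaplan–Meier and restricted mean time lost

Incidence is summarised by the product-limit estimator with Greenwood
variance. The effect measure is deliberately *not* a hazard ratio: when
an effect wanes over follow-up, proportional hazards fails and a single
Cox coefficient has no clean interpretation. Instead the package uses
the restricted mean time lost up to a horizon $\tau$,

$$\mathrm{RMTL}(\tau) = \tau - \int_0^\tau S(t)\,dt,$$

the average time lost to (or lived with) the outcome per person by
$\tau$. Its variance is the standard large-sample restricted-mean
formula $\sum_{t_i \le \tau} \left[\int_{t_i}^\tau S\,du\right]^2
d_i/(n_i(n_i-d_i))$. Between-group contrast: the RMTL *ratio*
(primary/comparator), with a delta-method CI on the log scale and a
two-sided z-test. The absolute difference is additionally translated
into *additional event-free days among the affected*,
$365.25\,(\mathrm{RMTL}_c - \mathrm{RMTL}_p)/F_c(\tau)$, where
$F_c(\tau)$ is the comparator's cumulative incidence — the average
delay experienced by people who do develop the outcome.

Assumptions: censoring is non-informative within era; the horizon
$\tau$ lies within the support of both follow-up distributions (the
estimator refuses a $\tau$ beyond the last observed time unless the
curve has already reached $S=0$, in which case it is fully determined).

### Flexible parametric time-varying hazard ratios

Hazard-ratio dynamics are modelled on the log-cumulative-hazard scale,

$$\log H(t \mid g) = s_0(\log t;\gamma) + g\, s_1(\log t;\delta),$$

with restricted (natural) cubic splines $s_0, s_1$: cubic between the
boundary knots and linear beyond them, so extrapolation is tame.
Degrees of freedom have these meanings:

* baseline `df_baseline = d`: intercept plus $d$ basis columns in
  $\log t$; `d = 1` is linear in $\log t$, i.e. exactly a Weibull
  model;
* group `df_group = g`: $g$ group-interacted terms; `g = 1` is a single
  constant — proportional hazards — while `g = 2` adds a linear
  log-time interaction and `g = 3` a spline term. This makes the
  `(1,1)` model *identical* to Weibull proportional hazards, which the
  test suite uses as an analytic anchor (log-likelihood agreement with
  an independent Weibull MLE to $10^{-4}$).

Interior knots sit at quantiles of the uncensored log event times
(median for one interior knot, terciles for two); boundary knots at the
extreme uncensored log event times.

Model complexity is selected by lowest AIC ($2k - 2\ell$). The default
selection fits one *shared* df $\in \{1,2,3\}$ applied to both the
baseline and its group dependency (three fits), mirroring the selection
procedure this design is usually described with; a full 3×3 grid over
the two dimensions is available via `select_fpm(..., grid = "full")`.
Ties break toward fewer parameters. The shared grid also has better
selection behaviour: with a 3×3 grid, AIC's well-known tendency to
admit a superfluous parameter with probability
$P(\chi^2_1 > 2) \approx 0.16$ applies in two dimensions at once.

HR($t$) and its pointwise CI follow from the fitted model by the delta
method on $\log \mathrm{HR}(t)$; whether bands should be simultaneous
rather than pointwise is an open presentational question and pointwise
was chosen.

### Matching

The propensity score is a logistic regression of era membership on all
covariate indicators. Age enters as 2-year-bin dummies (65–66, …, 95+)
rather than linearly — tighter control than a continuous term, and the
same bins are reused by coarsened exact matching. Matching is greedy
1:1 nearest-neighbour without replacement within a caliper, processing
primary-era patients in an order randomized under the seed so that
record order cannot influence results; nearest-neighbour ties break by
a seeded random ranking of comparators. Greedy (rather than optimal)
matching was chosen because it matches the randomize-then-match
description this design follows and scales linearly; the implementation
uses a sorted linked-list with path compression, so matching 20,000
against 20,000 takes seconds.

The caliper defaults to 0.1 on the raw probability scale; since the
convention is genuinely ambiguous in the field, `caliper_scale =
"logit_sd"` switches to 0.1 standard deviations of the logit score.
Balance is judged by standardized mean differences; SMD < 0.1 after
matching is flagged as well matched. Because the primary era is usually
larger, most comparator patients find a match and the estimand is best
read as an average treatment effect in the comparator-era population.

Coarsened exact matching stratifies on the joint signature of a small
key-covariate set (default: binned age, sex, race, and the neurological
comorbidity flags) and forms random 1:1 pairs within strata. The strata
themselves are deterministic; only within-stratum pairing uses the
seed. CEM can never worsen balance on its own coarsened variables.

### Resampling inference

The moderation test permutes sex labels: individuals are reallocated to
two pseudo-sex groups of the original sizes and the absolute difference
in RMTL ratios is recomputed each time, giving
$P = (1+n_>)/(1+n)$ with $n_>$ the number of permutations strictly
exceeding the observed statistic. Permutation is era-preserving by
default (labels shuffle within each era, keeping the era composition of
the pseudo-groups fixed); `preserve_era = FALSE` shuffles globally. A
permutation that produces a degenerate stratum (zero RMTL) is counted
as exceeding — conservative — and logged.

The matched-pair bootstrap resamples pairs with replacement (both
members together, respecting the paired design), yielding a percentile
CI and a two-sided percentile p-value floored at $1/n_{\mathrm{boot}}$.
Resamples with zero events in a group are redrawn and counted.

Follow-up alignment answers "is the effect an artifact of unequal
follow-up?": cohort-wise alignment censors both eras at the smaller of
the two maximum follow-ups; pair-wise alignment censors each pair at
its shorter member. Events beyond the cut become censorings at the cut;
alignment can only shorten follow-up.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `landmark` | 0.25 | years | excludes diagnoses in the first 3 months, which are mostly pre-existing disease surfacing after contact |
| `horizon` | 6 | years | end of the outcome window |
| `caliper` | 0.1 | PS scale | the conventional published value for this design |
| SMD threshold | 0.1 | — | conventional balance rule |
| `df_baseline`, `df_group` | AIC-selected in 1–3 | — | enough to capture waning without overfitting |
| `n_perm`, `n_boot` | 1000 | — | resolves p down to ~0.001 |
| `alpha` | 0.05 | — | two-sided, no multiplicity correction across grid rows (each row is reported, not selected) |

The 3-month window is implemented as a *landmark*: subjects whose event
or censoring time precedes 0.25 y are dropped, time is re-origined at
0.25 y and the horizon becomes 5.75 y on the shifted clock. The
alternative — left truncation with delayed entry — would differ
slightly; the landmark was chosen for transparency and because every
downstream estimator then works on ordinary right-censored data.

Time is measured in years with 365.25 days/year for day-level
reporting.

## The synthetic cohort generator

No public patient-level data exist for this design, so
`generate_cohorts()` emulates the statistical structure the analysis
assumes:

* **two eras with drift** — ~55 covariates (age, sex, race, ethnicity,
  marital status, ~50 binary comorbidity and utilisation flags) with
  era-specific prevalences; with default drift several covariates
  (vaccination-behaviour and utilisation flags) exceed pre-match SMD
  0.15, which matching must then remove;
* **era-dependent censoring** — staggered uniform entry over a 3-year
  enrolment window per era plus an administrative data cut, giving
  median follow-up ≈ 6.0 y (comparator) and ≈ 4.15 y (primary), with
  2%/year exponential dropout;
* **outcomes from piecewise-exponential hazards**
  $h(t) = h_0(t)\exp(\beta'x + w(t)\,\mathrm{era} +
  \gamma\,\mathrm{era}\cdot\mathrm{female})$, drawn by inversion: a
  dementia-like outcome with a protective era effect that wanes
  ($w(t)$ stepping from $\log 0.78$ to 0 across six years) and is
  stronger in females ($\gamma = \log 0.88$); a zoster-like outcome
  with a stronger, also waning, protective effect; all-cause mortality
  (null era effect, terminal: death censors the other outcomes); and a
  negative-control outcome (null era effect) for detecting residual
  confounding;
* **missingness** — sex, race and ethnicity are set to an explicit
  `"missing"` category with configurable probability, which then
  participates in matching as its own level.

Randomness is split into named concerns (covariates, censoring, one
stream per outcome, missingness) via fixed sub-seeds of the master
seed, so adding a covariate never perturbs event draws, and the same
seed yields byte-identical cohort tables.

The era-effect step functions were calibrated once, analytically
against the generator itself, so that the paper-like scenario induces
6-year RMTL ratios of roughly 0.83 for the dementia-like outcome
(≈0.78 in females, ≈0.90 in males) and roughly 0.65 for the
zoster-like outcome; they are scenario constants, not fitted
quantities.

What the generator does *not* emulate — and hence what passing tests do
not establish about real EHR data: correlated comorbidity structure
(covariates are drawn independently), coding intensity that varies by
provider or calendar time (for example pandemic-era diagnostic
disruption), reverse causation beyond the landmark window,
misclassified or interval-censored diagnoses, repeat vaccine doses, and
unmeasured confounding that drifts with era. The negative-control
machinery exists precisely because the last of these cannot be ruled
out by construction on real data.

## Numerical choices

* **Ties:** events precede censorings at equal times (censored subjects
  stay in the risk set at their own time); Breslow tie handling in the
  Cox model.
* **Spline optimisation:** Weibull-equivalent initialisation from an
  AFT fit, BFGS with analytic gradients, then Newton polishing with
  step-halving until the gradient max-norm falls below
  $10^{-7}\max(1,|\ell|)$ — tight enough that log-likelihood
  comparisons at $10^{-4}$ are meaningful. Up to five jittered restarts
  on failure. Monotonicity of $\log H$ in $\log t$ is enforced on the
  data range by a smooth penalty (the $\log \eta'$ term is linearly
  extended below $\eta' = 10^{-6}$); residual violation at convergence
  is a refusal, with the minimum slope reported.
* **Degenerate inputs:** an all-censored sample is a valid $S \equiv 1$
  curve; zero RMTL in either arm makes the ratio undefined and returns
  a flagged difference-only comparison; perfect separation in the
  propensity model is flagged and coefficients are capped; a monotone
  Cox partial likelihood is flagged and capped; strata containing a
  single era contribute no CEM pairs.
* **Additional-days variance:** delta method treating the RMTL
  difference and the comparator cumulative incidence as independent;
  only the point-estimate formula is prescribed by the design this
  package follows, so the independence approximation is a documented
  package choice.
* **Provenance:** every pipeline artifact embeds the config, seed and a
  32-bit FNV-1a hash of the config, and omits timestamps so reruns are
  byte-identical.

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to make the oracles
sharp while keeping a full run around a minute: closed-form RMST checks
at n = 5,000 with 500 replicates; CI coverage at 2,000 per group × 500
replicates; permutation calibration at 200 replicates × 200
permutations; balance on the drifted scenario at 10,000 per era;
PH-test power at 10,000 subjects × 200 replicates; AIC-selection
consistency at n = 5,000 × 100 replicates; and the qualitative
time-varying-HR shape at 20,000 per era, where the waning generative
effect is comfortably detectable.

## Known limitations

* RMTL comparisons in the primary analysis ignore the pairing induced
  by matching (as is common); the pair bootstrap exists to quantify how
  much that matters.
* The flexible model's confidence bands are pointwise, not
  simultaneous.
* Competing risks are handled by censoring at death, i.e. estimands are
  cause-specific, not subdistribution-based; a Fine–Gray treatment is
  out of scope.
* Left truncation as an alternative to landmarking is not implemented,
  only configurable landmarks.
* The permutation test assumes exchangeability of individuals across
  the moderator within era; moderators correlated with follow-up
  length violate this subtly.
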