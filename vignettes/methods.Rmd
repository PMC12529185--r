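---
title: "Methods: emulating target trials of sustained medication exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating target trials of sustained medication exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trialemulate)
```

## The problem

Head-to-head randomized trials of glucose-lowering medication classes and
major adverse cardiovascular events (MACE: nonfatal myocardial infarction,
nonfatal stroke, cardiovascular death) are scarce, and naive observational
comparisons are distorted by confounded treatment choice, frequent
discontinuation and crossover, and informative loss to follow-up.
`trialemulate` implements the standard remedy — target trial emulation with
longitudinal causal estimators — as a reusable pipeline over four raw
EHR-style tables: patients (baseline covariates, enrollment span, death day
and cause), pharmacy dispensings (medication class, dispense day, days'
supply), a covariate measurement stream, and clinical events.

Two protocols are supported. The per-protocol (PP) analysis targets the
effect of *initiating and sustaining* a medication class, handling
treatment-protocol deviations (discontinuation or crossover) by artificial
censoring with inverse-probability correction. The intention-to-treat
analogue (ITT) targets the effect of initiation alone and ignores later
deviations.

## Pipeline stages

### New-user cohorts and attrition

`identify_new_users()` implements the new-user design: a fill of a compared
class on day $d$ is an index-fill candidate only if no other compared-class
dispensing occurred in $(d - w, d]$ with washout $w = 730$ days. A fill
exactly $w$ days earlier does not block; a same-day fill of a different
compared class does (the patient cannot be assigned a single arm). One
index fill per patient — the earliest qualifying one — defines cohort entry
and the start of follow-up, keeping the per-trial cohort i.i.d. for
variance estimation. `apply_eligibility()` then applies an ordered list of
exclusion predicates, attributing each excluded fill to the *first* failing
predicate so the attrition flow conserves exactly:
`new fills = index fills + sum(exclusions)`. Clinical exclusion definitions
(diagnosis-code logic) are deliberately out of scope; predicates are opaque
functions of baseline data.

### Dispensings to exposure episodes

A dispensing on day $d$ with supply $s$ covers $[d, d + 2s)$ — coverage
lasting twice the days' supply. Consecutive coverage periods merge into one
exposure episode when the refill gap (next dispense day minus the running
coverage end) is at most 90 days, and the gap days themselves count as
exposed. Overlapping coverage is unioned; an early refill never extends
coverage beyond its own window (no stockpiling) — the per-dispensing
union is a documented choice where cumulative stockpiling would be the
alternative reading. A treatment-protocol deviation is the earlier of the
index-class episode end (discontinuation) and the first covered day of a
comparator class after the index day (crossover; same-day ties classify as
crossover).

### The person-interval dataset

`build_long_dataset()` emits one row per patient per 30-day interval from
the index date to the earliest of the outcome, a censoring event, or the
horizon (default 30 intervals = 900 days, the closest interval multiple to
2.5 years). Censoring channels are disenrollment, non-cardiovascular
death, death of unknown cause (its own channel), administrative end of
study, and — under PP — artificial censoring at the deviation.

Ordering conventions (the tie-break rules are conventions, not data
facts, so they are documented precisely):

* outcome versus *real* censoring is resolved at interval level with
  outcome first — a MACE and a disenrollment in the same interval count as
  an event;
* the PP deviation is resolved at *day* level and wins same-day ties:
  follow-up ends at the deviation time, so an event later in the deviating
  interval occurs off-regime and is not attributed to the sustained
  regime. Counting such events would inflate every estimator by roughly
  the per-interval deviation rate;
* rows censored by a real cause remain *at risk with* $Y = 0$ in the
  product-limit risk sets (censoring acts at the interval end, and under
  outcome-first labeling their event-freeness is observed), while TMLE
  regression rows are strictly uncensored because the iterated outcome
  needs the next interval. The cumulative weights match each convention:
  real-censoring survival factors are lagged one interval for the at-risk
  convention and unlagged for the strict one; the deviation factor always
  includes the current interval because deviation acts at the interval
  start.

Covariates use the missingness-indicator approach: $M_k = 1$ if the
covariate was measured in interval $k$ (latest measurement wins);
$L_k$ is the last observed value at or before $k$, with never-observed
patients imputed by the cohort-wide baseline mode (categorical) or mean
(continuous). Values and indicators both enter every model.

## Nuisance models

Propensity series are fitted *per interval* for treatment initiation and
each censoring cause (continuation — "no interruption or crossover" — is
the artificial-censoring channel of the PP analysis). Each fit is a
cross-validated super learner: V-fold CV log-loss per learner
(intercept-only, main-terms logistic, L1-penalised logistic), and an
ensemble given by the convex weight vector minimising CV log-loss.
Single-learner corners are always candidates, so the ensemble's CV loss
never exceeds the best single learner's. Degenerate targets (a cause with
no events at desk scale) yield a flagged constant predictor rather than an
error. Intervals with fewer than `min_events = 25` target events share one
pooled fit with the interval index as a predictor. Multinomial initiation
(4-arm trials) uses one-vs-rest fits normalised to sum to one.

Emitted probabilities used in weight denominators are floored at
`g_floor = 0.005` to prevent unbounded weights; outcome regressions are
L1-penalised logistic with the penalty chosen by internal cross-validation.
Cumulative weights

$$w_i(k) = \frac{\mathbb{1}\{\text{followed regime, uncensored}\}}
{g_{\text{init}}(A_i \mid L_{i0}) \prod_{j \le k} \prod_c
\big(1 - p_c(j \mid \bar L_{ij})\big)}$$

are truncated at an absolute cap (20 for IPW, 200 inside the TMLE
fluctuation) or at the 99th percentile of the positive-weight
distribution; the percentile uses the order-statistic (type-1) quantile so
that at most 1% of positive weights can exceed the cap.

## Estimators

**Unadjusted / IPW product-limit.** The discrete hazard at interval $k$ is
the weighted event proportion among at-risk rows,
$\hat\lambda(k) = \sum_i w_i(k) Y_{ik} / \sum_i w_i(k)$, and
$\hat F(k) = 1 - \prod_{j \le k}(1 - \hat\lambda(j))$. With unit weights
and no censoring this is exactly one minus the Kaplan–Meier survival
curve. Standard errors use the influence curve of the weighted
product-limit estimator (delta method over interval hazards, weights
treated as known — conservative).

**Longitudinal TMLE.** For each reporting horizon $m$, the
sequential-regression (iterated conditional expectation) form: starting
from the event indicator by $m$, regress the iterated outcome backwards on
covariate history among at-risk, uncensored regime rows; at each step
fluctuate by a weighted intercept-only logistic update whose weight is the
cumulative inverse-probability product (the clever covariate enters as a
*weight*, not a regressor — more stable under large weights). The
fluctuation is solved as an exact root of the weighted score (bracketing
plus Newton polish), so the efficient-influence-curve equation
$|\text{mean(IC)}| \le 10^{-6}\,\text{sd(IC)}$ holds at every horizon by
construction; a non-convergent fluctuation falls back to the untargeted
plug-in with a flag, never silently. Patients with events before a step
carry value 1 deterministically. The per-horizon estimates are projected
to a monotone curve by isotonic regression when sampling noise inverts
adjacent horizons (flagged in the output).

Non-cardiovascular and unknown-cause deaths are treated as censoring — the
estimand is cause-specific, not subdistribution, risk; this is a known
limitation shared with the follow-up design.

**Contrasts.** RD at the reporting horizon; ARD as the *time-averaged*
difference $\frac1K \sum_k [F_1(k) - F_0(k)]$ (the area between the step
curves per unit follow-up — the area-in-risk-time-units reading is the
other candidate; the time-averaged convention matches the magnitude of
conventionally printed ARDs); NNT = $1/|RD|$ rounded, reported only when
the 95% CI excludes zero; an IPW hazard ratio from weighted pooled
logistic regression with interval main effect and patient-clustered
sandwich CI, flagged secondary because proportionality is not assumed.
Arms are estimated on a shared cohort, so contrast SEs use the influence
curve of the *difference*. Subgroup analyses refit every nuisance model
within the subgroup; the effect-modification test is the Wald z-test for
equality of two disjoint subgroups' RDs.

**Sensitivity analyses.** `truncation_sweep()` re-estimates contrasts
under alternative weight truncations without refitting nuisances;
`outcome_variant()` re-runs the pipeline under an expanded composite (for
example adding deaths of unknown cause to an expanded cardiovascular-death
definition); `g_value()` reports the smallest additive bias on the RD
scale that nullifies significance, $\max(0, |RD| - 1.96\,se)$ — a
documented stand-in for unmeasured-confounding sensitivity on the additive
scale, exposed so a different bias-shift definition can be slotted in.

## The synthetic EHR generator

Because the motivating studies rely on proprietary multi-site EHR data,
validation uses `generate_population()`: a discrete-time world with
confounded multinomial initiation, first-order Markov covariate dynamics
responding to current exposure, per-interval discontinuation and crossover
driven by time-varying covariates, informative disenrollment and
non-cardiovascular death (a configurable fraction relabelled
unknown-cause), and an exposure-dependent MACE hazard. All coefficients
apply to standardised covariates, so intercepts are log-odds at covariate
means. Ground truth comes from Monte-Carlo g-computation
(`true_counterfactual_risk()`): the same world with treatment forced,
deviations disabled (for sustained regimes) and censoring switched off.
Exact enumeration (`gcomp_enumerate()`) provides the oracle for tiny
finite-support instances.

Treatment and deviation decisions are made at interval starts and realised
*exactly* in the dispensing records: coverage episodes end on 30-day
boundaries, while fill days, supplies and refill gaps are jittered inside
episodes (including allowable 20–90 day gaps) so the exposure engine is
genuinely exercised. This keeps the engine-reconstructed exposure
identical to the simulated exposure — an intentional idealisation: real
dispensing data would add boundary noise the generator does not emulate,
so passing validation here demonstrates correctness of the machinery, not
robustness to exposure misclassification. Other simplifications: no site
heterogeneity, no coded diagnoses, Gaussian autoregressive dynamics for
continuous covariates, and measurement missingness completely at random at
a configurable rate.

Default scenario parameters (2 arms, 900-day horizon, ~0.4–0.8%
per-interval MACE hazard, ~5% per-interval discontinuation, ~1.5%
crossover, ~1.2% disenrollment, 10% missingness, 30/90-day supplies) were
chosen once as plausible for a type-2-diabetes pharmacoepidemiology
cohort; they are not calibrated to any published table.

## Validation studies and problem sizes

The test suite validates, among others: exact agreement of the exposure
engine with an independent day-scan oracle on 1000 random fill sets;
machine-precision equality of TMLE, saturated-g IPW and exact
g-computation on two-interval binary-confounder instances; agreement of
all three estimators with the Monte-Carlo oracle under randomization
(n = 2000, 10 intervals); double robustness at n = 4000 with oracle
propensities or oracle outcome regressions (trained on an independent
60 000-patient sample — exact iterated means are not closed-form under
the continuous dynamics); ≥90% coverage of IC-based RD intervals over 100
replicates at n = 1000; and nominal size of the effect-modification test
over 400 null replicates. These sizes were chosen as the smallest that
give the Monte-Carlo comparisons adequate power; the same code runs at
larger n unchanged.

## Known limitations

* Cause-specific (censoring) treatment of competing death, not
  Fine–Gray subdistribution risk.
* Static regimes only; no dynamic, covariate-responsive strategies.
* Per-cause censoring models are fitted marginally per cause and
  multiplied, approximating the joint uncensored probability (causes are
  rare and mutually exclusive, so the product error is second-order).
* The hazard-ratio output averages period-specific effects under
  non-proportionality and is reported as secondary only.
* IC-based SEs ignore nuisance-estimation variability, in the
  conservative direction for the weighted product-limit.
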