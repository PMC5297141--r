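---
title: "Monitoring procedural learning curves with Bernoulli CUSUM charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring procedural learning curves with Bernoulli CUSUM charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusumlc)
```

## The monitoring problem

When a new bronchoscopic sampling technique such as EBUS-TBNA (endobronchial
ultrasound-guided transbronchial needle aspiration) is introduced at an
institution, every operator — and the institution as a whole — traverses a
learning curve. A sampling attempt is judged *successful* when the aspirate
contains lymphocytes, granulomas or malignant cells (i.e. the node was
adequately visualised and sampled), and a *failure* otherwise; this outcome
definition isolates operator skill from false-negative cytology, which is a
limitation of the technique rather than of the operator. `cusumlc` monitors
such binary outcome sequences with a cumulative sum (CUSUM) control chart,
classifies each span of attempts as proficient, nonproficient or
inconclusive, segments the pooled institutional chart into chronological
proficiency intervals, and contrasts learning-environment covariates between
the intervals with multivariable logistic regression.

## The chart and its constants

The chart derives from a sequential probability ratio test of an acceptable
failure rate $p_0$ against an unacceptable rate $p_1$. With natural
logarithms throughout,

$$P = \ln(p_1/p_0), \qquad Q = \ln\!\big((1-p_0)/(1-p_1)\big),
\qquad s = \frac{Q}{P+Q},$$

each success moves the chart down by $s$ and each failure moves it up by
$1-s$. The decision intervals follow from the type 1 error $\alpha$ (falsely
flagging nonproficiency) and type 2 error $\beta$ (falsely flagging
proficiency):

$$a = \ln\!\big((1-\beta)/\alpha\big), \quad
  b = \ln\!\big((1-\alpha)/\beta\big), \quad
  H_0 = \frac{b}{P+Q}, \quad H_1 = \frac{a}{P+Q}.$$

The package default is $p_0 = 0.1$, $p_1 = 0.2$, $\alpha = \beta = 0.1$,
the design commonly used for EBUS-TBNA training:

```{r constants}
k <- cusum_constants(cusum_params(p0 = 0.1, p1 = 0.2, alpha = 0.1, beta = 0.1))
k
k$s
```

Full floating-point precision is kept internally; printing rounds to two
decimals. Note that some clinical applications of this design circulate
$s = 0.14$ and $1-s = 0.86$; the closed form above gives
$s = 0.1452$ and $1-s = 0.8548$ (so $s$ rounds to 0.15, not 0.14). The
truncated values appear to have been copied forward from earlier
presentations. `cusumlc` always uses the formula value — at 222 attempts the
accumulated difference is about one full chart unit, enough to shift a signal
by several attempts.

The chart starts at $C_0 = 0$ and has **no holding barrier at zero**: a
consistently successful operator's chart descends without bound. A reflected
(barrier-at-zero) CUSUM could never produce the descending curves that make
the downward proficiency signal observable.

## The two-boundary decision rule

An operator is declared *proficient* when the chart "descends across two
boundary lines", *nonproficient* when it "ascends across two boundary
lines", and remains *inconclusive* in between. Published descriptions of
this rule rarely say where the boundary lines sit. Two readings are
possible:

* a **fixed lattice** of horizontal lines spaced $H$ apart, with a signal
  when two lines are crossed in one direction; or
* a **running-extremum excursion**: a signal when the chart moves $2H$ away
  from its best (lowest or highest) point since the last signal.

`cusumlc` implements the excursion reading: proficiency is signalled at the
first attempt where the chart has descended $2 H_0$ below its running
maximum since the last signal (or the start), nonproficiency where it has
ascended $2 H_1$ above the running minimum. We chose it because it is
translation-invariant — a lattice rule's output depends on where the chart
happens to start relative to the arbitrary line positions — and because it
reproduces the qualitative behaviour expected of the rule (an operator who
is proficient from the start and later deteriorates is flagged on the fresh
upward excursion). The lattice reading is deliberately not configurable in
this version. Under the excursion rule and the default design, 38
consecutive successes are needed for a proficiency signal
($38 \times 0.1452 \ge 2H_0 = 5.419$) and 7 consecutive failures for a
nonproficiency signal.

Operational details:

* After any signal both running extrema reset at the signalling value, so a
  repeat signal requires a fresh $2H$ excursion.
* The declared state persists until the opposite signal; attempts before the
  first signal are inconclusive.
* No signal can fire on the first attempt, since
  $\max(s, 1-s) < 2\min(H_0, H_1)$ for any conventional design; this is
  asserted at run time and the constructor refuses degenerate designs that
  violate it.
* A classification run validates that the supplied trajectory's steps match
  the constants to $10^{-8}$, rejecting inconsistent inputs.

## Changepoint estimates versus signal attempts

A signal necessarily lags the true change in performance: with true failure
probability $p$, the chart drifts $|p - s|$ per attempt, so a $2H$
excursion takes roughly $2H/|p-s|$ attempts to accumulate (about 83
attempts for a true rate of 0.08 under the default design). Each segment
therefore also carries `changepoint_attempt`, the attempt at which the chart
attained the extremum the signalling excursion was measured from. This is
the standard CUSUM estimate of when the underlying rate actually shifted,
and it is the quantity to use when locating phase boundaries;
`interval_changepoints()` collects these estimates at every interval
transition.

## Chronological intervals

State segments are mapped to case-level intervals with the study semantics:
the initial inconclusive span (and any nonproficient span before proficiency
was first attained) is the *learning* interval; proficient spans are
*proficiency* intervals; a nonproficient span after proficiency was first
attained is a *worsening* interval. The case containing the signalling
attempt closes the preceding interval and the next case opens the new one.
Pooling across operators (`pool_institutional()`) orders attempts by
`date_order` with ties broken by case and node order, and runs one
continuous chart over the merged sequence.

## The learning-environment model

`build_analysis_frame()` joins each sampling attempt to its interval and
dichotomizes the case-level doses: midazolam at $\ge 10$ mg and fentanyl at
$\ge 300$ µg by default (both inclusive, both configurable; a 200 µg
fentanyl cutpoint is equally supported via the threshold argument — analyses
in this field have used both). `fit_environment()` then fits a multivariable
logistic regression of worsening-interval membership on the four covariates
(assisting attending, on-site cytopathologist, high midazolam, high
fentanyl), reporting odds ratios with Wald confidence intervals and
two-tailed Wald p-values.

Design choices worth knowing:

* **Unit of analysis.** The sampled node is the default unit, matching how
  sampling success is defined. Covariates are case-level, so nodes of one
  case are correlated; no clustering correction is applied (a `unit = "case"`
  mode is available) and every printed report carries a caveat to that
  effect.
* **Separation.** Interval contrasts on a couple of hundred attempts
  frequently produce covariate levels with zero events — maximum-likelihood
  estimates then diverge (a reported CI bound of exactly 0 in such analyses
  is a symptom). The fit flags separation per covariate (zero cell in the
  covariate-outcome cross-tabulation, or a diverging estimate) and
  `method = "firth"` provides a Jeffreys-penalized fit with finite
  estimates. The Firth route is implemented in the package (Newton iteration
  on the hat-adjusted score with step-halving on the penalized
  log-likelihood); its intervals are Wald intervals on the penalized
  information — profile-likelihood intervals are out of scope.
* **Missingness** is complete-case with a logged drop count; no imputation.
* **Degenerate inputs** raise explicit errors: a constant outcome
  ("degenerate outcome"), a constant covariate, or a perfectly collinear
  covariate pair (named in the message). The pipeline records such errors in
  its report bundle instead of aborting the run.
* **Alternative response.** `response = "failure"` regresses the sampling
  outcome itself on the covariates; this is the identifiable target when the
  data were generated with covariate effects on failure, and is what the
  simulation-based recovery checks use.

## The synthetic cohort generator

No node-level data accompany the published analyses this methodology comes
from, so the package generates cohorts with the same structure and known
ground truth. A `simulation_scenario()` fixes, per operator, a sequence of
phases (attempt count, baseline failure probability) and, per covariate, a
case-level prevalence (or a gamma dose distribution rounded to clinical
increments) and a log-odds effect on failure. Outcomes are drawn with a
logistic link, so phase baselines are the failure rates at covariate
reference levels. Each operator consumes a deterministic random sub-stream,
so adding an operator to a scenario leaves the others' draws untouched.

`replica_scenario()` emulates the motivating study's cohort: operators A, B
and C with 84, 89 and 49 sampled nodes over 47, 50 and 34 cases (222 nodes,
131 cases), case times evenly spaced per operator with bounded jitter so all
three progress in parallel, and a pooled four-phase chronology — learning
(baseline failure 0.35, 55 pooled attempts), proficiency (0.02, 80),
worsening (0.50, 35), proficiency (0.02, 52). The phase lengths and rates
are chosen so that each phase's *expected* excursion clears the $2H$
signalling threshold with margin: a proficient phase needs at least
$2H/(s - p)$ attempts to be detectable in expectation (about 44 attempts at
$p = 0.02$), a worsening phase at least $2H/(p - s)$ (about 16 attempts at
$p = 0.50$). Under these defaults the four-interval institutional pattern is
the typical realisation. The packaged fixture
(`inst/extdata/synthetic_replica_cohort.csv`) is one such cohort, generated
with seed 20080301 and shipped as plain CSV; it is synthetic and is labelled
as such.

What the generator does **not** emulate: lymph-node station, size or
difficulty (no such data exist in the motivating setting); operator-specific
narratives (all operators share the institutional phase fractions);
empirically calibrated covariate prevalences per interval (none are
published — the defaults are illustrative, e.g. dose distributions giving
roughly 28% of cases at $\ge 10$ mg midazolam). Passing tests on these
cohorts therefore demonstrate that the pipeline recovers structure it was
designed to see, not that real training data are this clean.

## Operating characteristics

`simulate_operating_characteristics()` estimates by Monte-Carlo the
probability that an operator with constant true failure rate is ever flagged
within a horizon, and the mean run length to first signal. The one-shot SPRT
error bounds ($\alpha$, $\beta$) do not apply exactly to a repeatedly
monitored two-boundary excursion rule, so the package's checks use the loose
Wald-style bound $\alpha/(1-\beta) + 0.05$; at the default design over a
200-attempt horizon the estimated false-flag rates are around 0.06 on both
sides, comfortably inside it.

## Numerical choices and problem sizes

* Trajectory/constants consistency tolerance $10^{-8}$; conservation of the
  final chart value holds to $10^{-12}$.
* The proficiency threshold is checked before the nonproficiency threshold
  at each attempt; the two cannot both fire on one attempt because a single
  step is smaller than either threshold (asserted).
* Firth iterations cap at 100 with convergence tolerance $10^{-8}$.
* Simulation sizes used by the package's checks: 10,000 replicates for
  operating characteristics, 200 replicates for four-phase segmentation
  recovery, 500 replicates for Wald CI coverage (nominal 95%, accepted
  92–98%), 60 replicates for covariate-effect recovery on 2,000-attempt
  cohorts.

## Known limitations

* The four-phase recovery scenario with 60–70-attempt proficient phases at
  baseline 0.08 sits *below* the excursion rule's detectability limit
  (expected descent $60 \times (s - 0.08) \approx 3.9 < 2H = 5.42$), so full
  four-interval recovery there succeeds in only about a fifth of replicates
  — a property of the decision rule at that effect size, not of the
  implementation. Detectable designs need longer proficient spans or lower
  within-phase failure rates, as in `replica_scenario()`.
* No risk adjustment: every attempt is weighted equally, with no per-node
  difficulty covariate.
* No resetting/FIR variants, and no likelihood-based changepoint estimation
  beyond the extremum estimator.
* The environment model ignores within-case correlation; with ~1.7 nodes per
  case its confidence intervals are somewhat anti-conservative.
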