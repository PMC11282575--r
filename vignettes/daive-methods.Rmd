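---
title: "Methods: Bayesian decision analysis for factorial optimization trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian decision analysis for factorial optimization trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(daive)
```

## The decision problem

A factorial optimization trial randomizes participants across all `2^k`
combinations of `k` two-level candidate intervention components. The
analysis question is not "which effects are significant?" but "which
combination of component levels should the optimized intervention use,
given preferences over several valued outcomes?". This package answers it
in four stages — saturated Bayesian factorial ANOVA per outcome, posterior
expected outcomes per candidate condition, a swing-weighted linear value
function over 0–1-scaled outcomes, and argmax selection with a systematic
weight-variation exercise around it. This vignette documents the model, the
defaults and the numerical choices, and what the synthetic-data tests do
and do not establish.

## The model

For outcome `j` and participant `i` in condition `c(i)`:

`y_ij = b_0j + x(c(i))' b_j + g_j z_i + e_ij,  e_ij ~ N(0, sigma_j^2)`

where `x(c)` holds all `2^k − 1` factorial terms (main effects, all
interactions up to order `k`) and `z_i` is an optional baseline measurement
of the outcome (used for the primary outcome; the secondary instruments in
the motivating trial were only administered post-intervention, so they get
no covariate). The model is saturated: with the covariate aside, its fitted
values are exactly the `2^k` cell means, which is what makes the expected
outcomes — not the individual coefficients — the natural decision quantity.

**Coding.** Factors are effect-coded by default (low = −1, high = +1, the
factorial-trial convention, under which the coded main effect is half the
high-vs-low difference and the balanced design matrix is orthogonal).
Treatment (0/1) coding is also supported because common regression software
defaults to it. Under the saturated model the two codings are
reparameterizations of the same cell means, so predictions — and therefore
every decision quantity downstream — are coding-invariant; the test suite
verifies this both for least squares (exactly) and for the posterior
(to Monte-Carlo tolerance).

**Priors.** Effect and covariate coefficients get independent `N(0, 5^2)`
priors on the raw outcome scale. Two interpretive choices are deliberate
and configurable:

* "`N(0,5)`" is read as SD = 5, not variance 5 (`prior_spec(coef_sd =
  sqrt(5))` gives the other reading). On outcomes whose attainable ranges
  are a few tens of points, SD 5 is diffuse relative to plausible
  component effects.
* The intercept gets a much wider `N(0, 50^2)` prior, so the diffuseness
  statement applies to effects rather than to the grand mean, whose scale
  is set by the instrument, not by the components.

The residual variance gets an inverse-gamma(0.01, 0.01) prior — near-flat,
and configurable since software defaults differ.

**Sampling.** The model is conditionally conjugate, so a self-contained
Gibbs sampler draws exactly from the full conditionals: coefficients given
`sigma^2` from the multivariate normal with precision `X'X/sigma^2 + P`
(`P` the diagonal prior precision — a ridge-type posterior), and `sigma^2`
given coefficients from the inverse gamma with shape `a + n/2`, rate
`b + RSS/2`. There is no tuning, no rejection and no asymptotics; mixing is
effectively immediate. Defaults: 4 chains × 2000 iterations, 1000 warmup,
overdispersed residual-variance starts. Split R-hat and an
autocorrelation-based effective sample size are computed per parameter; a
fit with any split R-hat ≥ 1.01 warns and is flagged `converged = FALSE`
rather than aborting — at desk scale a longer rerun is cheap, and the flag
propagates into the decision report so a provisional report is visibly
provisional. Note that with very short chains split R-hat has appreciable
Monte-Carlo noise of its own, so occasional flags at test scale are
expected behaviour, not sampler failure.

**Correctness anchors in the test suite.** Three independent oracles pin
the sampler down: (i) with no data, the coefficient posterior must
reproduce the prior; (ii) with the residual variance held fixed, draw
moments must match the closed-form ridge posterior; (iii) with diffuse
priors at the trial's full size, posterior means must match ordinary least
squares. A calibration study (50 simulated trials at 50 participants per
cell, the generator's default noise) checks that 95% credible intervals
cover the true coefficients at close to the nominal rate (the suite
requires ≥ 90%; the Monte-Carlo standard error of the estimated rate over
50 × 31 interval checks is about 0.6 percentage points).

## From posteriors to a decision

**Expected outcomes.** For each posterior draw and each condition,
`Ŷ = b_0 + x(c)'b` plus the covariate term at a reference value. The
baseline covariate is centered before fitting and predictions default to
covariate-at-mean, so they describe the average participant; any other
reference value can be supplied. No screening intervenes: every term,
however uncertain, contributes its posterior weight.

**Scaling.** Each outcome is mapped to 0–1 with 0 = worst and 1 = best.
The default *candidate-range* basis takes worst/best over the `2^k`
candidate posterior-mean outcomes, which is the reading of "worst/best"
that makes the weights act on the swings actually on offer in the trial;
a *fixed-range* basis (instrument bounds) is provided both as the
alternative reading and as the fallback when an outcome's candidate range
is zero (degenerate input, signalled as an error rather than silently
producing 0/0). A per-outcome direction flag handles lower-is-better
outcomes. Candidate-range scaling is invariant to positive affine
transforms of an outcome — so score units, per-item rescalings and the
like cannot change the decision — and this is tested as a property.

**Weights.** Swing points are normalized by their total. Exact weights are
the default; a nearest-0.1 rounding mode reproduces the published form of
the value function (100/50/25 → 0.6/0.3/0.1). Rounded weights need not sum
to 1, so both vectors are always reported. Ranking by value is invariant to
positive rescaling of the points in exact mode (tested).

**Value and selection.** `V(c)` is computed on posterior-mean expected
outcomes by default, matching the "expected value per condition" reporting
convention; a per-draw value distribution is available via `value_draws()`
for uncertainty display. Under fixed-range scaling the value function is
linear, so per-draw averaging and mean-then-value agree exactly (tested to
numerical precision); under candidate-range scaling the scaling itself is
draw-dependent and the two can diverge — the per-draw variant exists
precisely so that divergence can be inspected instead of hidden. Selection
is the argmax of `V`. Exact ties are broken toward the condition with fewer
components at their higher level (the smaller, cheaper-to-attend-to
package), then by condition index, and any tie is reported in the
selection object.

## Robustness of the decision

The weight-variation exercise re-runs the decision — never the model fits,
which do not depend on weights — over a grid of point vectors:

* **Step 1** incrementally reduces the least important outcome's points to
  a small floor, holding the others constant, then the next outcome
  (default grid: satisfaction 25 → 15 → 5, then knowledge
  50 → 40 → … → 10 → 5; 8 settings including the start).
* **Step 2** incrementally increases the more important secondary outcome
  to parity with the primary, then the remaining one (default: knowledge
  50 → 60 → … → 100, then satisfaction 25 → 35 → … → 85 → 100; 13
  settings).

Grids are stored as explicit point vectors rather than from/by/to rules: a
published grid may end with an irregular jump to the floor or to equality
(as the default satisfaction grid does), and an explicit vector encodes it
exactly; `points_grid()` builds the regular parts. Named preference
scenarios (single-outcome primaries, reversed secondaries, two-way ties)
are run the same way; outcomes given zero points are excluded from scaling
and weighting entirely. Every sweep row is reproducible by an independent
single-shot decision at that row's points — there is no state carried
across the sweep — and this, along with "a condition that weakly dominates
on every scaled outcome is selected at every grid point", is tested
against brute-force oracles.

## The synthetic cohort: what it emulates, and what it does not

`generate_trial()` draws participants per condition (defaults to the
motivating trial's randomization counts, 38–63 per condition, n = 1603),
computes each outcome as intercept + effect-coded factorial terms +
baseline term + residual, with residuals correlated across outcomes within
participant (default correlation 0.3, a plausible shared-respondent value;
the trial does not report one) and a truncated-normal baseline score. The
default truth gives the primary outcome a clear patient-input main effect
with a smaller side-effects effect and synergy, echoing the component
pattern the motivating trial reported — but the residual SDs, correlations
and effect sizes are *testing placeholders*, not estimates of the trial.
Outcomes are generated on their natural scales and can be discretized
(rounded and clipped to instrument ranges), and `generate_item_responses()`
disaggregates integer scores into item-level blocks — 5+5 belief items, 8
keyed true/false items, 11 satisfaction ratings — whose re-scored values
reproduce the stored outcomes exactly (a tested round trip with the
scoring module).

What passing tests on this generator establishes: the algebra of the
design, sampler and decision engine; parameter recovery and interval
calibration under a correctly specified Gaussian model; end-to-end
selection of a truth whose optimum is unique. What they do not establish:
behaviour under the features the generator deliberately omits — missing
data, non-normal and floor/ceiling-compressed outcomes (real instrument
scores are bounded and discrete; the model is Gaussian), item-level
measurement error structure, or preference elicitation. Real-data
conclusions inherit the usual caveats of the Gaussian ANOVA they rest on.

**A structural caution on near-ties.** If some components are truly null,
conditions that differ only in those components have *identical* true
expected outcomes, and their posterior-mean values differ only by
estimation noise — noise that candidate-range scaling does not shrink,
because it is scale-free. Within such an equivalence tier the argmax is
essentially arbitrary (with two real components and three null ones, the
specific "only the two real components high" condition heads its 8-member
tier with probability about 1/8, at any sample size). The selected
condition reliably *contains* the truly active components; which null
components ride along is noise. This is why the report always carries the
top-two gap, why ties are broken toward smaller packages, and why a tiny
gap should be read as "these versions are empirically interchangeable —
choose on package size or cost", not as evidence for the winner.

## Numerical choices and problem sizes

* Chain starts overdisperse the residual variance (×U(0.5, 2) around the
  sample variance); coefficients need no start since their full
  conditional is drawn first.
* The coefficient full conditional is sampled via the Cholesky factor of
  the precision matrix (one `chol()` of a `(2^k + 1 + q)`-square matrix per
  iteration; `X'X` and `X'y` are formed once per fit).
* Degenerate inputs fail loudly: rank-deficient design matrices,
  non-finite outcomes, zero candidate ranges, all-zero scenario points and
  sub-minimal item blocks are errors, not warnings.
* Reproducibility: one seed drives a whole fit (chains are consecutive
  segments of one stream); `run_daive()` offsets the seed per outcome, so
  a report is a deterministic function of (data, config).
* The test suite runs the trial-sized calibration study at 50 trials × 50
  participants per cell with 2 × 700-iteration chains, and the end-to-end
  recovery checks at 100 per cell with 2 × 600-iteration chains — sizes at
  which the Monte-Carlo tolerances documented in the tests hold with
  generous margins while the whole suite stays fast on a laptop.

## Known limitations

* Gaussian likelihood only: the bounded, discrete instrument scores are
  modeled as continuous, as in the motivating analysis. No hierarchical
  shrinkage across the 31 effects, no model comparison.
* The value function is linear in scaled outcomes; no cost term,
  nonlinear utilities or probabilistic preference elicitation.
* Whether rounding of weights is applied before or after value
  computation, and which scaling basis was used in the motivating
  analysis, are not documented there; the defaults (exact weights,
  candidate-range scaling) are stated choices, and both alternatives are
  runnable.
* The robustness exercise explores deterministic preference grids, not a
  formal sensitivity index over weight space.
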