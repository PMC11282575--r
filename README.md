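# daive

Decision analysis for intervention value efficiency (DAIVE) in factorial
optimization trials.

## The problem

In the multiphase optimization strategy (MOST), a multicomponent behavioral
intervention is optimized by running a factorial optimization trial: each of
`k` candidate components becomes a two-level factor, participants are
randomized to one of the `2^k` factor-level combinations, and the trial
estimates the individual and combined effects of the components. The
decision that follows — which combination of components to carry forward —
traditionally screened components one outcome at a time using significance
thresholds. DAIVE replaces that screening with a Bayesian decision analysis
that uses all of the empirical information and accommodates several valued
outcomes at once:

1. For each outcome `Y_j`, fit a **saturated Bayesian factorial ANOVA** —
   all `2^k − 1` main and interaction effects, diffuse independent `N(0, 5)`
   coefficient priors, optionally adjusting for a baseline measurement of
   the primary outcome.
2. From the joint posterior, compute the **posterior expected outcome**
   `Ŷ_j(c)` for every candidate condition `c` (no preliminary screening of
   effects).
3. Put the outcomes on a common 0–1 scale (0 = worst, 1 = best) and combine
   them with a **swing-weighted linear value function**

   `V(c) = w_1 Y_1(c) + w_2 Y_2(c) + … + w_J Y_J(c)`,

   where `w_j` = (swing points for outcome j) / (total points). With the
   canonical points 100/50/25 this gives weights 0.6/0.3/0.1 after rounding
   to the nearest 0.1.
4. Select the condition maximizing `V` as the **optimized intervention**,
   and probe robustness by systematically varying the points (reducing,
   then increasing, the secondary outcomes' importance; plus named
   preference scenarios).

The package implements this pipeline for the motivating application — a
2^5 trial of an information leaflet supporting adherence to adjuvant
endocrine therapy (AET) in breast cancer, with three outcomes: a
medication-beliefs differential (necessity − concerns, −20..+20), objective
knowledge (0–8 true/false items) and satisfaction with information (0–11
domains) — and for any other `2^k` two-level factorial trial. It is aimed at
intervention scientists analyzing their own optimization trials and at
methodologists studying the decision procedure itself: a synthetic-trial
generator with known ground truth (down to item-level instrument responses)
makes every stage testable without access to trial data.

The Bayesian fit uses a self-contained Gibbs sampler: the saturated
Gaussian model with independent normal coefficient priors is conditionally
conjugate, so the sampler alternates between the exact multivariate-normal
full conditional of the coefficients (a ridge-type posterior) and the
inverse-gamma full conditional of the residual variance. Split R-hat and
effective-sample-size diagnostics are computed for every parameter.

## Worked example

A full synthetic run of the leaflet trial: five components
(D = diagrams, B = benefits, SE = side-effects, C = concerns, P = patient
input), 32 conditions, the trial's per-condition sample sizes (n = 1603),
and a truth in which patient input and side-effects carry real effects.

```r
library(daive)

design <- leaflet_design()
trial  <- generate_trial(design, leaflet_truth(), seed = 1)

report <- run_daive(
  trial, design,
  outcomes   = c(beliefs = "beliefs", knowledge = "knowledge",
                 satisfaction = "satisfaction"),
  points     = c(beliefs = 100, knowledge = 50, satisfaction = 25),
  covariates = list(beliefs = "baseline"),
  config     = sampler_config(chains = 4, iter = 2000, warmup = 1000, seed = 1),
  sweep_plan = leaflet_sweep_plan(),
  scenarios  = leaflet_scenarios())
report
#> DAIVE decision report
#>   outcomes: beliefs, knowledge, satisfaction
#>   weights (exact): beliefs=0.571, knowledge=0.286, satisfaction=0.143
#>   selected condition: D, B, SE, P (V = 0.895)
#>   runner-up: B, SE, C, P (V = 0.822, gap 0.073)
#>   weight sweeps: 21 settings, selections: D, B, SE, P; SE, P
```

The selected condition is the leaflet version with diagrams, benefits,
side-effects and patient input at their higher levels; its expected value
0.895 is the weighted sum of its scaled outcomes, and the small gap to the
runner-up (0.073) quantifies how close the decision is. The ranking behind
it:

```r
head(as.data.frame(report$decision$value_table)[, c("rank", "label", "value")], 5)
#>   rank          label value
#> 1    1    D, B, SE, P 0.895
#> 2    2    B, SE, C, P 0.822
#> 3    3 D, B, SE, C, P 0.793
#> 4    4           C, P 0.785
#> 5    5          SE, P 0.750
```

Effect summaries per outcome mirror the trial's credible-interval figures;
here the generating `patient` main effect (truth 0.8) is clearly recovered:

```r
s <- summarize_effects(report$fits$beliefs)
s[s$term == "patient", ]
#>      term mean   sd lower upper excludes_zero
#> 5 patient 0.91 0.13  0.65  1.17          TRUE
```

Swing weighting itself is a one-liner:

```r
swing_points_to_weights(c(beliefs = 100, knowledge = 50, satisfaction = 25),
                        "nearest_0.1")
#> Swing weights (nearest_0.1 mode)
#>          beliefs knowledge satisfaction
#> points  100.0000   50.0000      25.0000
#> exact     0.5714    0.2857       0.1429
#> rounded   0.6000    0.3000       0.1000
```

`report$step1`, `report$step2` and `report$scenarios` hold the robustness
tables (points per outcome → selected condition), shaped like the published
sweep tables; `compare_selections()` reports the symmetric difference
between two selected component sets.

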