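---
title: "Modelling a published literature under selective publication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a published literature under selective publication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litsim)
```

## The model

`litsim` simulates the literature a research field publishes when every
positive claim rests on a null-hypothesis significance test and only
significant results are published. One iteration of the simulation is one
experiment:

1. **Effect draw.** A true effect size `ES` (a standardized mean
   difference, Cohen's *d*) is drawn from the field's effect-size
   distribution. The effect is *true* when `|ES|` strictly exceeds the
   minimum effect of interest (default 0.5, a medium effect), and *null*
   otherwise. The threshold is arbitrary but necessary: it is what lets a
   continuous world be scored in the true/false vocabulary of the
   diagnostic-screening framework.
2. **Sampling.** A control sample is drawn from N(0, 1) and a treatment
   sample from N(ES, 1), both of size `n`. Because the within-group SD is
   fixed at 1, the raw mean difference is on the *d* scale.
3. **Test and publication.** A two-tailed pooled-variance Student's t-test
   (df = 2n − 2) compares the groups. If p < α (default 0.05) the finding
   is published with the mean difference as its effect estimate. If not,
   with probability 1 − *b* it is shelved; with probability *b* (the
   *bias*) the experiment is re-run — fresh samples, same effect and n —
   until significance is reached in either direction, and that final result
   is published. Bias stands in for every practice that turns a negative
   result into a publishable positive one (p-hacking, analytic
   flexibility, outcome switching); re-running experiments is simply its
   concrete implementation here.
4. The loop repeats until the literature holds a fixed number of published
   findings (5,000 by default).

Publication does not consider the estimate's size by default: a
significant estimate below the minimum of interest is still published,
which is how significance-only fields behave. The alternative rule
`significance_and_magnitude` additionally requires `|estimate| >
min_effect` before a result (first-run or re-run) can be published.

## Effect-size distributions

Effects follow a mixture of two normals: component A is N(0, `sd_a`),
component B is N(`mu_b`, `sd_b`) with mixture weight `w_b`. An SD of zero
is treated as an exact point mass, not a narrow normal, so the dichotomous
model has literally no variation within its "true" and "null" classes.
The five named models:

| model             | sd_a   | mu_b | sd_b | free parameter |
|-------------------|--------|------|------|----------------|
| dichotomous       | 0      | 1    | 0    | w_b            |
| two_peaks         | 0.1    | 1    | 0.1  | w_b            |
| overlapping_peaks | 0.3    | 1    | 0.3  | w_b            |
| two_normals       | 0.1    | 0    | 1    | w_b            |
| single_normal     | varies | 0    | 0    | sd_a           |

The free parameter controls the **prevalence of true effects**
`P(|ES| > min_effect)`, which has a closed form from normal tail masses.
For weight-controlled models the prevalence is linear in `w_b`, so
`solve_weight_for_prevalence()` is exact; achievable prevalences are
bounded by the two components' own tail masses (`prevalence_bounds()`).
Two consequences matter in practice:

* the two-normals model cannot exceed `2 * (1 - pnorm(0.5))` ≈ 61.7%
  prevalence, because that is all the mass its wider N(0, 1) component has
  beyond 0.5 — so a 66.7%-prevalence scenario is reported as unachievable;
* the overlapping-peaks model cannot go below ≈ 9.56%, the tail mass of
  its N(0, 0.3) component, so very-low-prevalence scenarios (0.1%) are
  unachievable for it.

For the single normal, `solve_sd_for_prevalence()` inverts
`2 * (1 - pnorm(min_effect / sd))` directly; any prevalence strictly
between 0 and 1 is attainable.

`build_table1_scenarios()` resolves nine canonical research scenarios
(power × pre-study odds × bias) against all five models. Scenario
prevalences that fall outside a model's interval become explicit skip
records — with one refinement: a target within half a percentage point of
the interval (the 9.09% scenarios against the 9.56% overlapping-peaks
floor) is clamped to the boundary, because scenario parameters are meant to
approximate the stated odds, not to hit them exactly. The
`prevalence_solved` column always records what was actually attained, and
the simulation separately reports the empirical (achieved) prevalence of
the effects it drew.

## Power and sample size

The sample size is resolved **once per literature**, not per effect: the
field sizes its experiments for a *typical* true effect, namely the mean
absolute effect among true effects, `E[|ES| | |ES| > min_effect]`
(`typical_true_effect()`). The absolute value is essential — for models
symmetric about zero the signed conditional mean is 0 and could not anchor
a power calculation. The conditional mean has a closed form from truncated
normal moments; a Monte Carlo variant (100,000 draws) exists to mirror
sampling-based estimation of the same quantity and as a cross-check.

Power itself is the exact two-sided power of the equal-variance two-sample
t-test, via the noncentral t distribution (df = 2n − 2, noncentrality
`effect * sqrt(n/2)`), including the (tiny) wrong-tail rejection
probability. `sample_size_for_power()` returns the smallest integer n ≥ 2
meeting the target, so the achieved power slightly exceeds the nominal one;
both are reported (`achieved_power`), since at small n the granularity can
be substantial (e.g. 20% nominal power is often achieved at 25–30%).

Because the single-normal model raises its typical true effect as
prevalence grows (larger SD ⇒ larger conditional mean), powering for the
typical effect makes its experiments relatively less sensitive at high
prevalence. The `power_reference` option (`"min_effect"`,
`"twice_min_effect"`) reproduces the fixed-reference variants used to
control for this.

## Scoring the literature

All metrics condition on publication (full publication bias: every
published finding is a positive claim).

* **PPV** — fraction of findings that are true positives: `|true ES| >
  min_effect` *and* the estimate has the true effect's sign. A significant
  estimate with the wrong sign counts as a false positive even when the
  effect is true.
* **Type S rate** — fraction of findings whose estimate has the wrong
  sign, over all published findings regardless of the threshold. Undefined
  when a true effect is exactly 0, hence unavailable for the dichotomous
  model (an error from `type_s_rate()`, `NA` in summaries).
* **Type M (exaggeration)** — `estimate / true_es` among sign-correct
  findings only (wrong-sign findings are excluded, not folded by absolute
  value); summarized by median and quartiles. Quantiles use R's default
  linear interpolation between order statistics (type 7); the convention is
  stated because medians/IQRs of heavy-tailed ratios depend on it more than
  one would like.
* **p-curve** — histogram of published p-values on (0, α], default bin
  width 0.005 (10 bins), plus the median published p. A literature of
  nulls pushed to significance yields a flat curve; evidential value shows
  as right skew. The median p falls as the PPV rises, which is what makes
  p-value distributions a usable diagnostic of a field's health.

## Randomness and reproducibility

Each simulation consumes a single RNG stream seeded from `config$seed`
(via `withr::with_seed`, so the caller's RNG state is untouched): effect
draw, then control and treatment samples, then the bias coin-flip and any
re-runs, in that fixed order. Batch runners derive one independent seed
per cell from the master seed (`(seed + 104729 * index) mod 2147483647`),
so any cell of a table or sweep can be reproduced in isolation. The bias
loop carries a safety cap (default 10^6 re-runs) that turns an almost
surely unsatisfiable publication rule into an informative error instead of
a hang.

## Numerical and design choices

* Degenerate mixture components are exact point masses; `|ES| =
  min_effect` counts as false (a measure-zero event for continuous
  models).
* The t statistic is computed directly from the pooled variance rather
  than through `stats::t.test()`, purely for speed in the inner loop — a
  literature can require millions of t-tests once bias re-runs are
  counted; the test suite verifies exact agreement with
  `stats::t.test(var.equal = TRUE)`.
* Significance is strict (`p < alpha`), matching the publication rule's
  wording rather than the weak inequality.
* The analytic screening PPV (`ioannidis_ppv()`) is evaluated in closed
  form, never simulated; the dichotomous simulation is its Monte Carlo
  counterpart, and the two agree within binomial error once the analytic
  formula is fed the *achieved* (integer-n) power.

## What the generator does and does not emulate

The simulated literatures realize the model's own assumptions: normal
outcomes with known unit variance, equal group sizes, a single fixed
design per field, complete publication bias, independent experiments, and
bias implemented as honest re-runs. Passing tests therefore show that the
implementation reproduces the model's consequences — higher PPV with
power and prevalence, lower with bias; sign errors vanishing as prevalence
approaches 1; exaggeration near 1 at high power and prevalence — not that
real literatures behave this way. Real data add publication of negative
results, replications, heterogeneous designs, correlated hypotheses and
non-Gaussian effect distributions, all outside this model's scope.

Default problem sizes follow the study conditions: 5,000 published
findings per literature for scenario tables (1,000 is a common choice for
sweep curves). The package's own test suite exercises the same machinery
at 200–5,000 findings per literature, which keeps the full suite under a
minute while leaving Monte Carlo error well inside the tested tolerances
(binomial SE at 5,000 findings is ≈ 0.6 percentage points at PPV 80%).

## Known limitations

* Prevalence cannot be varied independently of the effect-size
  distribution's shape in continuous models: moving `w_b` or `sd_a`
  changes both, and results at "the same" prevalence are not otherwise
  comparable across models.
* The exaggeration factor explodes for true effects near zero (ratios are
  unstable in the denominator), which is faithful to its definition but
  means type M medians are sensitive to the distribution's mass near zero.
* Bias is a single mechanism (re-run until significant); other
  questionable practices with different p-value footprints are not
  distinguished.
* Effects are mean differences from two-sample t-tests; other designs are
  represented only insofar as their standardized effects behave similarly.
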