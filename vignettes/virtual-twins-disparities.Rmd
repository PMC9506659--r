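---
title: "Virtual-twins subgroup discovery for treatment-completion disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-twins subgroup discovery for treatment-completion disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtdisparity)
```

## The problem and the method

National discharge registries for substance use disorder (SUD) treatment,
such as the U.S. TEDS-D public-use files, record one coded categorical row
per discharge episode: demographics, substance-use characteristics,
treatment characteristics, and a seven-category discharge reason whose
"treatment completed" level defines the binary completion outcome
\(Y_i \in \{0, 1\}\). A disparity question asks whether a binary attribute
\(T_i\) — being white non-Hispanic, having wage income, having no
co-occurring mental health disorder, and so on — shifts the probability of
completion, and *for whom* the shift is largest.

Immutable attributes cannot be randomized, so the package implements the
two-stage *virtual twins* procedure:

1. **Stage one.** Fit a flexible probability model
   \(\hat p(x, t) \approx P(Y = 1 \mid X = x, T = t)\) on the analysis
   sample, with covariates one-hot encoded and the derived indicator
   \(T\) included as a feature. For every record predict twice — once with
   the indicator forced to 1 and once to 0, all other covariates untouched
   (the record's "counterfactual twin") — giving
   \(P_{1i}\), \(P_{0i}\), and the per-record difference
   \(Z_i = P_{1i} - P_{0i}\).
2. **Stage two.** Fit a small regression tree to \(Z\) over the remaining
   covariates (the disparity attribute and its source variables are masked).
   Node means of \(Z\) are subgroup-specific probability differences; node
   sizes are fractions of the analysis sample. Nodes covering at least 1%
   of the sample form the subgroup report.

Four stage-one learners are compared over repeated 70/30 train/test splits
(10 by default, seeds `base + 0..9`, splits shared across learners):
a probability random forest, gradient boosted trees, a neural network, and
logistic regression. The finalist maximizes mean held-out AUC, with ties
broken by mean F1, then mean accuracy, then declaration order. Accuracy,
precision, recall and F1 use a 0.5 threshold; AUC is the rank statistic
with tied scores counted half-concordant.

## Data model

A **codebook** (YAML) declares each variable's integer category codes,
labels, missing codes, and whether the variable may be absent from a file.
Reading a cohort validates every cell and normalizes all missing codes
(TEDS-D uses `-9`) and empty cells to one internal marker, so analysis code
never sees dialect-specific codes. The packaged codebook reproduces the
published 2017–2019 cohort description (30 variables from the published
table, plus the optional discharge-service and health-insurance variables).

Nine built-in disparity contrasts derive \(T\): white non-Hispanic (race
*and* ethnicity), wage/salary income, no co-occurring disorder, male,
no health insurance, veteran, age under 35, primary alcohol, and primary
opioid (heroin, non-prescription methadone, other opiates/synthetics).
A contrast is a conjunction of variable-in-category-set clauses; custom
contrasts use the same grammar. Records whose source variables are missing
have a missing indicator and are dropped from that contrast's analysis —
\(T\) is the causal attribute, and imputing it would manufacture twins.

Two design choices deserve emphasis:

* **The stage-one design excludes the contrast's raw source variables.**
  If `RACE` and `ETHNIC` stayed in the design next to the derived
  white-non-Hispanic indicator, a flexible model could reconstruct the
  indicator from them and route its effect around the flipped column,
  making the counterfactual flip inert. A switch
  (`include_sources_stage_one = TRUE`) restores them for sensitivity
  analyses.
* **Missingness indicators are ordinary split candidates** in stage two:
  missingness may define real subgroups, and the published cohort has
  variables with more than 20% missing (DSM diagnosis, discharge-time use
  frequency, discharge living arrangement).

## The difference tree

Stage two is a binary regression tree minimizing within-node variance
of \(Z\). Every split is "variable ∈ category set" versus the complement.
For a single numeric response the optimal category subset is found exactly
by the classical reduction: order the node's observed categories by their
mean \(Z\) and scan the \(K - 1\) contiguous cuts. Growth stops at
`max_depth` (default 4, matching the shallow published trees), when a
child would fall below `min_leaf_frac` (default 0.5% of the analysis
sample), or when the best split's variance reduction
\(\Delta\mathrm{SSE} / n_{\text{root}}\) drops below the complexity
penalty `cp` (default `1e-4`, on the squared scale of \(Z\)). Ties in the
search resolve toward the earlier design variable and the smaller cut, so
fits are deterministic. A constant \(Z\) yields a root-only tree. The
reported rule names the smaller category side; the printed and DOT renders
put the "yes" branch first, show node means to three decimals and node
sizes as percent of sample, and shade DOT nodes from light (low) to dark
(high).

Two invariants are enforced by tests: the leaf means conserve the root
mean (\(\sum_{\text{leaves}} \text{frac} \times \bar Z = \bar Z_{\text{root}}\)
to 1e-9), and on small designs the root split equals an exhaustive search
over all category subsets.

## The synthetic cohort generator

Because the full registry extract is multi-gigabyte and external, the
package validates itself on synthetic cohorts with *known* ground truth.
Covariates are drawn independently from per-variable marginals defaulting
to the published full-sample frequencies (649,479 discharges); the binary
attribute is Bernoulli; and the outcome follows a logistic model

\[
\eta(x, T) \;=\; \beta_0 + \beta_T T + \textstyle\sum_v \beta_x[v, x_v]
  + \sum_k \gamma_k \, T \, \mathbf{1}[x \in S_k],
\]

with successes written as the "treatment completed" reason and failures
drawing a non-completion reason from the published not-completed mix, so
both outcome codings behave as on real data. The true twin difference
\(z_{\text{true}} = \sigma(\eta(x,1)) - \sigma(\eta(x,0))\) is available
per record, and `expected_subgroup_z()` integrates it exactly over any
subgroup using the independence of the covariates.

What the generator does *not* emulate: covariate dependence (real
discharge variables are strongly associated — admission and discharge
service settings, primary substance and DSM diagnosis), repeated
discharges of one person, informative (MAR/MNAR) missingness, and
year-to-year drift. Passing tests therefore demonstrate that the
machinery recovers known effects under clean conditions, not that the
published subgroups are correct; optional pairwise dependence could be
added without changing the ground-truth computation, at the cost of a
less tractable closed form.

## Reference scenarios and their calibration

Two fixed scenarios drive the validation suite (`synthetic_scenario()`),
both at \(n = 20{,}000\) with eleven covariates (gender, age, admission
and discharge service settings, length of stay, admission and discharge
use frequency, primary substance, referral source, prior episodes,
discharge employment), an intercept placing the baseline completion rate
at the published 33.8%, main effects on discharge use frequency, prior
episodes and length of stay, and attribute prevalence 0.435 (the
no-co-occurring-disorder share):

* **planted** — one interaction \(\gamma\) on the subgroup "no use in the
  past month at discharge" (54% of records), with \(\gamma\) solved
  numerically so the exact in-subgroup mean of \(z_{\text{true}}\) is
  0.080; outside the subgroup \(z_{\text{true}} = 0\). The subgroup
  variable has three categories, all with large mass, which matters: a
  category rarer than the minimum leaf size (e.g. the 0.05%
  hospital-rehab service category) can never be isolated by an admissible
  split, so it attaches arbitrarily to one side and exact recovery of a
  predicate involving it is structurally impossible.
* **null** — the same model with \(\beta_T = 0\) and no interaction, so
  \(z_{\text{true}} \equiv 0\).

The eleven-variable restriction keeps a single replicate (cohort, forest,
twins, tree) near fifteen seconds, so ten-seed sweeps of both scenarios
fit comfortably in a test run.

**Twin-model choice for the validation sweeps.** The sweeps use a
probability random forest with `mtry = floor(p/3)` rather than the
classification default \(\sqrt{p}\). With ~90 one-hot columns,
\(\sqrt{p} \approx 9\) means the single indicator column is offered to a
split roughly one node in ten, and the counterfactual flip is visibly
attenuated; the regression-style `mtry` restores most of the indicator's
effect. Gradient boosting tracks the in-sample subgroup mean slightly
better but, refit on the full sample, overfits individual outcomes and
produces covariate-structured noise in \(Z\) that the tree mistakes for
subgroups under the null. The forest with enlarged `mtry` satisfies both
sides of the validation suite: the planted predicate is recovered in at
least 8 of 10 seeds with the recovered subgroup mean within 0.02 of
truth, and null replicates produce a spurious leaf
(\(|\bar Z| > 0.02\)) in at most 2 of 10 runs. The general-purpose
`learner_spec("random_forest")` default keeps \(\sqrt p\) for
classification use; the sweep's choice is explicit in
`scenario_replicate()`.

**Mild residual attenuation is expected.** Even the Bayes-optimal
stage-one fit can only track the *sample's* empirical difference (a
~0.009 standard error at this \(n\)), and regularized ensembles shrink
further, so recovered subgroup means sit slightly below the planted
truth on average. This is a property of virtual twins generally:
stage-two node means are conservative estimates of the true subgroup
effect.

## Other numerical choices

* `Z` defaults to "mode A": one final model refit on the full analysis
  sample, matching node percentages to the full sample. "Mode B"
  (averaging twin predictions over the ten split models) is available via
  `z_mode = "average"`; neither mode is privileged by the method's
  description, and mode A is cheaper and deterministic given one seed.
* The neural-network learner is a single hidden layer of 64 logistic
  units (`nnet`), weight decay `1e-4`, 100 BFGS iterations. It is the
  costliest learner and intended for the comparison roster at moderate
  design widths, not as the twin model.
* SMOTE operates in the one-hot space: each synthetic row interpolates a
  minority row toward one of its `k = 5` nearest minority neighbors and
  each variable block is snapped back to a valid one-hot pattern (base
  row's category below interpolation weight one half, neighbor's above).
  With purely categorical predictors this is resampling-with-snapping,
  which is exactly what parity balancing needs here; it is applied to
  training splits only.
* Permutation importance permutes all columns of a variable jointly
  (blocks stay valid patterns) and reports the mean AUC drop; tree
  ensembles use impurity/gain importance. Per-variable importances are
  the sum over the variable's columns, scaled so the maximum is 1.
* Model selection logs all per-learner means; selection is invariant to
  roster order except through the documented tie-break.

## Known limitations

* Node means carry no uncertainty quantification (none is defined by the
  method); the null-safety sweep bounds false-positive subgroup signal
  empirically instead.
* Stage-two trees are not honest/sample-split trees; with the full-sample
  refit, \(Z\) and the tree share data, which is the method as described
  but inflates in-sample node means slightly.
* The generator's independence assumption makes planted effects easier to
  find than real, correlated effects of the same size.
* Exact predicate recovery is only meaningful for subgroups whose
  categories all exceed the minimum leaf size (see the planted scenario).

## Problem sizes used by the validation suite

Table arithmetic runs on the packaged 184-row count fixture. Conservation
uses 100 random designs of 100–400 records; exhaustive-search equivalence
uses 50 designs of 80–200 records with ≤3 variables × ≤4 categories.
Recovery and null sweeps use ten seeds each at \(n = 20{,}000\) with the
eleven-variable scenario. End-to-end pipeline tests run at
\(n = 800\)–1,500 with two learners and two split iterations.
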