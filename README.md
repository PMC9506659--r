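# vtdisparity

Two-stage **virtual twins** analysis of disparities in substance use
disorder (SUD) treatment completion, for coded categorical discharge
cohorts in the TEDS-D public-use dialect (one row per discharge episode,
integer-coded variables, `-9` for missing). The package is aimed at health
services and disparities researchers who want to go beyond "is there an
average gap?" to "which subgroups carry the gap, and how large is it
there?" — without hand-rolling the counterfactual machinery.

## The method

Let \(Y_i \in \{0,1\}\) be treatment completion (discharge reason
"treatment completed" = 1), \(X_i\) the coded covariates, and
\(T_i \in \{0,1\}\) a binary disparity attribute derived from the record
(e.g. white non-Hispanic vs. rest, wage income vs. rest, no co-occurring
mental health disorder vs. co-occurring).

1. **Stage one** fits a flexible probability model
   \(\hat p(x,t) \approx P(Y=1 \mid x, t)\) — a probability random forest,
   gradient boosted trees, a neural network and a logistic regression are
   compared over ten 70/30 train/test splits, and the learner with the
   best mean held-out AUC (ties: F1, then accuracy) is selected. For every
   record the model is evaluated twice, with the attribute forced to each
   value and everything else untouched (the *counterfactual twin*):
   \(P_{1i} = \hat p(x_i, 1)\), \(P_{0i} = \hat p(x_i, 0)\), and

   \[ Z_i = P_{1i} - P_{0i}. \]

2. **Stage two** fits a small regression tree to \(Z_i\) over the
   remaining covariates (the attribute and its source variables are
   masked). Splits are "variable ∈ category set" vs. the complement, with
   the optimal set found exactly per variable by the sorted-means scan.
   Node means of \(Z\) are subgroup-specific completion-probability
   differences; node sizes are percentages of the analysis sample, and
   subgroups covering ≥ 1% of the sample form the report.

The package also provides: codebook-driven cohort I/O and validation with
a packaged TEDS-D 2017–2019 codebook, published-table descriptives by
completion stratum, nine built-in disparity contrasts, SMOTE balancing and
an alternate planned-discharge outcome coding as robustness variants, and
a synthetic cohort generator with closed-form ground-truth twin
differences (logistic outcome model with plantable subgroup interactions)
for end-to-end validation.

## Worked example

A synthetic 20,000-discharge cohort with a planted disparity: the focal
group completes treatment 8 percentage points more often (true mean
difference 0.080) *only* among discharges with no primary-substance use in
the month before discharge (54% of records); elsewhere the true difference
is 0.

```r
library(vtdisparity)

cfg <- synthetic_scenario("planted", n = 20000)
s   <- sample_cohort(cfg, seed = 1)

report <- run_full_analysis(
  s$cohort,
  contrasts = list(synthetic_attr = synthetic_contrast()),
  learners  = list(random_forest = learner_spec("random_forest", mtry = 30)),
  iterations = 3, seed = 1
)
res <- report$contrasts$synthetic_attr
cat(render_tree(res$tree, "text")[1:2], sep = "\n")
```

```
mean_z=0.046 (100%) n=20000 | split: FREQ1_D in {1}?
  [yes] mean_z=0.087 (54%) n=10879 | split: SUB1 in {3,5,6,9,10,11,13,17}?
```

The tree's root split recovers the planted subgroup exactly — "frequency
of use at discharge = no use in past month" — and its node mean (+0.087,
54% of the sample) estimates the planted +0.080. The overall mean
difference (+0.046 across 100% of the sample) is the planted effect
diluted over the full cohort. Deeper nodes (e.g. +0.123 over 24% of the
sample) refine the subgroup along noisy secondary splits; with no planted
sub-structure they hover around the in-subgroup truth. Held-out metrics
for the selected forest (accuracy 0.596, AUC 0.593, F1 0.367) are modest
by design: completion here is mostly noise except for a few main effects,
which is exactly when subgroup discovery on \(Z\) (not raw accuracy) is
informative.

On a real extract you would instead call
`read_cohort("teds_d.csv")` and run the nine built-in contrasts:

```r
report <- run_full_analysis(read_cohort("teds_d.csv"),
                            contrasts = builtin_contrasts(),
                            output_dir = "results/")
```

which writes, per contrast, the learner-comparison metrics, selection
summary, scaled variable importance, subgroup tables (main and
low-support), and the tree in text and Graphviz DOT form.

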