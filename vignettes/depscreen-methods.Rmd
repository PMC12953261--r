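---
title: "Methods: sequential multimodal depression screening and biomarker subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential multimodal depression screening and biomarker subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The problem

General practitioners see many patients whose depressive disorders go
unrecognized. Questionnaire screens such as the PHQ-9 help, but a single
cutoff wastes information: most patients can be classified confidently from
a handful of items, while a minority genuinely needs richer assessment.
`depscreen` implements a screening study design built around that
observation: modality-specific base classifiers, a *sequential* model that
defers uncertain cases to richer feature sets via propagation thresholds, a
traffic-light presentation of prediction certainty, and a data-driven
subtyping of the depressed group from biomarkers alone.

Because participant-level clinical data of this kind are not publicly
deposited, the package ships a synthetic cohort generator calibrated from
published group-level descriptive statistics. All tests and the worked
examples run on generated cohorts; what that does and does not demonstrate
is discussed at the end.

## The synthetic cohort generator

`sample_cohort()` draws a cohort of `n_total` participants with exactly
`n_depressed` positive diagnosis labels (a deterministic split, not a
binomial draw; the default 90/581 mirrors the calibration cohort's 15.5%
prevalence). Features fall into modality blocks — questionnaire items and
totals (PHQ-9, WHO-5, WHODAS 2.0, PHQ-15, GAD-7, UCLA-3, PC-PTSD, LSNS-6,
observer-rated MADRS), blood biomarkers, heart-rate-variability (HRV) and
bioimpedance measures, anthropometrics/vitals, and biographic variables.

The calibration fixture (`inst/extdata/cohort_profiles.yaml`) records, per
feature, the marginal mean and standard deviation (continuous) or category
probabilities (categorical) for the depressed and non-depressed groups, and
per-subtype overrides for the biomarker panel. Within the depressed group
every participant carries one of four latent subtypes — `Adaptive`,
`LateDepression`, `ImmunoMetabolic`, `OverweightNonInflammatory` — with
sizes allocated by largest remainder proportional to 26/27/9/28.
Questionnaire parameters stay group-level for all subtypes, because the
published subtype profiles show no significant questionnaire differences;
age is included among the subtype overrides because the subtype profiles
differ strongly in age and the post-hoc labelling rule needs it.

Only marginal moments are published, so the joint distribution is a
modelling choice: continuous features within a modality block share a
single exchangeable correlation (default `rho = 0.3`), blocks are
independent, and draws are clipped to physiological plausibility bounds
kept in the data dictionary (Gaussian draws would otherwise produce
negative CRP or a heart rate of 400). Clipping slightly biases means of
features whose bounds sit within ~2.5 sd of the mean (CRP, the HRV spectral
powers, episode counts); the calibration tests therefore check only
features whose bounds are farther out. Questionnaire totals are drawn
first, rounded and clipped to the scale range, and then split over items by
a seeded uniform random partition (`allocate_item_scores()`): every
feasible item increment slot is equally likely, the items always sum to the
total, and the split is random rather than a deterministic rounding.

Missingness is missing-completely-at-random at a configurable per-cell
rate (default 0: the mechanism of the original cohort's missingness is
unknown, so nothing more structured is pretended). Identical generator
specs produce byte-identical cohorts.

## Fold-safe preprocessing

All preprocessing is fitted on a training split and applied unchanged to
held-out rows:

* **Rare-category aggregation** — categories below 5% training frequency
  merge into `"other"` (strict inequality: exactly 5% is kept); unseen
  categories at apply time also map to `"other"`.
* **KNN imputation** (`k = 7`) — distances are Euclidean over mutually
  observed coordinates, rescaled by the observed-coordinate count;
  continuous features are standardized by training mean/sd and categorical
  features contribute a 0/1 mismatch with weight one. A missing cell takes
  the mean (continuous) or mode (categorical, ties to the
  lexicographically first level) of the 7 nearest training rows observed on
  that feature. Whether the original analysis standardized before
  distances is unstated; we standardize, since raw scales would let
  laboratory units dominate.
* **Yeo-Johnson transformation** (clustering path only) — the exponent is
  fitted per feature by maximum profile likelihood over a bounded
  one-dimensional search on [-5, 5] with tolerance 1e-6; the transformed
  training columns are standardized. Constant features pass through with a
  warning.

## Base-model pipelines and the registry

Four pipelines cover the modality-specific models:

| id | stages | intended for |
|----|--------|--------------|
| P1 | gradient boosting only | small feature sets (< 10) |
| P2 | Boruta, then boosting | moderate feature sets |
| P3 | Boruta, greedy forward wrapper, then boosting | parsimonious clinical models |
| P4 | standardize, PCA (>= 80% variance), linear SVM + logistic calibration | highly inter-correlated panels (labs, HRV) |

Boosting hyperparameters are fixed (300 rounds, depth 3, learning rate 0.1,
subsample 0.8) rather than tuned: no tuning grid is published, and fixing
them keeps nested cross-validation honest and cheap. Class imbalance is
handled by balanced case weights, `n / (2 * n_class)`, everywhere a
classifier is fitted. The P4 margin parameter defaults to 1; its decision
scores pass through a held-in logistic calibration because the stacking and
sequential layers need probabilities. A predicted probability of exactly
0.5 is classified non-depressed, favouring specificity in a screening
context.

The registry (`model_registry()`) mirrors the published base-model table:
nine models with printed feature counts (9, 26, 36, 18, 15, 11, 19, 16, 15)
and pipelines (P1, P4, P4, P2, P3, P3, P3, P3, P1). Where the original
engineered feature list is not published, the registry
carries the full modality pool of the synthetic dictionary and the
pipeline's selection stage narrows it; the printed count is kept as
metadata. The `clinical_15` item list was frozen from one Boruta pass over
the WHO-5 + PHQ-9 + WHODAS-12 item pool on the reference synthetic cohort
and is flagged `synthetic_derived` — it is this package's stand-in, not the
original list.

## Feature selection

**Boruta.** Each of (by default) 100 iterations appends a row-shuffled
shadow copy of every feature, fits a 300-tree random forest with balanced
case weights, and scores a hit for every real feature whose out-of-bag
permutation importance beats the best shadow. Features are confirmed or
rejected by a two-sided binomial test on the hit count (alpha 0.05,
Bonferroni over features); leftovers resolve by comparing their median
importance to the median of the per-iteration shadow maxima. Permutation
importance is used rather than impurity gain: impurity gain of an
in-sample chance correlation persistently exceeds shadow level, which
inflates null confirmations. Even so, under a global null the single best
real feature is exchangeable with the per-iteration shadow maximum, so an
occasional confirmation of a lucky noise feature is intrinsic to the
shadow-comparison idea — roughly a third of pure-noise datasets confirm one
feature. The tests assert the bound actually achieved, not an impossible
zero.

**Greedy forward wrapper.** Starting empty, repeatedly add the candidate
that maximizes inner-cross-validated balanced accuracy of the boosted
model, ties to the lower candidate index; stop at the first improvement
below `epsilon` (default 0.001). A pure XOR pair — jointly perfect,
marginally uninformative — is unrecoverable by *any* forward-greedy search,
because the first step sees no signal; the recovery experiments therefore
plant a dominant interaction with weak main effects, and a brute-force scan
of all one- and two-feature subsets confirms the planted pair is optimal.

## Nested cross-validation and the screening baseline

`evaluate_nested()` runs 5 stratified outer folds; inside each
outer-training split, 5 stratified inner folds serve greedy selection,
stack training and threshold tuning. Everything — imputation, aggregation,
selection, calibration, tuning — is fitted on outer-train only, and each
outer-test split is predicted once. The report stores a hash of the
outer-test rows taken before and after fitting as an auditable leakage
check, and per-fold metrics are aggregated as their unweighted mean
(sensitivity, specificity, balanced accuracy = their mean, with depression
the positive class). The PHQ-9 baseline screens positive when the total
strictly exceeds 8 and is computed on the full cohort (whether the original
comparison was cross-validated is unstated; the full-sample choice is
documented here).

## Stacked and sequential models

The stacked model feeds member base-model probabilities — strictly
out-of-fold, enforced by a provenance flag — into a balanced-weight
logistic meta-learner.

The sequential model splits the `clinical_15` model's five most important
items into a first step and keeps the full model as the second. A case is
decided at a step when its certainty `max(p, 1 - p)` reaches the step's
propagation threshold; otherwise it propagates. Thresholds come from a
grid (default 0.50 to 1.00 in steps of 0.05; 1 means "never decide early")
tuned on inner cross-validation for mean balanced accuracy, ties broken by
the smaller propagated fraction — fewer per-case examinations — then by the
smaller threshold. The top-5 item list is derived once per outer-training
split; the second step is the full model retrained on all 15 items, not a
residual model. An optional third biomarker step is supported but disabled
by default, mirroring the study's finding that it added no accuracy.

Certainty bands use the half-open intervals [0.50, 0.67) (low, yellow
light), [0.67, 0.83) (medium) and [0.83, 1.00] (high); non-low certainty
renders red if depression is predicted and green otherwise. The printed
integer ranges 50–66/67–82/83–100 are read as displayed roundings of these
intervals. `traffic_light_report()` cross-tabulates colour by true class
with one-decimal percentages; `render_traffic_light()` pools red and green
as the high-certainty column per class.

## Subtyping the depressed group

Clustering consumes laboratory, HRV/bioimpedance and anthropometric
features only — a modality-tag filter enforces that no questionnaire enters
— imputed with the same KNN machinery on the depressed subset and
Yeo-Johnson transformed. `select_gmm()` scans components 2–8 against four
covariance structures (full, tied, diagonal, spherical), each fitted by
expectation-maximization with seeded k-means restarts plus a
hierarchical-agglomeration start, and reports AIC, BIC
(`-2 logL + df log n`, recomputed from the maximized likelihood and the
structure-correct parameter count) and the mean silhouette of the hard
assignments; BIC decides, ties to fewer parameters. Singular covariances
refit under a weak conjugate prior and are flagged. Profiles are compared
on imputed but untransformed values: Shapiro-Wilk on model residuals gates
one-way ANOVA (+ Tukey HSD) versus Kruskal-Wallis with
`eta^2 = (H - k + 1)/(n - k)` (+ Dunn post hocs, Bonferroni); categorical
variables get omnibus and pairwise chi-squares. Labels are rule-based on
cluster means: highest CRP with lowest SDNN and highest Baevskii index is
`ImmunoMetabolic`; highest remaining BMI is `OverweightNonInflammatory`;
oldest remaining is `LateDepression`; the rest is `Adaptive`.

One structural caveat deserves emphasis. The generator gives every subtype
the *same* within-block correlation, so subtype covariances differ only in
scale — exactly what the diagonal structure captures with far fewer
parameters. The likelihood gain of a per-component full covariance
(~0.05 nats per correlated pair per observation at rho 0.3) cannot offset
its BIC penalty until samples of several thousand, far beyond the planted
n = 360 recovery experiment. Model selection on generated data therefore
recovers *k* = 4 but prefers the diagonal structure; recovering the
full-covariance choice reported for the real cohort would require
subtype-specific correlation structure that no published table constrains.
The recovery experiments use the sixteen biomarkers with the largest
between-subtype shifts; at n = 360 the selected four-component solution
matches the planted subtypes at adjusted Rand index >= 0.7 in most seeds.

## Problem sizes and numerical choices

The shipped tests run generated cohorts of 200–581 participants for the
modelling stages, 4000–5000 for generator calibration (three standard
errors of the mean), 360 for subtype recovery, and reduced booster/Boruta
settings where the full defaults would add nothing but runtime; the
package defaults remain the full study settings. Seeds derive from one run
seed through a fixed integer hash (`derive_seed()`), so stages can be rerun
in isolation. Ties are resolved deterministically everywhere (feature
names ascending for importances, lower index for greedy candidates,
smaller propagated fraction then smaller threshold for policies).

## What the synthetic cohort can and cannot show

Passing tests on generated cohorts demonstrate that the machinery is
correct: calibrated marginals, leak-free fold discipline, threshold
optimization that trades accuracy against examinations, selection that
recovers planted structure, clustering that recovers planted mixtures.
They do not validate the clinical claims: the generator's
conditional-independence structure (one exchangeable correlation per
block, independent blocks) is far simpler than real psychometric data, its
subtype separations are exactly as printed rather than as messy as nature,
and synthetic discrimination performance (e.g., the near-0.93 balanced
accuracy of `clinical_15` on generated cohorts) reflects the planted
effect sizes, not expected field performance. Real-data conclusions
require the real cohort.
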