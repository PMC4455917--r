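---
title: "Mechanism-strength classifiers for anti-TNF non-response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-strength classifiers for anti-TNF non-response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mechsig implements a blood-transcriptome procedure for identifying
rheumatoid arthritis patients who are unlikely to respond to anti-TNF
therapy (e.g. infliximab) before treatment starts. This vignette is the
package's own account of the science: the model at each stage, its
assumptions, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the numerical
conventions adopted where the procedure leaves room.

## The problem

Roughly 30–40% of RA patients fail to respond to first-line anti-TNF
biologics. Because alternative biologics (abatacept, rituximab,
tocilizumab) have similar overall response rates, a pre-treatment test
that flags *likely non-responders* with high specificity lets those
patients start an alternative immediately, trading a modest sensitivity
for a high-confidence prediction. The input is a pre-treatment blood
gene expression profile; the output is a score in [0, 10] and an NR/R
call at a fixed threshold.

## Mechanism strength scoring

Rather than fitting thousands of individual genes, expression is
aggregated into *mechanisms*: prior-knowledge signed gene sets, each
gene tagged +1 or −1 according to whether it goes up or down when the
mechanism's upstream entity becomes more active. For mechanism $m$ with
measured member genes $G'_m$ and signs $s_g$, the strength in sample
$j$ is

$$\mathrm{strength}_{m,j} \;=\; \frac{1}{|G'_m|}\sum_{g \in G'_m} s_g\, d_{g,j},$$

where $d_{g,j} = x_{g,j} - \mathrm{median}_j(x_{g,\cdot})$ is the
gene's log2 expression referenced to the within-cohort median
(midpoint convention for even sample counts). Median referencing is the
only cross-platform harmonisation performed: when every sample is
expressed relative to its own cohort's median patient, log-ratio
measurements from different microarray platforms are approximately
comparable. The assumption that median patients are similar across
cohorts weakens when cohorts are small or have very different
responder fractions — a real limitation inherited by anything trained
on the stacked scores.

Because platforms measure different gene subsets, $|G'_m|$ varies by
cohort; the denominator counts only the genes *used*, keeping scores on
the log2 fold-change scale. Mechanisms with fewer than `min_genes`
(default 4) measured genes in any cohort are excluded up front by
`filter_by_coverage()`. The coverage filter is applied once, globally,
before any cross-validation — matching a design in which the candidate
feature set is fixed by platform coverage, not by labels — rather than
re-run inside each training split (labels play no role in coverage, so
no information leaks either way).

Probe handling before scoring: probes mapping to multiple genes are
discarded, unmapped probes are discarded, multiple probes per gene are
averaged, technical replicates are averaged per subject, and genes left
with missing values are dropped per cohort. Inputs are assumed
normalised, log2-scale gene matrices; `log2_transform = TRUE` applies
log2(x+1) for raw-scale inputs. Probe collapse happens before median
centering — a convention, since the reverse order changes nothing when
replicate probes are complete.

## The classifier

The model is an L1-penalised (lasso) logistic regression on the stacked
strength matrix, non-responder as the positive class, fit with glmnet.
Three post-fit steps make it a reporting-friendly instrument:

1. **Rescaling.** The affine map sending the minimum training linear
   predictor to 0.5 and the maximum to 9.5 is folded into the
   coefficients and intercept. Ranking (hence AUROC) is unchanged;
   scores become readable on a 0–10 scale.
2. **Clipping.** Test scores outside [0, 10] are clipped. Training
   scores are never clipped, by construction of the rescale.
3. **Thresholding.** The decision threshold is the largest value with
   at least 60% of training non-responders strictly above it (the
   `floor((1-0.6)n)`-th ascending NR order statistic; ties resolve
   toward the lower threshold, i.e. higher sensitivity; when no
   admissible cut exists above the minimum NR score, a value strictly
   below that minimum is used). Targeting a *training sensitivity*
   rather than a specificity is what yields the high test specificity
   this procedure is built around.

Two choices the procedure leaves open are exposed as arguments and set
as follows by default:

- **Penalty selection** (`penalty`): internal stratified 5-fold CV
  minimising binomial deviance with the one-standard-error rule
  (`lambda.1se`). The 1se rule is the sparser conventional choice for
  the fitting tool and materially affects how many mechanisms survive;
  `lambda.min` and a fixed `lambda` are available.
- **Standardisation** (`standardize`): off. Strength scores already
  share log2 fold-change units, so penalising them on their native
  scale is the defensible default; the toggle exists because the
  original fitting convention is unknowable from outside.

`gene_contributions()` decomposes a fitted model to the gene level:
gene $g$ contributes $\sum_m \beta_m s_g / |G'_m|$ over selected
mechanisms containing it, which is why mechanisms with hundreds of
supporting genes dilute each gene's individual contribution.

## Validation schemes

All resampling is *batch-aware*: fold plans shuffle within cohort and
deal round-robin, so every cohort is split approximately equally across
folds (per-cohort fold sizes differ by at most one) while global fold
sizes also stay balanced. Per repeat, out-of-fold scores are pooled
across the ten folds and one performance report is computed from the
pooled scores (each patient scored exactly once per repeat); summaries
over repeats are medians with 2.5/97.5 percentile intervals. Folds are
balanced by cohort only — an optional response-stratification exists in
concept but is deliberately not the default, since only dataset balance
is part of the procedure.

Leave-one-batch-out CV trains on all-but-one cohort and tests on the
held-out cohort, whose strengths are already expressed against its own
median reference — nothing about the held-out cohort is recomputed from
training data. Leave-one-sample-out is k-fold with k = n. The
permutation null permutes labels across the pooled samples (class
counts preserved) before each full CV repeat.

Degenerate situations are handled explicitly rather than silently:

- A training split with a single class causes the fold plan to be
  redrawn from a derived seed (capped at 100 attempts).
- A lasso fit that selects no mechanism has a constant linear
  predictor and cannot be rescaled; such folds score every sample at
  the midpoint 5. The tied scores carry no ranking information (they
  contribute AUROC ½ against any opposite class), which is exactly the
  honest behaviour for an empty model — and the reason the permutation
  null centres crisply at 50%: under permuted labels the 1se penalty
  usually, and correctly, selects nothing.

## Performance statistics

The positive class is NR throughout. Sensitivity, specificity and
precision get Clopper–Pearson exact binomial intervals (Beta
quantiles). The positive likelihood ratio, sensitivity/(1−specificity),
gets the standard log-method interval
$\exp(\ln LR \pm z\sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)})$, and is
reported as ∞ with no interval when there are no false positives. Both
interval methods reproduce, cell for cell after rounding, the published
tables this machinery was checked against. AUROC uses the Mann–Whitney
form with half-credit ties; its one-sided p-value is the Wilcoxon
rank-sum test (exact when total n ≤ 20 without ties, otherwise normal
approximation with tie and continuity corrections). For single-shot
evaluations the AUROC interval is DeLong's; resampled summaries use
percentile intervals across repeats instead.

## Clinical response calling and the DAS28 noise ceiling

EULAR response categories are computed from the standard van Gestel
grid (improvement cutoffs 1.2/0.6; attained-DAS28 cutoffs 3.2/5.1),
which the procedure invokes by name without printing — an external
standard dependency. Three label criteria are supported:
moderate-or-good = R (the usual convention), good-only = R with
moderate excluded, and a plain ΔDAS28 ≥ 1.2 threshold with a
strictness flag because cohorts differ on whether Δ = 1.2 counts as
response.

DAS28 has a measurement standard deviation near 0.6, so even a
classifier that knew each patient's true improvement could not
perfectly predict labels derived from noisy measurements.
`das28_noise_ceiling()` quantifies this: per repetition, independent
Gaussian noise is added to each baseline and follow-up score (the
improvement therefore absorbs sd·√2 of noise — perturbing the two
measurements independently is this package's reading of "noise imposed
onto the measurements"; perturbing Δ once is the alternative), labels
are re-derived, and the original Δ is scored against the noisy labels;
the median AUROC over repetitions is the ceiling. Repetitions yielding
a single class are skipped and counted, not scored 0.5. The ceiling is
data-dependent: it is a property of where a cohort's Δ values sit
relative to the label cutoffs, which is why the package checks it
qualitatively (exactly 1 at sd 0 for separated classes, strictly below
1 and non-increasing as sd grows) rather than against any fixed number.

## Published gene-list signatures

Earlier studies published gene lists without scoring formulas. The
re-evaluation harness re-trains each list with a clustering scorer:
average-linkage hierarchical clustering on correlation distance cut at
two clusters (Euclidean for single-gene lists, where correlation across
genes is undefined), each cluster called by its majority label, test
samples scored by distance-to-R-median minus distance-to-NR-median. A
k-NN scorer (k = 3, scores 0/1) covers lists defined that way; its
binary scores are why the corresponding ROC curves have so few steps.
Every tie rule — cluster call, equidistant samples, split votes —
favours the NR call, keeping specificity estimates conservative. The
specific clustering conventions are this package's defaults, not
reconstructions of the original studies' unpublished pipelines;
evaluation is leave-one-sample-out over pooled cohorts with an option
to exclude a signature's own training cohort.

## The synthetic study generator

`simulate_study()` generates everything needed to exercise the pipeline
end to end: a signed mechanism collection with log-uniform set sizes
(default 4–100) and overlapping membership; four cohorts of 44/15/30/27
samples (27% non-responders, about 2.5:1 R:NR) on random 90% platform
subsets of a 1200-gene universe; and DAS28 records whose EULAR labels
agree with the true labels for the large majority of subjects. Class
signal enters additively: non-responders get
`effect × direction_m × sign_g` added to every gene of each of the 10
informative mechanisms (directions split +1/−1, mirroring the
raised-metabolic / lowered-cytokine contrast the real classifier
found), on top of gene baselines ~N(7, 1), per-cohort per-gene batch
offsets (sd 0.3) and N(0, 1) measurement noise.

The additive linear model is chosen for analysability — strength scores
then have closed-form class means (a shift of exactly `effect` per
informative mechanism), which is what makes the recovery tests sharp.
It deliberately does **not** model microarray heteroskedasticity,
probe-level effects, correlated gene noise, or non-linear batch
distortions. Passing tests therefore demonstrate that the machinery is
correct and calibrated, not that the classifier would achieve any
particular performance on real cohorts.

Defaults are the study conditions, chosen once: cohort sizes and class
imbalance copied from the cohort table of the study design this
package targets; effect 0.5 and noise sd 1 as the stated recovery
conditions; gene universe 1200 and retention 0.9 as a realistic
platform-overlap regime at a size every test can afford. Problem sizes
used by the shipped checks: the permutation null runs 100 repeats of
10-fold CV at the full 116-sample scale; recovery runs 50 generator
seeds and two 25-repeat CV runs; the noise ceiling uses 200
repetitions on 30 records.

## Numerical conventions and edge cases

- Medians: midpoint for even counts, everywhere.
- Rescale degeneracy is an error for a directly fitted model and a
  midpoint-scored fold inside CV (see above).
- A gene listed with both signs in one mechanism is dropped from that
  set with a warning — summing to zero would silently change support
  counts; dropping is conservative and logged.
- All randomness flows from one root seed through deterministic
  substreams (fold plans, permutations, noise repetitions, generator
  stages), so any component can be reproduced in isolation; seeds stay
  below 2^31.
- Model JSON serialises doubles at 17 significant digits and
  round-trips bit-exactly.

## Limitations

The package ingests gene-level matrices; raw CEL/bead preprocessing and
normalisation are out of scope, as are gene-identifier translation, the
content of any proprietary mechanism knowledge base (collections are
user-supplied or synthetic), and functional enrichment of classifier
genes. Real-data headline numbers require the original cohorts and
curated collection and are not reproduced here; what this package
guarantees is the correctness of every computational step and the
calibration of its statistics under a generator whose assumptions are
stated above.
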