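---
title: "Simulating and analyzing a gratitude/joy appraisal fMRI experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing a gratitude/joy appraisal fMRI experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emofmri)
```

## The experiment being emulated

`emofmri` implements, end to end, the analysis stack of an event-related fMRI
experiment that dissociates gratitude from joy by manipulating two appraisal
factors: the benefactor's intention to help (strong / weak / no) and the
value of the benefit received (high / low / zero). Participants imagine a
help-reception scenario on each trial and then rate, on two consecutive
screens, how grateful and how joyful they feel (1 = weakly, 2 = moderately,
3 = strongly). The factorial structure is 3 (intention) x 3 (value) x 2
(emotion), with emotion realized not as a stimulus manipulation but as which
rating is being given.

Because no participant data are distributed, the package ships a fully
seeded synthetic-data generator that reproduces the design's statistical
structure — trial timing, counterbalancing, pseudo-randomization, ordinal
ratings with a configurable effect pattern, and 4D BOLD volumes whose voxel
time courses follow the design matrix with known ground-truth amplitudes and
modulation slopes. Every downstream stage is validated against that known
truth.

## Trial schedules

A trial is rigidly timed: a 3-s scenario screen, a 0.5-s fixation, two rating
screens whose durations are one of the permutations 8/4, 7/5, 6/6, 5/7, 4/8 s
(each followed by a 0.5-s fixation), for a constant 16.5-s trial. A run has
20 trials, two of them nulls; the 18 non-null trials cover each of the nine
intention-by-value cells exactly twice, so a six-run session is exactly
balanced at 12 trials per cell. Trial order is drawn by sequential
constrained sampling with restarts so that no two consecutive non-null trials
share an intention or a value level; null positions are uniform, and the
adjacency rule is evaluated between non-null neighbors (nulls are
transparent). The displayed help-intention percentage is integer-uniform on
[95, 100], [7, 12] or {0}, and the displayed amount on [800, 1200], [80, 120]
or {0}, per condition.

Two design choices were open and are settable: the rating-duration
permutation is drawn uniformly per trial (`duration_assignment = "uniform"`,
the default) or in balanced shuffled blocks; and the per-run order of the two
rating screens follows one of two counterbalancing schemes, A-B-B-A-A-B or
B-A-A-B-B-A, assigned alternately across subjects, with A meaning the
gratitude rating comes first (the label mapping is arbitrary and only needs to
be consistent). An independent validator, `validate_run_schedule()`,
re-checks every constraint from scratch and is used throughout the tests.

## The rating generator

Ratings come from a latent-Gaussian ordinal model: a cell's latent mean is a
grand mean plus intention and value main effects plus an emotion-difference
term; a subject intercept (SD 0.2) and a trial residual (SD 0.4) are added,
and the result is cut at 1.5 and 2.5 into the three ordinal categories. Each
single rating is missing with probability 0.02, a small realistic nonresponse
rate. The default effect pattern places the gratitude-minus-joy difference
(0.3 latent units) only in the strong-intention cells with low or zero value
— the qualitative signature the behavioral analysis is meant to detect — with
main effects (strong +0.45, weak -0.10, no -0.35; high +0.50, low 0, zero
-0.50 around a grand mean of 1.95) that keep every latent cell mean inside
[1, 3]. `latent_cell_means()` and `expected_rating_means()` expose the
analytic cell means before and after discretization, and the tests check the
simulator against them.

The generator emulates the design's structure, not everything about real
ratings: it assumes a common latent scale across subjects, independent
residuals for the two emotions within a trial, and missingness completely at
random. Passing tests therefore demonstrate that the pipeline recovers known
effect structure, not that it would behave identically on real button
presses.

## Behavioral statistics

`subject_cell_means()` excludes any trial missing either rating from both
emotions' aggregation (so each subject's gratitude and joy cell means are
computed over identical trial sets), then averages within subject and cell.
`rm_anova()` runs the classical fully within-subject decomposition (via
`stats::aov` error strata): each effect is tested against its
effect-by-subject interaction mean square, giving the familiar F(2, 58) for a
3-level factor with 30 subjects and F(4, 116) for the 3 x 3 interaction
terms. Partial eta-squared is SS_effect / (SS_effect + SS_error). No
sphericity correction is applied by default; Greenhouse-Geisser is available
(`gg = TRUE`), implemented from the covariance of the orthonormalized
contrast scores. Planned comparisons (`paired_comparison()`) average each
subject over a named cell set before a classical paired t with df = n - 1 and
carry no multiplicity adjustment; the headline comparison collapses low with
zero value and weak with no intention and contrasts gratitude against joy in
the strong-intention/low-or-zero-value cell.

## First-level GLMs

The haemodynamic response is the canonical double-gamma (positive lobe
peaking near 5 s, 1/6-amplitude undershoot near 16 s, unit peak). Event
regressors are amplitude-weighted boxcars on a 16-fold oversampled grid,
convolved and sampled at TR = 2.3 s over 145 volumes per run; runs are
concatenated with per-run intercepts and no high-pass filtering by default.

Model 1 carries 18 condition regressors — one per emotion x intention x value
cell, with events at that emotion's rating screen, labeled by the trial's
cell — plus the nuisance block. Model 2 carries, per emotion, one unmodulated
rating-event regressor followed by four parametric modulators in fixed serial
order: the ordinal emotion rating, intention in linear coding (strong/weak/no
= 1/0/-1), intention in quadratic coding (the square of the linear code,
computed before centering), and value in linear coding. Modulators are
mean-centered and serially orthogonalized within run (runs are separate
sessions), on the modulator values before convolution — the convention of the
standard SPM-style analysis — so each later modulator carries only variance
unexplained by the onset regressor and earlier modulators. Trials missing
either rating are dropped from both models' events.

The rating-order nuisance is implemented as a per-run constant indicator, the
more defensible reading of an "order indicator" that varies only across runs.
That makes it exactly collinear with the run intercepts: `fit_glm()` detects
rank deficiency, warns, and falls back to a minimum-norm solution, under
which the condition and modulator coefficients — the only ones ever
interpreted — remain identified and exact. Fitting is ordinary least squares
per in-mask voxel, without prewhitening; the simulator's AR(1) noise is mild
(default coefficient 0.3) and affects efficiency, not bias.

On noiseless simulations the chain closes exactly: Model 1 recovers the
ground-truth condition amplitudes and Model 2 the modulation slopes to
numerical precision, because the simulator composes its signal from the same
regressor construction the models fit (uniform condition amplitudes are
absorbed by Model 2's unmodulated onset regressors).

## Group inference

The three interaction contrasts spread the printed formula terms evenly over
collapsed factor levels (e.g. the emotion-by-value contrast puts
(1/2, 1/2, -1)/3 on each emotion's low/zero/high cells, negated for joy);
their weight vectors sum to zero, mirror between emotions, and are mutually
non-collinear. Group maps are voxelwise one-sample (or paired) t statistics,
transformed to Z through the t probability integral and capped at |Z| = 10
for degenerate voxels.

Cluster-extent correction is a Monte-Carlo simulation implemented in the
package (not a wrapper): white Gaussian noise on the mask grid, separable
Gaussian smoothing at the target FWHM, exact per-voxel renormalization to
unit variance (computed from the squared kernel, so edge truncation cancels),
one-sided thresholding at the voxel-level p, and 26-connectivity component
labeling; the largest cluster per field is recorded. The critical size is the
ceiling of the empirical 95th percentile of that null distribution and
clusters at least that large are significant; components reaching the 0.005
voxel tier and its own critical size are reported as trends. Defaults are
10,000 simulated fields for production and 1,000 in tests. Smoothness can be
estimated from standardized GLM residuals by the gradient method, calibrated
to return the width of the equivalent smoothing kernel (the convention the
null simulation consumes), since a field smoothed with a kernel of SD sigma
has neighbor correlation exp(-d^2 / (4 sigma^2)).

Two numerical notes. First, on the small grids used for testing (6^3 voxels)
a 0.001 voxel threshold leaves an expected suprathreshold count near 0.2
voxels and an essentially empty excursion set, so the package's calibration
checks run at the 0.005 tier, where the cluster-size distribution is
informative. Second, with integer cluster sizes the quantile rule is slightly
anticonservative (the attained family-wise rate can sit above 0.05, e.g.
~0.07 under the test grid's conditions); the simulation-based check in the
test suite verifies it stays near the nominal level. The null model is the
Gaussian-smoothing variant; an autocorrelation-function-based variant (as in
newer AFNI releases) is out of scope and would differ on real data with
heavy-tailed spatial correlation.

## Multivariate decoding

For a chosen Model-2 modulator, each subject contributes one unsmoothed
gratitude and one joy beta map; in-mask voxels form the feature vector.
Leave-one-participant-out cross-validation holds out both samples of one
subject per fold. Within each fold, features are min-max scaled to [0, 1] on
the training set (the same affine map is applied to the held-out samples,
which may fall outside [0, 1]; zero-range features map to 0); a paired
two-tailed t-test across the training subjects' gratitude-minus-joy
differences retains features with p < 0.05; and a linear SVM with C = 1
(LIBSVM via e1071, the same library the original analysis used) is trained on
the selected features. The decision rule is deterministic: the weight vector
is oriented so positive decisions mean gratitude, and a decision value of
exactly zero predicts gratitude. A fold whose selection is empty predicts by
bias sign and is flagged. Accuracy is the fraction of all 2n predictions
correct; specificity and sensitivity are the gratitude- and joy-sample
accuracies, so with equal class counts accuracy is their mean.

The permutation test reruns the complete cross-validation — scaling,
selection, training — under permuted labels. The default scheme swaps the two
labels within randomly chosen subjects, the label permutation subgroup that
respects the two-samples-per-subject pairing the paired-t selection requires;
a full label shuffle is available (`scheme = "full"`), with selection then
falling back to an unpaired two-sample t-test. Because the training split and
the min-max scaling do not depend on labels, they are computed once per fold
and shared across permutations. The p value is the proportion of permutation
accuracies strictly above the observed one, with the safeguarded
(count >= observed + 1) / (n + 1) variant as an option — the latter is what
uniformity checks should use, since it is exactly uniform under the null.

Pattern localization intersects the selected-feature sets of all folds,
averages each surviving feature's absolute SVM weight across folds, and
reports connected clusters of at least 5 voxels.

## What the calibration tests show — and one honest caveat

With exchangeable null features the cross-validated accuracy is unbiased at
0.5 and the permutation p is uniform. Its spread, however, is wider than the
binomial reference for 60 independent predictions: folds share 28 of 29
training subjects, and within-fold feature selection couples the two held-out
predictions, a dispersion inflation well documented for cross-validation
error estimates. Measured across 100 null generator seeds at the study's
geometry (30 subjects, 200 features), about a quarter of seeds fall outside
the two-sided binomial 95% band (empirical SD ~0.12 vs the binomial 0.065).
A calibration check that expects near-binomial coverage of LOPO accuracy will
therefore fail — not because the estimator is biased (it is not, and its
permutation p is uniform, which the suite verifies) but because LOPO accuracy
is not a sum of independent Bernoulli draws. The package's inferential
guarantee is the permutation test, which is calibrated by construction.

Signal recovery is verified at a deliberately strong planted effect: the
default ground truth assigns a 12-voxel region intention-linear slopes of
+0.25 (gratitude) and -0.25 (joy) against AR(1) noise with unit innovation SD
— a regime where the full simulate-fit-decode chain should and does reach
accuracies near 1 with the consensus weight map covering the planted region.
This verifies mechanics (no leakage, correct bookkeeping, correct
localization), not field-realistic effect sizes.

## Problem sizes

Tests and the reproduction script run the full cohort (30 subjects, 6 runs,
145 volumes at TR 2.3 s) for the behavioral and decoding analyses, on a
6 x 6 x 6 voxel grid at 3 mm — the grid is the package's test-scale choice;
the generator accepts realistic grids through `ground_truth(grid_dim = ...)`.
Null calibration uses 1,000-field null distributions, 500-dataset
family-wise-error estimates, 100 generator seeds for the null decoding checks
(100 permutations each) and 50 seeds for signal recovery (99 permutations
each).

## Known limitations

The simulator omits hemodynamic nonlinearity, physiological noise, motion
artifacts (motion nuisance columns are synthesized slow random walks, kept
only to preserve the design-matrix shape) and surface geometry. OLS without
prewhitening is used throughout, as is a single canonical HRF. Anatomical
labeling of clusters is out of scope; "regions" in this package are planted
voxel sets in synthetic volumes, and conclusions about real brains require
real data.
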