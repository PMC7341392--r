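---
title: "Decoding stimulated body locations from event-related fMRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulated body locations from event-related fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somadecode)
```

## The analysis problem

`somadecode` implements a complete multivoxel pattern analysis (MVPA)
pipeline for a four-location somatosensory stimulation experiment. In each
run a participant receives 20 five-second stimuli, five at each of four
body sites (two on the arm: *Arm A*, *Arm B*; two on the leg: *Leg A*,
*Leg B*), in randomized order with jittered inter-trial intervals, while
BOLD volumes are acquired every 2 s on 3-mm isotropic voxels. The
questions the pipeline answers are:

1. Can a linear classifier decode *which* of the four sites was
   stimulated from the trial-wise activation patterns (chance 0.25), and
   which of the two body parts (upper vs lower limb, chance 0.5)?
2. Is the observed cross-validated accuracy significant against a
   permutation null, with false-discovery-rate control across units of
   analysis?
3. *Where* in the volume is the information, via a spherical searchlight
   with Monte-Carlo cluster-extent family-wise-error correction?

Because raw data of this kind are rarely shareable, the package ships a
synthetic-data generator that emulates the acquisition and design, so
every downstream stage is testable end to end. Everything is seeded and
exactly reproducible.

## The synthetic session

`session_config()` encodes the design: 4 conditions x 5 trials, 5-s
stimuli, TR 2 s, a 20 x 20 x 20 grid of 3-mm voxels, and onset-to-onset
inter-trial intervals (ITIs) with mean 14.92 s and SD 1.66 s constrained
to 13-17 s. Two points deserve explanation.

**ITIs are onset-to-onset.** Twenty trials at ~15 s onset spacing fill a
five-minute stimulation scan exactly; an offset-to-onset reading would
stretch the run to almost seven minutes. The stimulus (5 s) always ends
before the shortest interval (13 s) elapses, so events never overlap;
configurations violating this are rejected.

**Jitter is drawn from discrete levels.** No unimodal distribution
supported on an interval of width 4 s can have a standard deviation of
1.66 s: the SD of any normal truncated to [13, 17] is below the uniform
limit 4/sqrt(12) ~ 1.15 s. A mean of 14.92 s with SD 1.66 s on a 13-17 s
range is, however, exactly achievable by a three-level jitter scheme --
the common event-related practice of cycling among a few interval
durations. The default draws from {13, 15, 17} s with sampling weights
solved in closed form (`solve_iti_weights()`) from the three moment
equations, so the jitter distribution has *exactly* the configured mean
and SD. A truncated-normal option remains available
(`iti_method = "truncnorm"`) for users who prefer it, with the caveat
that its realized SD is necessarily smaller than nominal. With
`iti_sd_s = 0` every interval equals the mean, which is convenient for
degenerate-case tests.

## Spatial patterns and the forward model

`generate_pattern_map()` builds per-condition 3-D amplitude volumes with
a two-scale structure mirroring the somatotopic assumption that the two
arm sites activate one cortical neighbourhood and the two leg sites
another:

* a *shared body-part component*: constant `shared_amplitude` inside the
  arm region for both arm conditions, likewise for the leg region
  (regions are disjoint boxes; overlapping regions are rejected);
* a *condition-unique component*: an independent random-sign pattern of
  magnitude `unique_amplitude` inside the region.

Binary (arm vs leg) decoding is therefore driven by the coarse regions,
and four-way decoding by the fine sign patterns. With
`unique_amplitude = 0` the two conditions of a body part are identical by
construction; with both amplitudes zero the data are signal-free.

`simulate_bold()` applies the forward model

    y_v(t) = baseline + sum_trials a(c_trial, v) * r_trial(t) + e_v(t)

where `r_trial` is the trial's unit boxcar convolved with the gamma HRF
(below), sampled at the TR -- *identical* to the regressors the GLM later
uses -- and `e` is stationary Gaussian noise with marginal SD `sigma`,
optionally filtered to lag-1 autocorrelation `ar1` (AR(1), the simplest
model that exercises the GLM's robustness; the baseline defaults to 100
so amplitudes read as percent signal change). Run length defaults to the
last event offset plus 20 s of HRF decay, and can be pinned with
`n_volumes`. The generator purposely omits motion, physiological noise,
slice-timing effects, scanner drift beyond what the user injects, and any
realistic spatial covariance: passing tests demonstrates the *pipeline's*
correctness and calibration under known conditions, not performance on
real data. In particular, real-data accuracies cannot be predicted by any
synthetic setting, because effect sizes in the synthetic world are free
parameters.

## Hemodynamic response and trial-wise GLM

The HRF is a single gamma in the AFNI GAM parameterization,

    h(t) = (t / (p q))^p exp(p - t / q),

with defaults p = 8.6, q = 0.547 s: unit peak at t = p q ~ 4.70 s,
h(0) = 0. The source analysis chain preprocessed in AFNI and specified
only "a gamma function", so these canonical GAM defaults are a package
decision, exposed via `hrf_spec()`.

`build_design_matrix()` convolves each trial's boxcar with `h` on a 0.1-s
grid (jittered 5-s boxcars are not TR-aligned) and samples at the volume
times, giving one regressor per trial -- the LS-A convention, a single
joint model for all trials, which is what "least squares, each trial a
separate regressor" describes. Nuisance columns are an intercept plus
Legendre drift polynomials up to `drift_order` (default 1; motion
covariates are out of scope for aligned synthetic data). Rank deficiency
(e.g. coincident trials) is reported with the offending column names.

Before fitting, `scale_voxelwise()` divides each in-mask voxel series by
its temporal mean and multiplies by 100, the classic mean-scaling that
makes betas percent-signal units; voxels with non-positive mean are
excluded from the mask with a warning. `fit_beta_series()` then solves
ordinary least squares for all voxels through one shared QR factorization
and returns the trials x voxels matrix with the four-location labels and
their deterministic two-class collapse (`relabel_two_class()`).

## Decoding

`cross_validated_decode()` follows the standard MVPA recipe:

* **stratified k-fold CV** (default 5 folds): per-class counts across
  folds differ by at most one; with 5 trials per condition every fold
  holds exactly one trial of each condition. The seeded fold assignment
  is a function of each trial's class and its within-class rank, so
  reorderings that preserve within-class ranks leave results unchanged.
* **within-fold ANOVA-F selection** (`fscore_select()`, default top 10
  percent): the one-way F statistic is computed per voxel on the
  *training rows only*; the top `ceiling(percentile/100 * V)` voxels are
  kept, ties broken toward the lower index for reproducibility. A voxel
  constant across trials gets F = 0 and is never selected ahead of any
  voxel with positive F.
* **linear support-vector classification** (libsvm via `e1071`), cost
  fixed at 1.0 -- no nested tuning, as none is reported for the analysis
  being reimplemented -- with libsvm's native one-vs-one scheme for the
  four-class task. Features are not standardized beyond the GLM's
  percent-signal units.

Pooled cross-validated predictions yield accuracy, the confusion matrix,
and macro-averaged precision/recall/F1 (classes are balanced by design).
ROC-AUC is computed from pooled decision values for binary tasks only and
deliberately omitted (with a message) otherwise.

## Permutation inference

`permutation_null()` re-runs the *entire* pipeline -- label shuffle,
fold re-stratification, within-fold selection, training, held-out
prediction -- for each of `n_perm` permutations. The whole label vector
is permuted (class counts preserved), which is the natural reading of
"randomly labeled training data" when selection is refit per fold.
Permutation *i* uses the derived seed `seed + i`, so null streams are
reproducible and prefix-stable in `n_perm`.

The empirical p value uses the add-one (Phipson-Smyth) convention
`p = (1 + #{null >= observed}) / (1 + n_perm)`, so Monte-Carlo p values
are never zero and ties count against the observation. `fdr_bh()` applies
Benjamini-Hochberg step-up correction (by default across subjects for the
whole-brain tests; the unit of correction is the caller's choice).
`group_accuracy_test()` provides the one-sample t of accuracies against
chance and a paired variant between two accuracy vectors -- the source
description of "paired t-tests" does not say what is paired, so both are
available and neither is privileged. Zero-variance inputs are flagged
degenerate instead of yielding spurious significance.

## Searchlight and cluster-extent correction

`sphere_offsets()` enumerates all integer voxel offsets within
`radius_mm` (default 5 mm; on 3-mm voxels that is 19 voxels: centre, 6
face neighbours, 12 edge neighbours). `searchlight_map()` runs, for every
in-mask centre, the same stratified CV linear SVC on the sphere's in-mask
voxels -- *without* percentile selection, which would be meaningless on
at most 19 features -- and assigns the mean accuracy to the centre
(the standard convention). Spheres are truncated at mask boundaries;
centres with fewer than two voxels are skipped and counted. One fold
assignment, drawn from the decoder seed, is reused across centres, making
the map independent of centre visiting order.

`group_searchlight_stat()` computes the per-voxel one-sided one-sample t
of (accuracy - chance) across subjects; the group model of the original
analysis is not stated, and this is the common default. Voxel-wise
thresholding at p < 0.001 (uncorrected) feeds `cluster_threshold()`,
which labels connected components under face connectivity by default
(18- and 26-connectivity are selectable; the original NN level is
unstated).

`monte_carlo_cluster_extent()` calibrates the cluster-size threshold k:
`n_iter` Gaussian white-noise volumes are smoothed to an assumed FWHM,
standardized exactly to unit variance (the separable kernel's sum of
squared weights factorizes, so boundary voxels are standardized
correctly), thresholded at the one-sided z equivalent of the voxel
threshold, and the maximum suprathreshold cluster size recorded; k is the
smallest size reached by at most `alpha_fwe` of iterations. Smoothness is
a *user parameter* rather than residual-estimated: synthetic data have
known smoothness, and residual-based estimation (the 3dClustSim workflow)
is out of scope. The default 6 mm FWHM comes from the searchlight
geometry itself: neighbouring centres share 13 of 19 sphere voxels, and
matching that induced correlation with a Gaussian autocorrelation gives
roughly a 6-mm FWHM for accuracy maps from 5-mm spheres on 3-mm voxels.
Because cross-validated accuracy under the null sits slightly *below*
chance (the well-known pessimistic bias of CV), the one-sided group test
is mildly conservative, which errs on the safe side for family-wise error
control.

## Orchestration

`run_experiment()` chains the stages for `n_subjects` simulated subjects
with per-subject seeds derived from a master seed
(`master_seed + 1000 s + stage`), runs both labelings, permutation tests,
group tests, and optionally the searchlight stage with cluster
correction, and writes events TSVs, decoding JSONs, null CSVs, NIfTI
maps, a cluster CSV, `report.json`, `summary.txt`, and a `manifest.json`
listing every artifact. Re-running with the same configuration reproduces
every output byte for byte. With one subject, group stages are skipped
with a logged reason. A thin command-line wrapper around these functions
is installed under `inst/scripts/run_pipeline.R`.

## Numerical choices and edge cases

* Convolution grid 0.1 s; regressors Riemann-scaled so they approximate
  the continuous boxcar-HRF convolution.
* Selection count `ceiling(percentile/100 * V)`; F-score ties break
  toward the lower voxel index (stable radix sort).
* Degenerate variance: constant voxels get F = 0; voxels separating
  classes perfectly (zero within-class variance) get F = Inf and sort
  first; zero-variance group contrasts and searchlight voxels are flagged,
  not silently significant.
* Empirical p values can never be 0; BH-adjusted q values are capped at 1
  and always >= their p values.
* The beta solver rejects rank-deficient designs and volume-count
  mismatches rather than silently pseudo-inverting.

## Scale of the validation suite

The packaged tests validate calibration at sizes chosen to balance
statistical resolution against desk-scale runtimes, stated here as
package decisions: permutation-null calibration uses 1000 shuffles on the
default 20^3 grid; the type-I-error study uses 200 signal-free datasets
with 199 permutations each on an 8^3 grid (the calibration of a
permutation test does not depend on voxel count); the searchlight
recovery/FWE study uses 12 subjects on a compact ~56-voxel ellipsoidal
mask inside the 20^3 grid, with a 500-iteration Monte-Carlo extent
threshold and 100 matched null replicates; generator timing moments pool
200-500 schedules. The acceptance script
(`scripts/acceptance.R`) recomputes the chance-calibration and
ITI-moment quantities from scratch at the same scales.

## Known limitations

* The noise model is stationary Gaussian AR(1); no physiological or
  motion structure, no spatial noise correlation (the searchlight's
  Monte-Carlo correction takes its smoothness from a user parameter for
  exactly this reason).
* Effect sizes are free parameters; no synthetic configuration can claim
  to reproduce real-data accuracy values.
* LS-A is the only beta-series estimator (no LS-S variant).
* Surface-based searchlights, anatomical cluster labeling, and
  permutation-based cluster inference are out of scope.
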