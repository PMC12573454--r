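---
title: "Explainable connectivity classification: models, design choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable connectivity classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control classification from resting-state fMRI functional
connectivity faces a standing tension: deep models reach high accuracy on
cohorts such as multi-site autism collections, but clinicians cannot act
on a black box, and attribution methods imported from computer vision have
never been validated for connectivity data. `fcxai` implements, as a
tested R pipeline, the full loop needed to study that tension: from ROI
time series to Fisher-Z connectivity features, through supervised feature
selection and a sparse autoencoder classifier, to seven attribution
methods benchmarked by Remove-And-Retrain (ROAR) and aggregated into a
ranked table of brain regions.

Because the real multi-site accession cannot ship with a package, the
pipeline is exercised end-to-end on synthetic cohorts with *planted*,
therefore known, group differences. Every claim the test suite makes is a
claim about recoverable ground truth.

## The synthetic cohort generator

`generate_cohort()` draws each subject's time series from a zero-mean
multivariate normal whose correlation matrix encodes the group structure:

* **Baseline**: 116 ROIs partitioned into 8 contiguous "network" blocks
  with within-block correlation 0.3 and zero between blocks. This gives
  feature selection and attribution a realistically *correlated* nuisance
  background rather than white noise.
* **Planted effect** (case group only): a hub — all 17 connections between
  ROI 43 (Calcarine_L in AAL file order) and partner regions spread across
  the atlas, shifted by ±0.15 — plus a diffuse background of 70 further
  ROI pairs shifted by ±0.15. The two-component design mirrors how
  case-control connectivity differences present in practice: a few
  strongly implicated regions on top of a distributed, individually weak
  signal. A hub-only effect is mathematically capped (the hub row of a
  correlation matrix must stay positive definite) at a total signal too
  small for any classifier at this sample size, which is also why purely
  "one strong edge" simulations are unrealistic.
* **Motion**: 20% of each group receives additive i.i.d. noise
  (sd 2.0, against unit-variance signal) and a mean framewise
  displacement drawn from (0.25, 0.6) mm; clean subjects draw from
  (0.02, 0.18) mm. Motion is thus represented by its two downstream
  consequences — attenuated, noisier correlations and a high FD scalar —
  not by simulated rigid-body trajectories, because the pipeline only
  consumes FD as a filter key.
* **Sizes**: 100 subjects per group, 150 timepoints (within the typical
  range of resting-state runs). Each subject consumes an independent
  seeded stream, so enlarging a cohort never perturbs existing subjects.

If a planted configuration makes the target correlation matrix
non-positive-definite, generation fails naming the offending pairs;
nearest-PD repair is never applied silently, because it would quietly
change the planted ground truth the tests rely on.

What the generator does *not* emulate: site/scanner effects,
hemodynamics, autocorrelated BOLD noise, age/sex structure, or realistic
motion spikes. Passing tests therefore show that the pipeline recovers
planted linear-correlation structure under correlated Gaussian noise —
necessary, not sufficient, evidence for behaviour on real data.

## Feature extraction

Per subject: Pearson correlation between all ROI pairs, Fisher-Z
(`atanh`) variance stabilisation, and row-major flattening of the strict
lower triangle (i > j, 1-based, following AAL file order), giving
116·115/2 = 6670 features. The flattening convention is fixed and
bidirectional (`feature_index_map()`), since reproducible feature indices
are what lets attribution scores be traced back to ROI pairs.
Correlations are clipped to ±(1 − 1e−7) before `atanh`; degenerate
synthetic data can reach ±1 exactly. Subjects with mean FD above 0.2 mm
are excluded (boundary retained); the threshold follows the standard
corruption criterion for resting-state data.

## Feature selection

SVM-RFE: iteratively fit a linear soft-margin SVM (C = 1) on standardised
surviving features, rank by squared weight, drop the lowest 10% per sweep
(never overshooting), stop at exactly k = 1000. Linear-weight ranking is
the canonical RFE criterion; C and the standardisation are stated here
because weight magnitudes are only comparable across features after
scaling. By default RFE runs inside each training fold; a `global` switch
reproduces the leakier design some studies use, because which of the two
a published analysis used is often unknowable and the difference is worth
measuring rather than guessing.

## The classifier

Two ReLU autoencoders (1000→500→1000, then 500→100→500 on the frozen
codes) are pre-trained greedily without labels under

L(x, x̂) = MSE(x, x̂) + β · Σ_j KL(ρ ‖ ρ̂_j),

with ρ = 0.2 the target activation rate, β = 2 its weight, and ρ̂_j the
batch-mean activation of hidden unit j. The encoders are then stacked
under a softmax head and fine-tuned end-to-end with cross-entropy.
Optimiser: Adam; pre-training 50 epochs at lr 1e−3, fine-tuning 50 epochs
at lr 1e−4, weight decay 1e−4, batch 128. Decoders are untied; weights
initialise uniform fan-in-scaled; inputs are standardised with
training-fold statistics only.

**ρ̂ under ReLU.** The Bernoulli-KL penalty needs activations in (0, 1),
but the forward pass is ReLU. The package's default computes ρ̂ on
sigmoid(pre-activation) while the reconstruction path stays ReLU; the
alternative (`rho_hat_mode = "relu_clip"`) uses batch means of ReLU
outputs clipped to [0, 1]. The sigmoid form is the default because its
gradient is smooth everywhere, which makes the β-sweep property (sparsity
pressure monotone in β) hold cleanly; both modes are tested. Boundary
activations are clipped into (ε, 1−ε) so the penalty never produces NaN.
A property worth knowing: with Adam the *size* of β stops mattering once
the KL gradient dominates (Adam normalises per-coordinate scale), so
convergence of ρ̂ to ρ is governed by step count, not by β; the sparsity
tests therefore run the small convergence models for 2000 epochs.

**Checkpoint selection.** The checkpoint evaluated on test is the one
with the best validation accuracy, ties broken by lower validation loss.
The tie-break matters: validation accuracy on a 26-subject split
saturates within a few epochs, and "first epoch to reach the maximum"
returns a barely-trained model whose attributions are dominated by the
random initialisation of the head. Validation loss keeps falling through
the 50 epochs, so the tie-break selects the converged model.

## Evaluation protocol

Stratified 5-fold cross-validation; within each fold the non-test 80%
splits 80/20 into training and validation, i.e. 64/16/20 overall, class
ratios preserved within ±1 subject. Metrics: accuracy, sensitivity,
specificity, precision, F1, with the case group as the positive class
(reported as mean ± sd over the five folds; metrics with empty
denominators are NA, never 0). Standardisation, RFE and training see only
training-fold subjects; validation steers checkpoint choice; a leakage
audit records every subject index used in any fitting call so the test
suite can assert that test subjects never appear.

## Attribution

Seven methods over the trained model, all targeting the logit of the
predicted class and all using the all-zero vector as baseline/background
— zero Fisher-Z correlation means "no relationship", the natural absent
value for connectivity:

* Integrated Gradients (midpoint Riemann path integral, 200 steps;
  completeness holds to well under 1%);
* DeepLift with the rescale rule (summation-to-delta is exact for this
  architecture), DeepLiftShap (DeepLift averaged over baselines);
* GradientShap (expected gradients with seeded interpolation noise);
* Guided Backprop (ReLUs pass only positive gradients from positive
  activations);
* LIME (zero-imputation perturbations, kernel-weighted ridge surrogate);
* kernel SHAP (coalition sampling with the Shapley kernel; the
  local-accuracy constraint is enforced exactly in the solve).

Cohort-level rankings aggregate per-sample scores by mean absolute value
(signed mean switchable). On an exactly linear logit all four
gradient-family methods coincide with w·x, which the tests use as a
cross-method oracle.

## Remove-And-Retrain

For a ranking and removal fraction t, the top ⌈t·k⌉ features are set to
zero in *all* partitions, the full model is retrained from scratch with
fresh seeds (original hyperparameters, architecture unchanged — zeroed
columns stay as inputs), and test accuracy is recorded; the canonical
threshold grid is {0.01, …, 0.99} (13 values). A uniformly random
ranking, redrawn per repeat, is always included; per-threshold dispersion
over retrain seeds is reported, never a single draw. The area under the
accuracy-vs-threshold curve summarises each ranking (lower = the ranking
found features the model depends on). Rankings are computed per fold on
training data only; ablation masks nest with t and are idempotent; ties
at the cut break by ascending feature index.

## Regions

Each top-k (default 100) feature credits both endpoint ROIs; ROIs sort by
endpoint count, ties by summed attribution magnitude, then AAL index.
Both the count and the weighted score are emitted, since either could
legitimately order a published table. Brodmann annotation comes from a
bundled 116-row lookup compiled from published region-area pairings and
standard AAL documentation; cerebellar, vermis and deep-grey regions are
annotated "–". `cross_run_consensus()` ranks ROIs by how many runs place
them in the top m, then by mean rank.

## Problem sizes and runtime choices

The test and acceptance workloads run the full pipeline at its published
configuration (6670 → 1000 features, 1000/500/100 autoencoder, 5 folds)
on the default 200-subject cohort; ROAR in the tests runs the two
headline rankings at removal fractions 0.1 and 0.99 with 3 retrain seeds,
and the analysis scripts run a 7-threshold grid. Sparsity-convergence
checks use a 60-feature model for 2000 epochs. These sizes were chosen so
the whole suite completes on a single desktop CPU core in well under half
an hour while still exercising every stage at the published widths.

## Known limitations

* The null-calibration distribution of cross-validated accuracy at these
  sample sizes is wide and can sit below 0.5 (selection effects invert
  chance-level fits); the calibration test uses a ±3 sd band for exactly
  this reason.
* LIME's surrogate on 1000 correlated features is noisy at any perturbation
  budget that is affordable; it is included because benchmarking it is part
  of the point, not because its rankings are expected to win.
* The generator's Gaussian, temporally white signal means time-domain
  properties (autocorrelation, spectral structure) are untested.
* Kernel SHAP cost grows with the coalition solve (p × p); at p = 1000 it
  is run on sample subsets in the analysis scripts.
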