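---
title: "Decoding group membership from band-limited EEG covariance: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding group membership from band-limited EEG covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bandcov)
```

## The model

`bandcov` treats 2-s multichannel EEG epochs as realizations of a linear
forward model

$$x(t) = A\,s(t) + \varepsilon(t),$$

where the columns of the mixing matrix $A$ are the sensor topographies of
latent band-limited sources $s(t)$ and $\varepsilon$ is sensor noise. Under
this model the class-relevant information lives in the *spatial covariance*
of the band-passed signal: if a group expresses a source more strongly, the
covariance gains energy along that source's topography. All three decoding
pipelines are different parameterizations of this covariance structure.

**Feature space.** Epochs are decomposed into seven bands (theta1 4–6 …
beta3 20–24 Hz) by zero-phase order-4 Butterworth band-passes, and per-epoch
spatial covariances $\Sigma_{X_i}\in\mathbb{R}^{N\times N}$ are estimated
per band, giving a bands × epochs × N × N tensor.

**Supervised projection.** Per band, CSP filters $W$ solve
$\bar\Sigma_1 w = \lambda(\bar\Sigma_1+\bar\Sigma_2)w$ on the class-mean
training covariances, columns sorted by decreasing $\lambda$ and normalized
so $w^\top(\bar\Sigma_1+\bar\Sigma_2)w = 1$. Features are
$\log\operatorname{diag}(W^\top\Sigma_{X_i}W)-\log\operatorname{diag}(W^\top\bar\Sigma_1 W)$,
concatenated over bands ($K\cdot J$ values). The filters are selected from
the top of the spectrum only (the decreasing-eigenvalue rule); the
both-ends selection common in CSP practice is available via
`csp_fit(select = "both")`.

**Unsupervised projection.** Per band, the top-$J$ eigenvectors of the
grand-mean training covariance (classes pooled) project each epoch's
covariance to a $J\times J$ SPD matrix; these are mapped to the tangent
space at their Karcher mean under the affine-invariant metric,
$F_i=\mathrm{Upper}(\log(\bar\Sigma_Z^{-1/2}\Sigma_{Z_i}\bar\Sigma_Z^{-1/2}))$,
$J(J+1)/2$ values per band. Off-diagonal entries carry a $\sqrt2$ weight so
the Euclidean norm of $F_i$ equals the Riemannian distance to the mean; the
unweighted variant is `tangent_vectorize(offdiag_weight = 1)`.

**Handcrafted features.** Multitaper PSD per epoch/channel/band, normalized
to relative power. The denominator is the summed power over the seven
analysis bands (their union, 4–24 Hz), so the seven values of a channel
partition to exactly 1 — which makes the normalization testable to 1e-12;
a full-spectrum denominator is available
(`relative_power(denominator = "full_spectrum")`).

**Classifiers.** The two projection pipelines use L2-regularized logistic
regression with the inverse-regularization grid $[10^{-10},10^9]$ (20 log-
spaced points); ties in validation balanced accuracy resolve toward stronger
regularization. The handcrafted pipeline uses leaf-wise-grown gradient-
boosted trees with a 3×3×3 grid over learning rate, leaf count and minimum
child weight, early-stopped on validation log-loss. In both cases the tuning
unit is the *validation subjects* of the fold, never test epochs, and the
tuning objective is balanced accuracy (the headline metric).

**Evaluation.** `make_folds()` builds leave-subjects-out folds: one test
subject per group, one validation subject per group, the rest training.
Epoch-level predictions are scored by balanced accuracy and AUC
(Mann–Whitney with half-weight ties); pipelines are compared fold-paired by
a Wilcoxon signed-rank test whose null distribution is enumerated exactly by
sign flips for up to 14 folds (tied |differences| make the usual
normal-approximation p-values inaccurate exactly in the uniform-improvement
case one cares about).

## Explainability

Backward-model filters are not interpretable topographies; the forward-model
activation pattern is $A = \Sigma_X W$ (extracted-signal covariance taken as
identity, matching the scale-free column normalization to unit maximum;
`filters_to_patterns(sigma_s =)` applies the full scaling). In a noiseless
two-source simulation the pattern of the discriminative CSP filter recovers
the true mixing column with |correlation| ≥ 0.99, and degrades monotonically
with sensor noise — both asserted in the test suite.

Shapley attributions use the interventional (background-marginalized) value
function: $v(S)$ is the mean model margin over a background sample with the
features in $S$ fixed at the explained epoch's values. For ≤ 10 features the
exact value is computed by full coalition enumeration; above that, a seeded
antithetic permutation-sampling estimator is used. Both satisfy local
accuracy exactly (each permutation's marginal contributions telescope), and
the package asserts it at 1e-6 for every explained epoch. The ranking
statistic is the mean |attribution| per feature.

One measured caveat, reflected in the tests: boosted trees are greedy and
concentrate splits on few features, so when an effect is strong the top-10
ranking beyond the handful of active features is noise-ordered. The stable
ground-truth checks are the attribution *mass* on the planted band and the
identity of the rank-1 feature. With relative-power features the planted
band's information additionally leaks into all other bands through the
simplex normalization (they are anticorrelated by construction), so
band-identity checks use unnormalized band power.

## Cluster statistics

Group differences in band power are tested on **subject-level mean PSD**
(subjects are the exchangeable unit; permuting epochs would ignore
within-subject correlation and be anti-conservative). Per channel × band a
pooled-variance two-sample T is computed; channels with $|T|$ above the
cluster-forming threshold are clustered by spatial adjacency within each
band, separately by sign; cluster mass is the summed T; and each observed
cluster is referred to the permutation null of the maximum |mass| over
random subject relabelings, $p = (1+\#\{\text{perm}\ge\text{obs}\})/(n_{perm}+1)$.
When fewer distinct relabelings than `n_perm` exist they are enumerated
exhaustively (with a warning). Adjacency is geometric: channels within
1.3 × the median nearest-neighbor distance (recovering the 4-neighborhood of
a regular grid).

The default cluster-forming threshold is $|T| > 6$, an intentionally strict
value retained as the package default for the headline analysis. At
desk-scale group sizes (n ≈ 8–10 per group) a cell exceeds $|T|=6$ under the
null with probability ~3e-5, so at that threshold the test almost never
forms clusters and its family-wise rate is far *below* the nominal level —
strictness, not miscalibration. Calibration is therefore verified at the
conventional forming threshold $t_{0.975,df}$: over 200 null cohorts the
family-wise positive rate lands near 0.05 (the max-statistic construction
makes the test near-exact there). Planted strong effects are still recovered
at threshold 6 with Jaccard 1.0 against the ground-truth loaded channels.

Behavioral correlations use Spearman's rho per band between channel-mean
power and the behavioral score, permutation-tested by shuffling the behavior
vector, with the Bonferroni per-band threshold $\alpha/K$ reported alongside
(0.05/7 ≈ 0.00714 for the default bands).

## The synthetic cohort generator

`generate_cohort()` defines the study conditions the package is tested
under:

* one band-limited source per band (order-4 Butterworth-filtered Gaussian
  noise), sample variance rescaled exactly to the subject's source variance;
* a shared mixing matrix with unit-norm Gaussian columns (cross-subject
  decoding presumes partially shared topography; per-subject perturbation via
  `per_subject_mixing_sd`, spatially compact patch loadings via
  `source_topology = "patch"` when ground-truth spatial extent must be
  known);
* group effects as multiplicative ratios on source variance for group M,
  with lognormal mean-1 per-subject jitter (`subject_sd`, default 0.2 —
  variances stay positive and between-subject spread is realistic);
* white sensor noise (`noise_sd`, default 0.5 on unit-variance sources, a
  moderate SNR);
* defaults of 10 subjects/group, 24 channels, 40 epochs/subject/task at
  250 Hz / 2 s — a desk-scale cohort that keeps the full test suite within
  minutes while preserving the structure of a ~26-subject, ~83-channel
  study.

What the generator deliberately does **not** emulate: ocular/muscle
artifacts (no ICA stage is included; `reject_epochs()` provides the
peak-to-peak hook), realistic head-model lead fields, 1/f background
spectra, non-stationary drifts, or mains noise. Passing tests therefore
demonstrate correctness of the algorithms under the forward-model
assumptions, not robustness to every artifact of real recordings.

Null cohorts (`null_cohort()`) force all ratios to 1, making group labels
exchangeable by construction — the harness for type-I-error and
chance-level-decoding checks. Note that a *single* realized null cohort with
few subjects per group can be genuinely decodable: the per-subject power
jitter produces a nonzero realized group difference that a subject-
independent classifier legitimately exploits. The chance level is therefore
a property of the cohort distribution; `null_decoding_level()` estimates it
by averaging over independent null cohorts.

## Numerical choices

* **Filtering** is performed as cascaded second-order sections designed from
  the analog Butterworth prototype (band-pass transform + bilinear map),
  applied forward-backward with odd end-reflection padding. The
  transfer-function direct form is numerically fragile for narrow
  low-frequency bands (it loses ~1e-6 of linearity at 4–6 Hz / 250 Hz);
  the cascade keeps the zero-phase filter linear to ~1e-14. Note that an
  order-4 band-pass with 2 Hz bandwidth has a transient comparable to a 2-s
  epoch, so narrow-band variance of short epochs is not the asymptotic
  spectral integral; steady-state properties are tested on long epochs.
* **Multitaper** tapers are Slepian sequences from the tridiagonal
  eigenproblem, time-bandwidth NW = 2 with 3 tapers on 2-s epochs
  (half-bandwidth 1 Hz, resolving the narrowest 2 Hz band; 2NW−1 keeps taper
  leakage controlled).
* **Covariance conditioning**: shrinkage toward the scaled identity with
  γ = 0.05 by default (500-sample epochs at 24 channels are
  well-conditioned; any γ > 0 guarantees positive-definiteness for
  degenerate epochs).
* **Matrix functions** (log, sqrt, inverse sqrt) go through symmetric
  eigendecompositions with an eigenvalue floor of 1e-12; tangent
  vectorization errors out on genuinely non-PD input instead of flooring it.
* **Karcher mean**: fixed-point iteration from the arithmetic mean, step
  size 1, gradient tolerance 1e-8, at most 50 iterations (typical
  convergence in < 10); non-convergence is an error reporting the gradient
  norm, never a silent result.
* **Degenerate inputs**: zero-total-power epochs get uniform relative power
  1/K with a warning and a flag; non-positive projected variances in CSP
  features are floored at 1e-12 with a warning; all-rejected epoch sets are
  an explicit error.
* **Determinism**: every stochastic step (cohorts, folds, permutations,
  boosted trees, Shapley sampling) takes a seed; `run_experiment()` derives
  stage seeds from one master seed by stage-name hashing, and seeded helpers
  save/restore the caller's RNG state.

## Design decisions that were genuinely open

* **Per-band projections, concatenated features.** The projection equations
  are stated for a single covariance while the feature space is a K-band
  tensor; fitting one projection per band and concatenating is the minimal
  consistent reading (a joint block-diagonal CSP is the obvious alternative
  and would interlock the bands' scaling).
* **PCA on the grand-mean covariance** rather than on pooled concatenated
  data — "projection to a common space" reads as a property of the average
  spatial structure; the pooled variant is `pca_fit(pca_on = "pooled")`.
* **Class 1 = group M** anchors the CSP log features; the choice is
  arbitrary but fixed and recorded in the fitted object.
* **Epoch-level evaluation**: each test epoch is scored independently
  (subject-level aggregation would inflate apparent accuracy through
  within-subject correlation); fold means are reported with SD.
* **Monotonicity experiment design**: the decoding-vs-effect-size sweep
  (ratios 1–3) runs on a reduced, noisier cohort (8 subjects/group, 16
  channels, 15 epochs, noise_sd 1.0, subject_sd 0.3, 4 folds × 5 seeds) so
  the strong-effect end does not saturate at BA = 1 and the dose-response
  is visible across the whole range.
* **I/O**: epoch sets, features and reports are exchanged as in-memory S3
  objects plus plain-text CSV/JSON writers; no binary container format is
  imposed.

## Known limitations

* The generator's sources are stationary and Gaussian; real EEG band power
  is heavy-tailed and non-stationary within epochs.
* Relative-power features make band-level attribution intrinsically
  ambiguous (see above); interpret handcrafted-pipeline rankings at the
  channel × band level with that in mind.
* The permutation-sampling Shapley estimator has Monte-Carlo error in
  individual attributions (local accuracy is exact, per-feature values are
  not); increase `n_perm` for publication-grade rankings.
* The cluster test controls the family-wise error of the *maximal* cluster
  statistic; it does not license channel-level or band-level probability
  statements about cluster members.
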