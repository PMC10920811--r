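# bandcov

Subject-independent decoding of multichannel EEG from the spatial covariance
structure of band-limited oscillations, with interpretable spatial patterns,
Shapley feature attributions and cluster-based permutation statistics.

## The problem

Two groups of people (here labelled **M** and **H**) differ in how strongly
certain cortical oscillations are expressed while they work on cognitive
tasks. Given 2-s EEG epochs recorded during task solving, can a classifier
recognize which group a *previously unseen* person belongs to, and can the
discriminative signal be localized in sensor and frequency space? The
subject-independent setting is what makes this hard: every epoch of a test
subject must be excluded from all fitting, so the model has to generalize
across people, not just across trials.

`bandcov` implements three decoding pipelines over a common seven-band
filter bank (theta1 4–6, theta2 6–8, alpha1 8–10, alpha2 10–12, beta1 12–16,
beta2 16–20, beta3 20–24 Hz), plus the statistics around them:

1. **Supervised projection** — per band, epoch covariances
   `Σ_Xi` are projected through common spatial patterns (CSP): `W` solves
   `Σ̄₁ w = λ (Σ̄₁ + Σ̄₂) w`, filters sorted by decreasing λ, and the
   features are `F_i[j] = log Σ_Zi[j,j] − log Σ₁[j,j]` with
   `Σ_Zi = Wᵀ Σ_Xi W` (K·J features). Classifier: L2 logistic regression,
   C tuned on validation subjects over [1e−10, 1e9].
2. **Riemannian projection** — per band, PCA filters (top-J eigenvectors of
   the mean covariance) project the covariances to `J×J` SPD matrices, which
   are mapped to the tangent space at their Karcher mean `Σ̄_Z` under the
   affine-invariant metric: `F_i = Upper(log(Σ̄_Z^{−1/2} Σ_Zi Σ̄_Z^{−1/2}))`,
   J(J+1)/2 features per band. Classifier: L2 logistic regression.
3. **Handcrafted features** — multitaper power spectral density per epoch,
   channel and band, normalized to relative power (each channel's seven
   bands sum to 1). Classifier: gradient-boosted trees (leaf-wise growth)
   with a validation-tuned grid.

Explainability follows the forward/backward model distinction: linear
filters are converted to activation patterns `A = Σ_X W` (the interpretable
topography), and the tree ensemble is explained with interventional Shapley
values (exact coalition enumeration for small feature counts, seeded
permutation sampling otherwise; local accuracy is asserted for every epoch).
Group differences in band power are tested with a cluster-based permutation
test (two-sample T per channel × band, spatial-adjacency clustering,
max-cluster-mass null over subject relabelings) and behavior is related to
band power by permutation-tested Spearman correlations with a Bonferroni
threshold α/K.

Because the kind of recordings this targets are not freely downloadable, the
package ships a first-class synthetic cohort generator: band-limited sources
(Butterworth-filtered noise) mixed into sensors by a linear forward model
`x(t) = A s(t) + ε(t)`, with group effects planted as multiplicative source
power ratios and lognormal between-subject variability. Every stage is
tested against this generator's known ground truth.

## Worked example

```r
library(bandcov)

cfg <- cohort_config(n_subjects_per_group = 6, n_channels = 16,
                     n_epochs_per_subject_per_task = 20, tasks = "verb",
                     band_effects = list(alpha1 = 2), seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <bandcov_cohort>
#> <epoch_set> 240 epochs x 16 channels x 500 samples @ 250 Hz
#>   subjects: 12  groups: H/M  tasks: verb
#>   planted effects:
#>     alpha1 (source 3): M/H power ratio 2.00

subjects <- unique(cohort$epochs$subject)
groups   <- cohort$epochs$group[match(subjects, cohort$epochs$subject)]
plan <- make_folds(subjects, groups, n_folds = 5, seed = 42)
res <- evaluate_pipeline(cohort$epochs, "supervised", plan, seed = 42)
res
#> <classification_result> pipeline supervised, task all (5 folds)
#>   BA  0.890 +/- 0.091
#>   AUC 0.965 +/- 0.061
```

Mean balanced accuracy 0.89 means that, averaged over five held-out subject
pairs, 89% of each test person's epochs (class-balanced) are assigned to the
correct group — well above the 0.5 chance level, driven by the planted 2x
alpha1 power ratio. Per-fold results (`res$folds`) show the tuned component
count J varying between 2 and 6 across folds.

The same effect is localized by the cluster permutation test:

```r
psd <- multitaper_band_power(cohort$epochs)
sb  <- summarize_psd_by_subject(psd)
adj <- channel_adjacency(cohort$montage)
cl  <- cluster_permutation_test(sb$power, sb$groups, adj,
                                t_threshold = 2.5, n_perm = 1024, seed = 42)
cl
#> <cluster_result> threshold |T| > 2.5, 924 permutations
#>      band n_channels sign       mass     p_value
#> 2  alpha1         12    1  50.300300 0.007567568
#> ...
```

The dominant cluster is a positive (M > H) alpha1 cluster spanning 12 of the
16 channels at p ≈ 0.008 — the planted effect. (The remaining rows are
small sub-threshold-mass clusters with p > 0.05; with only 12 subjects the
permutation space is smaller than 1024, so all 924 distinct relabelings are
enumerated.)

A full multi-task, multi-pipeline run with report files is one call —
`run_experiment(run_config(...))` — or from the shell:

```sh
Rscript inst/scripts/run_cohort_study.R --out runs/demo --seed 7 --ratio 2
```

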