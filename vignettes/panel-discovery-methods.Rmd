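---
title: "Methylation biomarker panel discovery: models and methods"
author: "methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation biomarker panel discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

# The problem

Tumor tissue shows reproducible DNA-methylation changes at specific CpG
sites, and a handful of well-chosen CpGs can separate tumor from normal
tissue with high accuracy. `methpanel` implements a complete
discovery-to-validation workflow for such compact marker panels on
beta-value array data: merge multiple cohorts, remove between-cohort batch
shifts, call differentially methylated probes (DMPs) with moderated
t-statistics, discretise each candidate probe into a binary methylation
state, rank candidates by random-forest feature elimination, assemble a
non-redundant panel under a correlation filter, and validate the panel on an
independent, heavily imbalanced cohort.

This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where more than one reasonable choice
existed. It states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

# Value spaces

A beta value is the methylated fraction at a probe, bounded in $[0,1]$ and
strongly bimodal on arrays. The M-value is its logit,
$M = \log_2\!\big(\beta/(1-\beta)\big)$, unbounded and closer to
variance-stable. All linear modelling (batch adjustment, group contrasts)
runs on M-values: effect sizes of the magnitude reported for tumor/normal
CpGs (group differences above 1, up to about 1.5) are impossible as beta
differences near the boundaries but natural on the M scale, and an additive
batch model is only defensible on an unbounded scale. `beta_to_m()` clips
betas into $[\varepsilon, 1-\varepsilon]$ (default $\varepsilon = 10^{-6}$)
so boundary values stay finite; `m_to_beta()` inverts exactly inside the
clip range.

# Batch adjustment

Cohorts merged by `merge_datasets()` get their cohort of origin as the batch
label. `batch_adjust()` removes additive batch effects probe by probe: each
value is shifted by minus its probe's batch mean plus the probe's grand
mean — exactly the fitted batch effect of a per-probe one-way ANOVA on
batch. This is the simplest model consistent with gene-wise mean-centering
practice; per-batch variance scaling (ComBat-style empirical Bayes) is
deliberately out of scope. The operation preserves each probe's grand mean
exactly, drives every between-batch sum of squares to zero, and is
idempotent — all three properties are asserted in the test suite.

# Differential methylation

`fit_probe_models()` computes, per probe, the tumor-minus-normal M-value
group difference (the table's `logFC`), the pooled within-group variance
$s^2_g$ on $d_g = n_t + n_n - 2$ degrees of freedom, and the scaling
$v_g = 1/n_t + 1/n_n$. `estimate_moderation()` fits the standard scaled
inverse-chi-square prior on the per-probe variances by the method of
moments on log variances: with $z_g = \log s^2_g$ and
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$, the prior degrees of freedom $d_0$
solve $\psi'(d_0/2) = \widehat{\mathrm{var}}(e) - \overline{\psi'(d_g/2)}$
(by Newton inversion of the strictly decreasing trigamma), and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. A non-positive excess
variance yields $d_0 = \infty$, i.e. complete shrinkage. The moderated
statistic is $t_g = \mathrm{logFC}_g / \sqrt{\tilde s^2_g v_g}$ with
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$, referred to a t
distribution on $d_0 + d_g$ degrees of freedom (capped at $10^6$, the
normal limit). The estimator is checked in the tests against an independent
reference implementation and against parameter-recovery simulations
($d_0$ within ±25 %, $s_0^2$ within ±10 % at 5,000 probes).

Multiple testing uses Benjamini–Hochberg step-up adjustment (the field
default where the adjustment is otherwise unspecified); `bh_adjust()` is
verified against a brute-force $O(m^2)$ min-over-tail oracle. DMPs are
called at the strict thresholds $|\mathrm{logFC}| > 1$ and adjusted
$p < 0.05$; both are configurable. Result tables sort by adjusted p
ascending with deterministic tie-breaks (|logFC| descending, then probe id).

# Binarization

Methylation readouts of a diagnostic probe are naturally two-state, and a
binary coding generalises across platforms far better than raw values.
`two_means_split()` computes the exact one-dimensional 2-means solution:
over the sorted values every split between distinct adjacent values is
scored by total within-cluster sum of squares, and the global optimum is
returned. In one dimension the optimal 2-means clustering is always a
contiguous split of the sorted values, so this enumeration *is* the global
optimum that seeded Lloyd iterations only approximate — binarization is
therefore fully deterministic. Ties go to the larger low cluster; the
stored threshold is the midpoint of the two boundary values, and a sample
codes 1 exactly when its value exceeds the threshold (the higher-methylation
cluster is always 1). Probes with all-identical values are degenerate and
are dropped with a warning. Equality with exhaustive brute force is a
property test over hundreds of random inputs.

For validation cohorts, `rebinarize_panel()` deliberately *recomputes* the
splits from the new cohort's own values instead of reusing training
thresholds: between-platform and between-cohort shifts move the absolute
scale but not the two-state structure.

# Panel selection

Candidates enter as binarized features. `rf_importance_ranking()` performs
recursive feature elimination: fit a seeded random forest, score features by
out-of-bag permutation importance (mean decrease in accuracy — chosen over
impurity importance, which is biased for correlated binary features), drop
the least important 20 % (configurable `elimination_fraction`; at least one
survivor), repeat. The final ranking is the reverse elimination order with
deterministic tie-breaks.

`greedy_panel_build()` walks the ranking: a probe is admitted only if its
absolute phi coefficient (Pearson correlation of 0/1 vectors) with every
already-admitted probe is below `corr_threshold` (default 0.7). The
correlation is computed on the binarized features because that is the space
the classifier sees; beta-space correlation would answer a different
question. After each admission the prefix is scored by stratified 10-fold
cross-validation (stratification is essential under imbalance — an
unstratified fold can lose the minority class entirely), pooling out-of-fold
predictions and scoring accuracy and Cohen's kappa once.
`choose_final_panel()` picks the prefix with the best accuracy, breaking
ties by higher kappa and then by parsimony; accuracy-primary with kappa
tie-break is one reading of "best accuracy and kappa", and the functions
expose both metrics so a kappa-primary choice is a one-liner.

All stochastic steps (fold assignment, forests) consume seeds derived from
one configuration seed, so the entire selection is a pure function of
(features, labels, seed).

# Imbalance-corrected validation

External cohorts are typically tumor-heavy (hundreds of tumors against a
few dozen normals). `validate_external()` runs: re-binarize the panel
probes on the new cohort, stratified 80/20 train/test split, smoothed-
bootstrap oversampling of the training minority to exact balance, fresh
seeded forest, scoring on the untouched test set. The test set is never
rebalanced.

`rose_oversample()` keeps every original training sample and adds synthetic
minority samples: a uniformly drawn minority sample plus independent
Gaussian noise per feature with the kernel bandwidth
$h_q = \big(4/((d+2)n_j)\big)^{1/(d+4)} \sigma_{jq}$ computed from the
minority class. Because the features are binary, the smoothed values are
thresholded at 0.5 back to $\{0,1\}$ by default so training and test
features live in the same space (`binary = FALSE` keeps the continuous
values). This is top-up oversampling — the canonical smoothed bootstrap
regenerates a whole dataset, but preserving all real samples wastes none of
a small cohort. A single-sample minority with zero variance degenerates to
exact duplication, with a warning.

`evaluate()` reports confusion counts with tumor as the positive class,
accuracy, and Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with the expected
agreement from the marginals; kappa is flagged undefined when $p_e = 1$.

# The synthetic-cohort generator

`simulate_cohort()` generates beta-space cohorts with the statistical
structure the pipeline assumes, so every stage is testable without array
downloads:

* **Bimodal baselines.** Probes alternate deterministically between a
  CpG-island-like low mode and an open-sea-like high mode
  (`baseline_modes`, default 0.15/0.85), reproducing the bimodal beta
  distribution that makes 2-means binarization meaningful. The assignment
  is deliberately seed-free so two cohorts simulated from the same
  configuration with different seeds share probe identities and planted
  directions — a validation cohort then genuinely contains the discovery
  panel's probes.
* **Signal blocks.** `n_signal_blocks` blocks of `block_size` redundant
  probes carry a tumor-vs-normal shift of `effect_m` M-units, sign
  alternating by block (both hyper- and hypomethylated markers exist in
  real panels).
* **Shared block states.** All probes of a block read one per-sample
  epigenetic state: a tumor lacks the block's shift with probability
  `tumor_flip_prob`, a normal carries it with probability
  `normal_flip_prob`, independently per block. This models tumor
  heterogeneity and field effects, keeps each probe's distribution cleanly
  bimodal (so binarization is robust at any class balance), makes probes of
  one block agree almost perfectly after binarization, and decorrelates
  different blocks. An earlier design using a shared Gaussian latent wide
  enough to decorrelate blocks was rejected: it destroys the bimodality
  and with it the meaning of the 2-means split, precisely under the heavy
  imbalance the validation step must survive.
* **Noise.** Independent per-(probe, sample) M-space jitter
  (`within_block_noise_m`), per-(probe, batch) shifts (`batch_sd_m`,
  batches assigned round-robin), and Beta-distributed measurement noise
  with concentration `precision` after back-transforming the latent means
  to beta space.

One global RNG stream per call, seeded from the configuration, makes every
cohort byte-reproducible. What the generator does **not** emulate: Infinium
I/II probe-chemistry biases, sex chromosomes, copy-number contamination, and
cell-type composition. Passing tests on synthetic cohorts therefore show
that the algorithms behave as specified under the stated statistical
structure, not that the structure captures everything in real arrays.

## The seeded recovery scenario

`default_recovery_scenario()` fixes the benchmark used by the acceptance
suite: 4 blocks of 5 probes, 500 null probes, 180 tumors / 20 normals over
2 batches, `effect_m = 3`, flips 0.45/0.03, `precision = 300`, seed 101.
The parameters follow from closed-form calculations rather than trial runs:

* With flip probabilities $p_t, p_n$ and tumor fraction $\pi$, two blocks'
  binarized features have
  $\phi \approx \pi(1-\pi)(1-p_t-p_n)^2 / \big(P(f)(1-P(f))\big)$; at
  $\pi = 0.9$, $p_t = 0.45$, $p_n = 0.03$ this is about 0.10, comfortably
  below the 0.7 admission cap and below 0.3, while same-block probes agree
  up to the (small) independent noise, $\phi$ near 1.
* A Bayes classifier on four such features predicts tumor when at least one
  block reads tumor-like (given the likelihood ratios 0.55/0.03 and
  0.45/0.97), giving expected accuracy around 0.95 on the discovery mix and
  around 0.95 on a 458/34 validation cohort after balancing — and a clearly
  worse expected accuracy (≈ 0.91) for any three blocks, so the
  cross-validated trace peaks at the full four-block panel.
* The expected M-space group difference is
  $\mathrm{effect}_m (1 - p_t - p_n) \approx 1.56$, safely above the
  calling threshold of 1 relative to its standard error, while null probes
  (standard error below 0.1) never approach it.

# The end-to-end driver

`run_pipeline()` executes simulate → merge → adjust → dmp → binarize →
select → validate from one `pipeline_config()`. The configured discovery
samples are split evenly over `n_batches` separately simulated cohorts
(each internally single-batch with its own batch shift), which the merge
step then relabels by cohort — mirroring how multi-series discovery data
actually arrive. Stage seeds are pure functions of one master seed and the
stage name, every artifact is written as TSV/JSON with deterministic
formatting, and `manifest.json` records configuration, seeds and the md5 of
every file; reruns are byte-identical. Validation of configuration happens
before any stage runs. A thin command-line wrapper over this function is
shipped in `inst/scripts/run_pipeline.R`; the package's functions are the
primary interface.

# Numerical choices and degenerate inputs

* Logit clipping at $\varepsilon = 10^{-6}$; beta/M round trips are exact to
  1e-12 inside the clip range.
* Trigamma inversion by Newton iteration with the closed-form asymptotes
  ($1/\sqrt{x}$ for large, $1/x$ for small arguments) as guards.
* All-zero residual variances abort moderation with an explicit error
  (jitter or plain-t fallback is the caller's decision); individual
  zero-variance probes are excluded from hyperparameter estimation with a
  warning and still receive a shrunken variance.
* Two-means ties break toward the larger low cluster; splits are only
  placed between distinct values, so labels always equal
  `value > threshold`.
* A forest asked to train on an all-constant feature matrix returns the
  majority vote directly (the ensemble backend cannot split, and its
  native implementation loops indefinitely on such input).
* Fold counts reduce automatically (minimum 2, with a warning) when a class
  is rarer than the requested folds.
* Test problem sizes: the acceptance suite uses 500-case oracle sweeps,
  5,000-probe moderation recovery, twenty 2,000-probe null replicates and
  the 520-probe recovery scenario; these sizes give the stated statistical
  tolerances comfortable margins while keeping a full run in minutes on one
  CPU.

# Known limitations

* Two-group designs only: no covariates, no multi-factor contrasts, no
  region-level (DMR) calling.
* Batch correction is mean-centering only; strong batch-by-class
  confounding (e.g. a tumor-only cohort) biases group means by design and
  is not repaired.
* Cross-validated accuracy of the *chosen* panel is an optimistic estimate
  of generalisation — the choice itself consumed the CV signal. Nested CV
  is deliberately out of scope; the external validation step is the honest
  check.
* Missing values are rejected, not imputed.
* The binary feature space discards within-state methylation gradation;
  probes whose diagnostic signal is a shift within one mode are invisible
  to this design.
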