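---
title: "Methods: repeated-measures multi-omic inference with pairedomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-measures multi-omic inference with pairedomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedomics)
```

## The setting and the model

pairedomics targets paired intervention cohorts: each subject is profiled
at two timepoints (`pre`, `post`) across one or more omic layers — global
metabolic profiles (NMR-style feature matrices, possibly with a ppm axis),
taxa abundance tables and gene-catalogue read counts — together with
clinical covariates such as BMI and HbA1c. Two inferential questions
drive the design:

1. *Which features change with the intervention?* Answered by the
   repeated-measures Monte-Carlo cross-validated PLS-DA engine
   (`run_rm_mccv_plsda()`), backed by paired univariate tests.
2. *Which features track clinical state across subjects?* Answered by
   OPLS-DA between phenotype groups, Spearman/partial-Spearman networks,
   and β-diversity statistics for the microbiome.

The working model for intensity data is multiplicative: observed
intensity = dilution × exp(baseline + subject effect + condition effect +
noise). Three consequences shape the default pipeline:

* **Median fold change normalisation** (`median_fold_change_normalise()`)
  removes the per-sample dilution factor by dividing each sample by the
  median ratio to the median spectrum. The median-ratio step is iterated
  to its fixed point (step change < 1e-10, at most 1000 iterations), so
  renormalising an already-normalised table returns factors of 1 within
  1e-9. Ratios are taken only over features where both the sample and the
  reference are strictly positive; a zero-ratio feature carries no
  dilution information.
* **Log transform** (`log_transform()`): after dilution correction the
  data remain log-normal, and the subject effect is multiplicative. The
  within-subject transform removes subject effects exactly only when they
  are additive, so paired modelling operates on the log scale by default
  (`run_config(log = TRUE)`). On raw intensities the subject effect
  rescales each subject's pre/post difference and inflates the bootstrap
  coefficient dispersion enough to mask even large planted effects.
* **Scaling**: unit-variance scaling for serum/urine-like data, Pareto
  (divide by the square root of the standard deviation) where a few
  dominant resonances would otherwise monopolise the model, as with
  faecal spectra. Zero-variance columns are left as centred zeros rather
  than raising an error, since masked or constant features are routine.

## The RM-MCCV-PLSDA engine

`run_rm_mccv_plsda()` proceeds as follows. The feature table is
within-subject transformed — each row replaced by its deviation from the
subject mean, so a complete pair becomes two sign-opposed rows; the
transform is idempotent, which lets the engine accept raw or
pre-transformed input. Optional covariate adjustment replaces each
feature by its least-squares residual on an intercept plus the named
covariates (applied to X only; adjusting the class vector as well is a
defensible alternative but changes the estimand). The matrix is then
centred and unit-variance scaled once, before the Monte-Carlo loop,
mirroring the usual centre-and-scale-the-dataset convention for this
engine; per-split rescaling would be marginally more conservative.

Each of `n_models` (default 1000) iterations draws a test set of
`test_fraction` (default 0.3) of the *subjects* — samples of one subject
never straddle the split. A one-predictive-component PLS-DA (NIPALS) is
fitted on the training samples with the timepoint as the class (coded
±1, post positive); the model is oriented so the post class has positive
mean training score, stabilising score signs across iterations. Held-out
samples are projected to accumulate the cross-validated predictive score
T_pred (mean and variance over the iterations in which the sample was
held out; a sample never held out would be reported as missing). Within
each iteration, `n_boot` (default 25) bootstrap resamples of the training
subjects are refitted and their coefficient vectors collected.

Variable inference pools all `n_models × n_boot` coefficient draws:
z = mean(draws)/SD(draws), p = two-sided normal tail, q =
Benjamini–Hochberg. The SD of subject-resampled coefficient draws is a
bootstrap estimate of the coefficient's sampling error, so z is a
standard bootstrap z statistic; because it also absorbs between-split
variability it errs on the conservative side, which the null-calibration
test confirms (fraction of features at q ≤ 0.01 under the null stays
below 1 %). The per-feature decision threshold is q ≤ 0.01, displayed as
Manhattan scores −log₁₀(q) × sign(β) with a dotted cut line; q-values of
exactly zero are clamped to the smallest positive double with a warning
rather than producing infinities.

Parameters that matter:

| parameter | default | meaning |
|---|---|---|
| `n_models` | 1000 | Monte-Carlo train/test splits; 200 is used in the test suite, which agrees with the full engine on strong effects (Jaccard ≥ 0.9 on selected sets) |
| `n_boot` | 25 | bootstrap refits per split (subject-level resampling) |
| `test_fraction` | 0.3 | held-out subject fraction per split |
| `q_threshold` | 0.01 | BH FDR level for variable significance |

## PLS, OPLS and jackknifed coefficients

`fit_plsda()` is NIPALS with deflation (tolerance 1e-10, maximum 500
iterations; with a single class vector the inner loop converges in one
pass). Components are oriented so each score correlates non-negatively
with the class. `fit_oplsda()` extracts `n_orth` components whose scores
are exactly uncorrelated with the class (the orthogonal weight is the
loading minus its projection on the predictive weight), then fits the
predictive component on the filtered matrix; `n_orth = 0` reproduces
one-component PLS exactly. Q²Y uses 7-fold venetian-blind
cross-validation by default (a SIMCA-style convention; the fold count is
a package choice, not a claim about any particular software), with whole
subjects kept in one fold when a grouping is supplied, and a bounded
reshuffle if a training fold ever loses a class.

`coefficient_inference()` reports, per feature, the correlation loading
r (Pearson correlation with the full-model predictive score), and a
jackknife 95 % CI: refits over the CV segments give coefficient vectors
b⁽ˢ⁾, SE² = (S−1)/S · Σₛ(b⁽ˢ⁾ − b̄)², CI = b ± t₀.₉₇₅,S₋₁·SE. A feature is
*selected* iff |r| strictly exceeds `r_threshold` (default 0.35) **and**
the CI excludes zero. The threshold is applied to |r|; applying it to
signed r would only ever be more restrictive for negatively associated
features and has no support in the selection rule's usual usage.

## Association statistics

* Paired differences use the two-sided Wilcoxon signed-rank test,
  group comparisons the two-sided Mann–Whitney U test. Exact null
  distributions are used for n ≤ 25 pairs (signed-rank) or min(n₁,n₂) ≤ 10
  (Mann–Whitney) when ties permit, otherwise the continuity-corrected
  normal approximation. A feature with all-tied values reports p = 1 with
  a flag instead of failing.
* `spearman_matrix()` reports rank correlations with BH q-values over the
  emitted family (one family per call; family scoping beyond that is the
  caller's responsibility). p-values use the exact small-sample null when
  the data are tie-free and small, else the t approximation — the same
  rule as base R's correlation test, and the exact branch is what the
  permutation-oracle test checks.
* `partial_spearman()` is the Pearson correlation of the residuals of
  rank-transformed x and y on an intercept plus rank-transformed
  controls, with p from a t distribution on n − k − 2 degrees of freedom.
  With one control it agrees with the classical recursion formula on rank
  correlations to within sampling error.
* `overlap_report()` defines pairwise *commonality* as
  100·|A∩B|/|A∪B| — the only reading consistent with a 175-member union
  sharing 7 members being called 4 % — and also reports
  percent-of-reference shares 100·|A∩B|/|A|. Region counts always sum to
  the union cardinality. Set membership uses a strict q < α rule
  (default α = 0.05).
* `balanced_error_rate()` computes BER = 0.5 × (FPR + FNR): 0 for a
  perfect classifier, 0.5 for random predictions on balanced truth, 1
  for systematic inversion.

## Microbiome statistics

Bray–Curtis dissimilarities come from vegan; PCoA is the classical
eigen-decomposition of the double-centred −½D² matrix, with negative
eigenvalues reported but uncorrected (no Lingoes/Cailliez adjustment) and
axis variance proportions taken over the positive spectrum.

`permanova()` computes the one-way pseudo-F from among/within sums of
squared dissimilarities. Free permutations shuffle labels; the
repeated-measures ("nested") variant restricts permutations to
within-stratum shuffles, which for complete pre/post pairs is a
within-subject timepoint swap — the natural exchangeability under the
paired null. Sampled p-values use the +1 convention (the observed
labelling counts as a permutation, so p is never 0); exhaustive mode
enumerates all distinct two-group splits, or all 2^S swap patterns with
strata (capped at 20 strata). The implementation is cross-checked against
vegan's PERMANOVA in the test suite.

`gene_richness()` rarefies each sample to a fixed depth (the
field convention is 7 × 10⁶ reads and 30 draws) *without* replacement:
each draw is a uniform random permutation of the sample's reads, and
richness counts the distinct genes among the first `depth` of them. This
is exactly multivariate hypergeometric subsampling, and because a draw's
permutation does not depend on the depth, richness is monotone in depth
for a shared seed — a property the test suite exploits. Samples with
fewer reads than the depth are flagged and skipped.

## STOCSY

`stocsy_trace()` correlates the driver variable (snapped to the nearest
grid point; the snapped ppm is echoed) with every variable across
samples, reporting correlation and covariance on the ppm axis.
`stocsy_peak_candidates()` collapses contiguous runs of r ≥ threshold to
a single apex chosen by maximum |covariance| — on noiseless data whole
runs can tie at r = 1, and the covariance tie-break resolves to the true
resonance maximum. `peak_relative_concentration()` uses the apex (maximum)
intensity in a ppm window by default; a trapezoidal integral mode is
available where peak-shape stability across samples is in doubt.

## The synthetic-data module

The generators produce every input the pipeline consumes, with ground
truth returned for recovery testing. Design choices:

* Paired matrices: log-normal intensities; subject random effects are
  drawn per subject *and* feature (a scalar per-subject offset would be
  indistinguishable from dilution and vanish under MFC); affected
  features receive an additive log-scale shift at `post`; per-sample
  dilution factors are uniform on `dilution_range`. Defaults
  (`effect_size = 1.5`, `subject_sd = 1`, `noise_sd = 0.5`,
  `dilution_range = c(0.5, 2)`) are simulation conventions chosen to be
  realistic for global profiling data, not estimates from any cohort.
* Spectra: multiplets are Gaussian lines with Pascal's-triangle
  intensity ratios — only the correlation structure matters for STOCSY
  tests, so Lorentzian lineshapes, phase and baseline artefacts are
  deliberately out of scope.
* Taxa: log-normal composition vectors, group shifts applied on the log
  scale before renormalisation, multinomial counts at fixed depth.
* Gene catalogues: power-law abundances, multinomial reads (totals are
  conserved exactly).
* Covariates: rank-standardised anchor feature mixed with independent
  noise at weight ρ, so the realised Spearman correlation approximates
  the target.

One user seed is expanded into per-component seeds by seeding R's RNG
with it and drawing the required number of integers below 2³¹ − 1
(`pairedomics:::split_seed`); every generator and the engine are pure
functions of their arguments including the seed.

What the generators do *not* emulate: realistic NMR lineshapes and
alignment errors, compositional zero-inflation structure, chimeric reads,
realistic taxonomies, or feature–feature correlation beyond shared
molecules. Passing recovery tests therefore demonstrates the estimators'
correctness under the stated model, not robustness to every artefact of
real spectra.

## Problem sizes in the test suite

The suite runs the engine at 20 subjects × 200 features with
`n_models = 200`, `n_boot = 10` (null calibration over 10 seeds; power on
10 features planted at effect 2), checks scaled-vs-full engine agreement
at `n_models = 1000, n_boot = 25`, and uses 20 × 5000 matrices for
dilution recovery — sizes chosen so each property is measured at
realistic dimensionality while the whole suite stays quick to run.

## Known limitations

* The engine fits a single predictive component; multi-component
  predictive structure is out of scope.
* BH families are per call; reconstructing a study's exact family
  structure across biofluids is left to the caller.
* PERMANOVA is one-way (plus strata); factorial designs are not
  implemented.
* MFC assumes a majority of features are not changing; with pervasive
  effects the median ratio absorbs part of the signal.
* The exhaustive PERMANOVA modes are limited to two groups and to strata
  of size two, matching the paired designs they exist to test.
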