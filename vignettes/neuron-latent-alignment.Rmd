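---
title: "Measuring one-to-one alignment between neurons and latent units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring one-to-one alignment between neurons and latent units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A population of visually responsive neurons and the latent layer of a
generative model can carry the same stimulus information while organising it
very differently. The distinction this package quantifies is *axis
alignment*: does each individual neuron track an individual latent unit
(one-to-one, up to sign), or does every neuron read out a diffuse mixture of
many units? The question matters because a one-to-one correspondence between
single cells and the independent factors of variation of the stimulus set is
the signature of a disentangled neural code, and distinguishing it from
"same subspace, rotated basis" requires statistics that are deliberately
*not* invariant to rotations of the latent space. Ordinary goodness-of-fit
measures (variance explained by a linear read-out) cannot tell the two
apart; the scores below can.

`neuralign` implements the complete analysis pipeline: sparse per-neuron
encoding models, an entropy-based alignment (completeness) score over the
resulting weight profiles, the Spearman variant of the Unsupervised
Disentanglement Ranking (UDR) for label-free comparison of representation
families, direct correlation-ratio statistics, and decoding of held-out
stimuli from one-to-one matched single neurons. Because the neural
recordings that motivated these analyses are restricted-access, the package
ships a synthetic-data module that plants the relevant structure with known
ground truth; every statistic is validated against it.

## The scores

### Sparse encoding weights and the alignment score

For each neuron $j$, a Lasso regression predicts its responses from the $D$
model units over the training stimuli:
$$\min_\beta \; \tfrac{1}{2S}\lVert n_j - Z\beta \rVert^2 + \lambda \lVert \beta \rVert_1 .$$
The penalty is chosen on a 100-point geometric grid (from $\lambda_{\max}$,
the smallest penalty with an all-zero solution, down to
$10^{-4}\lambda_{\max}$) by 10-fold cross-validation with the
one-standard-error rule: the *largest* (sparsest) $\lambda$ whose CV error
is within one standard error of the minimum. Standardization constants are
computed inside each training fold, and the final refit standardizes on the
full training set, so no held-out information leaks into the fit. The
nonnegative relative-importance matrix $R$ collects $|\beta|$ from the
refits (rows = units $d$, columns = neurons $j$).

The alignment score normalizes each neuron's weight profile to a
distribution $p_{dj} = R_{dj}/\sum_d R_{dj}$, measures its entropy in base
$D$, and weights by the neuron's share of total weight:
$$H(p_j) = -\sum_d p_{dj}\log_D p_{dj}, \qquad
  \rho_j = \frac{\sum_d R_{dj}}{\sum_{dj} R_{dj}}, \qquad
  C = \sum_j \rho_j\,(1 - H(p_j)).$$
$C = 1$ exactly when every explained neuron is explained by a single unit;
uniform weight spreading gives $C = 0$; a neuron that is not explained at
all ($R_{\cdot j} = 0$) simply contributes nothing. The score is invariant
to global rescaling of $R$ and, because the encoding weights enter in
absolute value, to sign flips of any unit.

### Variance explained, uninformative units, model filtering

Held-out predictive quality is scored per neuron as
$\mathrm{VE}_j = 1 - \sum_i(\hat n_{ij} - n_{ij})^2 / \sum_i(n_{ij}-\bar n_j)^2$
on the held-out stimuli (62 under the defaults, mirroring the original
2100/62 design). The mirror-image decoding direction predicts each
informative model unit from the full neural population. No noise-ceiling
normalization is applied: repeat-level neural data are not part of the data
model, so encoding VE is interpretable only comparatively.

Before any regression, *uninformative* units are zeroed out: a unit whose
scaled responses have variance below 0.01 is masked. Scaling divides the
whole matrix by its mean per-unit standard deviation rather than
standardizing each unit separately — strict per-unit standardization would
force every variance to 1 and make the threshold vacuous, while
matrix-level scaling keeps collapsed latent units detectable. This is a
deliberate resolution of an ambiguity in the procedure the pipeline
follows, and it is the single semantics used everywhere (`zero_uninformative()`).

At the family level, models sharing no information with the population are
excluded when their mean VE falls below the across-model mean minus one
standard deviation (`filter_models()`).

### UDR

Two independently built representations of the same data are compared
through the absolute Spearman correlation matrix between their informative
latents. With $r_a(b)$ the column maxima and $r_b(a)$ the row maxima,
$$\mathrm{UDR} = \frac{1}{d_a + d_b}\Big[\sum_b \frac{r_a(b)^2 I(b)}{\sum_a R(a,b)}
  + \sum_a \frac{r_b(a)^2 I(a)}{\sum_b R(a,b)}\Big],$$
which is 1 for an exact permutation structure and degrades as correlation
mass spreads off the matching. A model's score is the median over its
pairwise comparisons. Two implementation notes. First, the informativeness
mask in the original formulation comes from the posterior KL of trained
variational models; without trained models the package reuses the
variance-based mask of `zero_uninformative()`, which identifies the same
collapsed-unit phenomenon from responses alone. Second, the printed form of
the score leaves the binding of the maxima ambiguous; the package uses
column/row maxima — the only reading under which an identity similarity
matrix scores exactly 1. Note also that with finite stimulus sets the
off-matching Spearman entries are $O(1/\sqrt S)$ rather than zero, so even
exact permuted copies of a model score slightly below 1; the analytic value
1 is reached exactly for permutation-matrix inputs.

### Correlation ratio and unit proportion

A regression-free check: per neuron, the maximum absolute Pearson
correlation with the informative units divided by the sum of those
correlations (sharpness of one-to-one coupling), and the number of distinct
best-matching units divided by the number of informative units (diversity).
Neurons are grouped by best unit and the maximum ratio per group is averaged
across groups; the phrase describing the original aggregation admits a
"mean within group" reading too, so that variant is available behind
`group_stat = "mean"`. Ties in the best-unit argmax break to the lowest
unit index, deterministically.

### One-to-one matched decoding

Each informative unit is paired with a distinct neuron by minimizing
$\sum (1 - D_{ij})$ over one-to-one assignments, where
$D_{ij} = \mathrm{Corr}(z_i, n_j)$ is the *signed* Pearson correlation over
training stimuli, solved exactly with the Kuhn–Munkres algorithm
(implemented in the package as a shortest-augmenting-path solver and
verified against exhaustive enumeration). Signed correlation follows the
original procedure; the univariate regression that then decodes each unit
from its matched neuron absorbs sign only where a genuinely anti-correlated
match was still selected, so a diagnostic warns when a unit's best absolute
correlation greatly exceeds its best signed one. Predictions on held-out
stimuli use standardization constants from the training stimuli only. They
are scored by the mean cosine distance to the true (standardized) latent
responses, and — for synthetic worlds — by feature-space reconstruction
error after mapping the predicted units back to factor space through the
model's ground-truth linear map and rendering through the world's decoder.

## What the synthetic worlds emulate

`generate_world()` plants the structure the statistics are designed to
detect: $K$ independent standard-normal factors over $S$ stimuli; $J$
neurons, each dominated by one factor (dominant loading of magnitude 1,
random sign) with several neurons per factor (redundancy $\approx J/K$);
additive Gaussian response noise; and a random linear decoder from factors
to observable features standing in for the stimulus-rendering pathway. The
model zoo supplies the comparison arms: `disentangled` (a factor subset
under permutation/sign, optionally rotated smoothly toward entanglement via
`mixing`), `rotated` (full orthogonal mixture of the same subset — the
critical control carrying identical information in a rotated basis),
`sparse_random` (factor-independent draws, soft-thresholded so each unit's
fraction of near-zero standardized responses matches a reference
disentangled sibling — one concrete reading of "sparseness-matched"), and
`pca_like` (leading principal directions of the neural matrix).

Three generator choices deserve explanation:

* **Random loading signs.** Real populations contain neurons tuned in both
  directions along a coding axis. The signed-correlation matching step
  *requires* this: with all loadings positive, a sign-flipped model unit
  would have no positively correlated partner anywhere in the population
  and matching would degrade for reasons no real recording would produce.
* **Noise scale.** The default neural `noise_sd = 0.5` with unit loadings
  plants a per-neuron signal fraction of $1/(1+0.25) = 0.8$, so held-out
  encoding VE has a known calibration target; the acceptance suite checks
  the pipeline recovers the planted 0.8 within ±0.05 (the one-SE refit is
  penalized, so the recovered median sits slightly below the ceiling).
  Model-side latent noise defaults to 0.1 in the comparison arms — enough
  to avoid degenerate perfect fits, small enough not to mask the orderings.
* **Default scale.** $S = 500$, $K = 8$, $J = 60$ keeps the Lasso stage
  (100 penalties × 10 folds × 60 neurons) comfortably on one desktop CPU
  while leaving sampling error well below the effect sizes of the planted
  orderings; the spirit of the emulated design (159 neurons × 2100 stimuli,
  10–50 latent units) is preserved at reduced scale.

What the worlds do **not** emulate: trial-to-trial neural variability with
stimulus repeats (hence no noise-ceiling correction), non-Gaussian or
correlated factor distributions, nonlinear factor-to-response maps, and any
actual image semantics — factors are abstract. Passing tests therefore
demonstrate that the statistics behave as designed on populations with
planted axis codes, not that any particular biological population is so
organised.

## Numerical decisions

* Standard deviations use the $n-1$ divisor throughout, except inside the
  penalty-grid computation where the $n$ divisor matches the solver's
  internal standardization exactly.
* Constant columns standardize to all-zero columns and are flagged, never
  errors: a collapsed latent unit is a meaningful outcome. Correlations
  involving constant vectors are defined as 0.
* Entropy uses $0\log 0 = 0$; the alignment entropy is base-$D$, the
  rater-consensus entropy is natural-log — they are different statistics.
* Solver coefficients whose standardized effect size falls below $10^{-8}$
  are exact zeros: coordinate-descent warm starts leave $\sim 10^{-17}$
  residue on structural zeros, and a support polluted by such dust would
  corrupt an entropy-based score that only looks at which entries are
  nonzero (a single spurious "support of one" can score a null model at
  the ceiling).
* CV folds are a seeded stimulus permutation cut into contiguous blocks;
  every randomized operation takes an explicit seed and per-stage seeds
  derive from one master seed, so any stage can be re-run in isolation.
* Zero denominators in the UDR terms contribute 0; assignment requires at
  least as many neurons as informative units and errors otherwise; the
  quantile in top-fraction UDR selection uses linear interpolation with
  ties kept.
* For the recombined-response control, the original procedure skips
  uninformative-unit zeroing (it changes the weights' sparsity there) and
  drops to 3 CV folds; `alignment_pipeline(zero_units = FALSE,
  cv_folds = 3)` reproduces exactly that.

## Known limitations

The alignment score inherits the known blind spots of completeness-style
measures: it does not penalize several neurons locking onto the *same*
unit (that is what the unit-proportion score is for), and it is undefined
for a single-unit model. Encoding VE without a noise ceiling is
comparative, not absolute. The rater-consensus chance level is estimated by
Monte Carlo under a uniform-choice null rather than quoted, because
published chance figures for such designs are not always derivable from
the stated choice set. The package deliberately omits
representational-similarity and CKA comparisons, elastic-net variants, and
everything upstream of response matrices (model training, image handling,
spike sorting).

## A worked run

```{r, eval = FALSE}
library(neuralign)
cfg <- study_config(master_seed = 42)
report <- run_full_comparison(cfg,
                              default_recipes(K = 8, noise_sd = 0.1, seed = 42),
                              S = 500, K = 8, J = 60, n_ceiling_subsets = 10)
report
write_run_report(report, "run42")
```

The disentangled arm should dominate every score, the rotated arm should
match it on variance explained while collapsing on alignment (same
information, wrong basis), the sparse-random arm should explain nothing,
and the subset ceiling should sit below 1 exactly because the population
codes each factor redundantly. The README shows the numbers this run
prints.
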