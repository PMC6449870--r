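---
title: "Methods: phenotypic screen profiling and reprogramming progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic screen profiling and reprogramming progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reprophen` implements the analysis stack of an early-reprogramming RNAi
screen: high-content colony-feature profiling with plate normalization,
phenotype clustering, two-axis hit ranking, transcriptome cross-correlation,
a polynomial-curve progression (pseudotime) model, and a multiplicative
epistasis test for double knockdowns. This vignette explains the models, the
parameters that matter, the synthetic-data generator the package is tested
against, and the numerical choices made where the design was genuinely open.

```{r setup}
library(reprophen)
```

## 1. Plate normalization and feature selection

A screen plates a few hundred siRNA knockdowns across multi-well plates,
images reprogramming colonies (CDH1/SALL4 staining), and extracts tens of
numeric features per well: marker intensities, colony size and counts,
symmetry, and texture filters. Plates are batches, so every feature is
standardized **per physical plate** to the Z-score
$z = (x - \bar x_{plate}) / s_{plate}$, with the sample SD ($n-1$) over all
wells of the plate, controls included. Each replicate transfection of a
library plate is imaged as its own plate and normalized separately. A
feature that is constant on a plate carries no signal there; it is set to 0
with a warning rather than propagating a division by zero.

Replicate wells are then averaged per target (arithmetic mean, missing
wells skipped, replicate counts recorded), and redundant features removed:
two features with absolute Pearson correlation above a threshold (default
0.8) are considered interchangeable. Which member of a redundant pair to
keep is not dictated by the threshold, so the package scans features in
order of decreasing variance across targets (ties broken by name) and keeps
a feature only if it is below-threshold against everything already kept.
This is deterministic, keeps the most informative member of each group,
yields a retained set whose maximum pairwise |r| is at most the threshold,
and is idempotent; the test suite verifies those properties against a
brute-force subset enumeration on small feature sets.

## 2. Phenotype clustering and hit ranking

Knockdown profiles (retained-feature Z-vectors) are partitioned with
K-means, Euclidean metric, 25 random restarts under a fixed seed; `k`
defaults to 5, the number of major colony phenotypes the assay
distinguishes (reference/normal, enhanced, blocked/low-marker, irregular,
dense). Feature columns are ordered for display by average-linkage
hierarchical clustering on Euclidean distance; this ordering is cosmetic
and feeds nothing downstream. The cluster holding the majority of
non-targeting (nt) controls is flagged as the reference, "normal
reprogramming" phenotype.

Hits are ranked on two axes:

* **Control correlation** — Pearson correlation of each knockdown's profile
  with each positive-control profile (Trp53, Myc, Oct4), combined into one
  score. The combination rule is deliberately simple: the arithmetic mean
  of the available control correlations (a `max` alternative is exposed).
  The mean is symmetric in its inputs, bounded in [-1, 1], and indifferent
  to feature scaling.
* **Facilitator prediction** — two classifier families are trained to
  recognize the profiles of known reprogramming facilitators (e.g. Tet2,
  Jarid2, Setdb1 in a real library), treating all unlabelled targets as
  negatives: a ridge-penalized logistic model (`glmnet`, fixed small
  lambda) and a probability random forest (`ranger`). Each emits a score
  in [0, 1]; the ensemble score is their mean. Scores for training targets
  use the forest's out-of-bag predictions to avoid memorization;
  generalization is reported as stratified 5-fold cross-validated AUC.
  Positive-unlabelled refinements are intentionally out of scope — the
  negatives are simply everything unlabelled.

The hit list is the union of the top `n_corr_top` (default 20)
correlation-ranked targets, the targets above the `ml_quantile` (default
0.95) quantile of the ensemble score, and an optional user-supplied
inclusion list for low-scoring "roadblock" candidates.

## 3. Transcriptome correlation and cross-modal concordance

Counts are normalized to log2(CPM + 1); genes are ranked by the variance of
that quantity across all samples and the top `n` (default 200) retained.
Variance is computed on the log scale so a handful of high-abundance genes
cannot dominate the selection. Replicates are averaged per condition
*before* correlating, and the knockdown-by-knockdown Pearson matrix is
computed over the selected genes. The same correlation is computed between
high-content profiles, and the two matrices are joined per unordered
condition pair: pairs exceeding thresholds on both axes — similar colony
phenotype *and* similar transcriptome — are flagged as candidate functional
interactions. Pairs are ordered by a concordance score, the product of the
two correlations when both are positive and 0 otherwise.

## 4. The progression (pseudotime) model

Reprogramming progression is modelled in a 2-D PCA embedding of the
log-normalized expression of the most variable genes, with the axes
swapped: x is PC2 and y is PC1, because in this assay the second component
tracks time while the first carries the dominant off-time variation. All
points are rotated by a fixed angle (default 15° counter-clockwise), a
second-order polynomial $y = c_0 + c_1 x + c_2 x^2$ is fitted by ordinary
least squares to the time-course samples within the fit window (default
days 2–7; the fibroblast starting state sits off the later trajectory), and
every sample is projected onto the curve by shortest Euclidean distance.
The projected x is the **pseudotime proxy**; the distance to the curve is
the **off-trajectory residual**, expression change unrelated to
progression.

Numerical choices:

* **Projection.** The squared distance from a point to the curve is a
  quartic in x whose stationary points solve a cubic; the package finds all
  real roots with `polyroot`, restricts them to the fit domain, always
  includes the domain endpoints, and takes the global minimum. Exact ties
  are broken toward smaller x — the earlier pseudotime, the conservative
  choice when calling delays. Clamping to the fit domain avoids trusting a
  quadratic outside the range it was fitted on. A dense-grid oracle in the
  test suite confirms optimality on 1,000 random instances.
* **Axis signs.** PCA signs are arbitrary, so x is oriented so that
  time-course day increases with x. The y orientation is chosen so the
  fitted arc opens downward. This is not cosmetic: rotating an
  upward-opening arc counter-clockwise can fold its late part back (x no
  longer monotone along the curve), making "y as a function of x"
  ill-posed; with the downward orientation the fold, if any, lands before
  the fit window.
* **Day calibration.** Each fitted day's mean coordinate is projected onto
  the curve, the day-to-x map is made monotone by isotonic regression, and
  day estimates for arbitrary samples interpolate that table piecewise
  linearly, clamped at its ends. This makes statements like "comparable
  with day 3–4 cells" well defined. Knockdowns whose day estimate trails
  the nt-control estimate by more than a threshold (default 1 day) are
  flagged delayed.

## 5. Epistasis from colony counts

For a gene pair $(a, b)$, per-replicate colony ratios divide each
condition's counts by the mean of the control replicates. Under
independent action the expected double-knockdown ratio is the product of
the single-knockdown mean ratios, $E = \bar r_a \bar r_b$; functional
interaction is a significant deviation of the observed double ratios from
$E$ (two-tailed, default $\alpha = 0.05$). A positive mean difference —
more colonies than expected — is an alleviating interaction, the signature
of genes acting in one pathway or complex (as for Brca1–Bard1).

The expected ratio is *estimated*, not known: it carries the sampling noise
of the two single-knockdown means and of the shared control mean. The
default test therefore propagates that uncertainty into the standard error
by the delta method (gradient of $\bar d/\bar c - \bar a\bar b/\bar c^2$
in the four group means, Welch–Satterthwaite degrees of freedom). A plain
one-sample t-test of the observed ratios against $E$ as a constant is kept
as `method = "one_sample"` for comparison; because it ignores the noise in
$E$ it is markedly anti-conservative — at cv 0.1 with 6 replicates it
rejects a true null about a quarter of the time, versus ~0.05 for the
delta form (both measured by the package's own Monte-Carlo calibration,
`epistasis_calibration()`). When all variances vanish the test degenerates
to an exact comparison and is flagged as such.

## 6. The synthetic-data generator

Every stage is exercised on simulations with planted ground truth; the
generator is first-class, tested code.

**Screen** (`generate_screen`). Each library target occupies one well on
one plate; every plate carries 7 nt controls and the 3 positive controls;
the whole layout is transfected in quadruplicate (defaults: 6 plates of 96
wells, 300 targets, 40 features). A well's feature vector is class
archetype + plate offset + noise: archetypes are group-level sign patterns
(intensity, size, symmetry, texture) scaled by `class_effect_size`
(default 3 SD) with per-feature jitter (0.5 × effect) so that same-group
features correlate realistically without being duplicates; plate offsets
are N(0, 0.5) per plate × replicate × feature; well noise is N(0, 1).
Class frequencies default to 47/12/6/20/15% — most knockdowns are
phenotypically silent, and the control-like "blocked" class is kept under
a tenth of the library so top-decile recall is a meaningful statistic.
Targets planted in the blocked class are facilitators (their knockdown
blocks reprogramming, like siMyc/siOct4); enhanced-class targets are
blockers (like siTrp53); the rest are neutral.

**Time course** (`generate_timecourse`). Time samples lie on a latent
parabola $(u, v) = (t - \bar t,\ \alpha (t-\bar t)^2)$ in day units
(days 0–7, 3 replicates); a knockdown at progression $p$ with offset $o$
sits at the curve point plus $o$ times the unit normal **on the convex
side**, where the nearest-point projection is single-valued for any offset.
Latent coordinates are lifted to per-gene log means through a pair of
orthonormal loadings concentrated on `n_signal_genes` (default 600 of
2000) and scaled by `loading_scale` (default 4); counts are
negative-binomial (dispersion 0.1) with per-sample expected totals of
`library_size` (default 1e6). The defaults were chosen so the generative
geometry is well-posed for the projection method as specified: the
curvature $\alpha = 1$ makes the off-time axis carry more variance than
the time axis (so the PC swap holds — this requires roughly
$\alpha > 0.55$ for a 0–7 day range); concentrating and bounding the
loadings keeps signal genes clear of the zero-count floor so the lift to
log expression is near-isometric and planted offsets translate into
proportional residual distances. With a linear-in-time latent geometry or
much weaker curvature, PC1 would capture time and the axis swap — a fixed
part of the method — would point x off-time.

**Colonies** (`generate_colony_counts`). Means follow the multiplicative
model $E[\text{double}] = \text{control} \cdot e_a e_b \gamma_{ab}$ with
mean-preserving lognormal replicate noise at a given CV; $\gamma = 1$ is
the null. `cv = 0` collapses to the exact product rule, used as a
closed-form oracle in the tests.

### What the simulations do and do not show

The generator reproduces the *statistical structure* the analysis assumes —
additive plate batches, class-structured correlated features, a smooth
low-dimensional expression trajectory, multiplicative colony noise. It does
not emulate segmentation artifacts, spatial within-plate gradients (edge
effects), siRNA off-target signatures, mixed or ambiguous phenotypes, or
trajectories whose intrinsic dimension exceeds two. Passing recovery tests
therefore demonstrates correctness of the implementation under its stated
model, not performance guarantees on any real screen.

## 7. Problem sizes and reproducibility

The bundled demonstration (`run_demo()`) and the test suite run the full
screen at its natural scale (300 targets × 4 replicates × 40 features), the
time course at 2,000 genes × 114 samples, 10-seed recovery sweeps, a
10,000-pair null calibration for the acceptance run (2,000 pairs in the
demo), and 1,000-instance projection-oracle sweeps; everything completes in
a few minutes on one CPU. All randomness flows from explicit integer seeds;
rerunning any generator or stage with the same configuration reproduces its
output bit for bit, and package functions restore the caller's RNG state.

## 8. Known limitations

* k for K-means is fixed by the user (default 5); no automatic selection.
* The negative class for the facilitator ensemble is "everything
  unlabelled", so its scores are biased low when many true facilitators are
  unlabelled.
* The progression model is strictly 2-D with a degree-2 curve; trajectories
  that fold in the plane or need more dimensions violate its assumptions
  (general principal-curve fitting is out of scope).
* The epistasis test treats one pair at a time; no multiplicity correction
  across pairs is applied, matching a confirmatory single-pair design.
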