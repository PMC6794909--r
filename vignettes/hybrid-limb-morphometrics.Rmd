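---
title: "Quantifying hybridization effects on limb-bone shape"
author: "morphohybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hybridization effects on limb-bone shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphohybrid)
```

## The problem

First-generation equid hybrids — mules (donkey sire x horse dam) and hinnies
(the reciprocal cross) — have long been bred for working qualities exceeding
those of either parent. Whether and how that "vigor" is expressed in the
skeleton is a quantitative question about shape: do hybrid limb bones sit
between the parental mean shapes, closer to one parent (phenotypic
dominance), or outside the parental axis altogether (transgression)? And does
hybridization perturb the covariation structure (morphological integration)
that normally ties developmentally and functionally related bones together?

morphohybrid implements the full quantitative pipeline for such a study on 3D
landmark data: Procrustes superimposition, shape-space ordination and group
tests, disparity, allometry, explicit transgression/dominance statistics, and
two-block PLS integration analysis — together with a synthetic-data generator
that produces studies with known ground truth, so every estimator in the
chain can be validated end to end.

## Superimposition and shape variables

Each bone is analyzed separately. Configurations of k 3D landmarks are
centered, scaled to unit centroid size and iteratively rotated to their
consensus (generalized Procrustes analysis). Design choices:

* **Full Procrustes fit.** Every configuration is scaled to unit centroid
  size; size is analyzed separately as log10 centroid size. Shape variables
  are therefore scale-free.
* **Proper rotations only.** Reflections are never absorbed by the fit;
  antimeres must be mirrored explicitly upstream
  (`reflect_configurations()`), since silently mirroring anatomical data
  hides real asymmetry.
* **Convergence.** Iteration stops when the root-mean-square change of the
  consensus falls below `tol = 1e-10` (at most `max_iter = 100` iterations;
  non-convergence is reported, not hidden). Realistic within-study samples
  converge in a handful of iterations; convergence is slow only for samples
  whose shapes are almost unrelated.
* **Canonical orientation.** GPA is defined only up to a global rotation, so
  the converged consensus is oriented along its principal axes with a
  deterministic sign rule; reruns and reordered inputs give identical output.
* **Tangent projection.** Shape variables are the flattened deviations from
  the consensus, orthogonally projected onto the tangent space at the
  consensus (the `projection = "residual"` switch gives raw Procrustes
  residuals instead). For the shape distances seen within a species the two
  differ by well under 1%.

## Group tests, disparity, allometry

PCA is computed on the pooled per-bone shape variables; downstream location
tests use the smallest leading set of PCs explaining 90% of the variance
(configurable). Group mean differences use Wilks' lambda with its F
approximation, pairwise over groups with Bonferroni correction; with a single
retained PC the test reduces exactly to the classical F test, which the test
suite checks. A crossed species-by-sex MANOVA (geldings excluded) guards the
pooled analyses: any bone with a significant interaction is rerun stratified
by sex, since pooling sexes would then mix two different species contrasts.

Disparity is the Procrustes variance: the mean squared distance of group
members to their group mean (divisor n, for comparability with the common
geomorph convention). Group differences in disparity are tested by permuting
group labels (999 permutations by default, p-values with the +1 correction,
Bonferroni over pairs).

Allometry is assessed two ways: the fraction of total shape variance
explained by log10 centroid size, `trace(SS_model)/trace(SS_total)`, with a
permutation test on the size vector; and a test of common allometric slopes
comparing `shape ~ size + group` to `shape ~ size * group` under residual
randomization (RRPP): residuals of the reduced model are permuted and added
back to its fitted values, and the interaction F recomputed. A small p-value
means the slopes are *not* parallel. Note that when groups differ in both
size and mean shape (as parent species do), the pooled shape-on-size
regression partly reflects the group contrast, not within-group allometry —
its R^2 should be read as "how much of the shape variation is predictable
from size in this sample", the usual diagnostic reading of pooled
multivariate allometry.

## Transgression and dominance

For each bone the group mean shapes of donkeys (D), horses (Ho) and hybrids
(Hy) are computed in the full tangent-space shape variables and the Euclidean
distances between them measured. With d the Euclidean distance:

* transgression % = (dDHy + dHoHy − dDHo) · 100 / dDHo — zero exactly when
  the hybrid mean lies on the segment between the parental means, positive
  when it leaves the parental axis;
* dominance % = (m − dDHy) · 100 / m with m = (dDHy + dHoHy)/2 — positive
  when hybrids are closer to donkeys, negative when closer to horses, ±100
  when the hybrid mean coincides with a parental mean.

These formulas are sometimes written with two different symbols for the
horse-hybrid distance (dHoHy in the transgression formula, dCHy — C for
*caballus* — in the dominance formula); they denote the same quantity and are
treated as such here.

Distances are computed in the full shape variables, not a PC subspace (a
`axes` argument allows subspace sensitivity analyses). Point estimates are
the plain plug-in distances; `hybrid_indices_boot()` adds nonparametric
bootstrap percentile intervals. The plug-in distance between two estimated
means is biased upward (E‖m̂₁−m̂₂‖² = ‖μ₁−μ₂‖² + tr Σ₁/n₁ + tr Σ₂/n₂), which
matters most when two group means nearly coincide — e.g. a hybrid placed at a
parent. `bias_correct = TRUE` subtracts the sampling terms from the squared
distances (truncated at zero) before the square root; the corrected estimator
converges to the same population value and is the one used when validating
parameter recovery against the generator's closed forms. The default stays
the plain estimator, the standard form of the method.

Sex-stratified index computation is supported (and automatic in the pipeline
for bones with a species-by-sex interaction), without significance tests —
the per-sex subsamples of a realistic study are too small for them.

## Morphological integration

Shape covariation between two bones is measured by two-block PLS on the
specimens common to both bones, each bone carrying its own GPA. The
cross-covariance matrix of the centered blocks is decomposed by SVD; rPLS is
the Pearson correlation of the first paired axis scores. Significance comes
from permuting the specimen rows of one block (999 permutations by default).

Raw rPLS values are not comparable across datasets: the null distribution of
the first singular-axis correlation shifts strongly with sample size and
variable count (small samples in high dimension give large rPLS under pure
independence). The standardized effect size z = (t(r_obs) − mean
t(r_perm)) / sd(t(r_perm)), with t Fisher's transformation (a switch gives
raw-r standardization), fixes the *null* location and scale: under no
integration z behaves like a standard normal deviate whatever n and the
variable counts, which is what makes two-sample comparisons of integration
strength between groups meaningful, via |z₁ − z₂|/√(se₁² + se₂²) referred to
the standard normal. The reported `z_se` is the spread of the standardized
permutation distribution. One caveat the test suite makes explicit: under a
*fixed alternative* any consistent test's effect size still grows with n —
the n-invariance holds for the null calibration, not for the expected value
of z under integration.

The covariation network evaluates three anatomically defined pair families
(serial homologs, within-limb adjacent bones, functionally equivalent
fore/hind bones; fully overridable). P-values are Bonferroni-corrected within
each family of tests sharing a bone, and an edge counts as significant only
if it survives in both of its bones' families — a deliberately conservative
reading of "each set of tests including a same bone". The talus and calcaneus
are linked to both the tibia and the metatarsal in the default hind-limb
chain, since their position in the adjacency chain is anatomically ambiguous;
the pair table is a plain data frame and can be replaced wholesale.

`pls_shape_changes()` deforms each block's consensus along the first-axis
loadings to chosen score quantiles and reports per-landmark displacement
magnitudes — the numerical content of the usual extreme-shape visualizations.
Surface warping/rendering is out of scope.

## The synthetic generator

`generator_spec()` + `generate_study()` produce studies with the statistical
structure the analyses assume, and `truth_report()` records every recoverable
generating value. Per bone, a deterministic non-degenerate base mean shape is
drawn; parent means are displaced ±divergence/2 along a fixed tangent-space
direction u; the hybrid mean sits at fraction `f` along the parental axis
plus an orthogonal offset `t`·divergence. Specimens add an allometric term
(slope x centered log10 size), latent integration factors shared between
coupled bones (correlation rho), an optional sex offset (optionally
restricted to one species, inducing an interaction), and isotropic tangent
noise projected off the similarity directions — so the closed-form index
expectations remain exact in expectation. Every configuration is then scaled
to its drawn centroid size, randomly rotated and translated: superimposition
always has real work to do, and a fixed seed makes the whole study
bit-reproducible.

Default conditions (chosen once, from the scale of published values for
equid limb bones, and documented rather than tuned):

* group sizes 38 donkeys / 42 horses / 21 hybrids (13 mules, 8 hinnies) —
  the sampling structure typical of museum osteological collections, where
  hybrids are the scarce group;
* 16 bones with k = 10 landmarks each;
* parental divergence 0.15 Procrustes units with per-coordinate tangent noise
  of SD 0.005, giving within-group Procrustes variances near 6e-4 — the scale
  of published disparity values for well-preserved equid long bones — and
  clear species separation (inter-parent distance ≈ 6-7 within-group SDs);
* hybrids at the parental midpoint with a mild transgressive offset
  (f = 0.5, t = 0.1);
* log10 centroid size means 2.0 / 2.2 / 2.17 (donkey / horse / hybrid), SD
  0.05 — donkeys distinctly smaller, hybrids near horses;
* weak allometry (slope 0.02 per log10 unit) and no planted integration or
  sex effect unless requested.

What the generator does *not* emulate: realistic bone geometry (base shapes
are random, non-degenerate configurations), measurement error structure of a
digitizer, missing landmarks, asymmetry, or quantitative-genetic structure
beyond a placed F1 mean. Passing tests therefore validate the statistical
machinery, not anatomical claims about real equids.

## Validation strategy and problem sizes

The test suite validates each estimator against an independent route:
ordinary Procrustes distance against a brute-force quaternion search, PLS
singular values against a dense eigendecomposition of the cross-covariance,
Procrustes variance and regression R^2 against direct summation, Wilks
against the classical F in one dimension, and the index formulas against
coordinate geometry. Property tests check invariances (rigid motions, common
rotations, input order, block order) and the (f, t) placement grid at
n = 200/group against the closed forms (2 percentage-point band, means over
20 seeds). Permutation tests are calibrated under the null with 500
simulations at n = 30/group and 199 permutations each; planted-network
recovery uses 100 replicate studies of six bones (k = 5) with coupling 0.8 on
the serial-homolog pairs. These sizes were chosen as the smallest at which an
a-priori power analysis puts the checks comfortably away from their
thresholds; they run in a few minutes on one CPU.

Numerical corner cases are explicit errors, not silent results: coincident
landmarks (zero centroid size), coincident parent means (transgression
undefined), a hybrid mean on both parents (dominance undefined), constant
size vectors, singleton groups, empty factor cells, and permutation spreads
of zero.

## Limitations

* The indices are distances between mean shapes; they say nothing about
  overlap of the group distributions. The bootstrap intervals are the honest
  companion to the point estimates.
* Bonferroni throughout is deliberate (it is what this analysis tradition
  uses) and conservative; with many bones a false-discovery-rate view would
  be less stringent.
* The two-way MANOVA requires every species-sex cell to be occupied; very
  small strata must be pooled or dropped by the user.
* Missing landmarks are handled by exclusion only (per-bone exclusion
  lists); there is no estimation of missing data, matching the original
  protocol for fragmentary material.
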