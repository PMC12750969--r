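---
title: "Vertebral ecomorphology: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral ecomorphology: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertecol)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical choices, what
the synthetic generator does and does not emulate, and the design decisions
taken where the analysis protocol was genuinely open.

## The problem

Isolated vertebrae are among the most common postcranial fossils, but
complete columns are rare. The pipeline asks how much locomotor ecology
(running speed: fast / intermediate / slow; hunting mode: pursuit / ambush /
pounce / occasional) a single vertebral position carries in a clade of
extant carnivorans, and uses the extant shape–ecology relationship to
predict the ecology of fossil vertebrae. Columns with varying vertebral
counts are made comparable by subsampling to ten homologous positions
(first/middle/last per region — for an even count the vertebra *after* the
midpoint — plus the diaphragmatic thoracic, which is anatomical metadata,
not computed) and by consolidating every regional landmarking scheme to the
same 30 landmarks (cervical 34 → 30 dropping 1-based landmarks 16, 17, 33,
34; thoracic 32 → 30 dropping 16, 17; lumbar 36 → 30 dropping 16, 17, 18,
19, 35, 36).

## Superimposition

`generalized_procrustes()` removes translation (centering), size (unit
centroid size) and orientation (iterative rotation to a working consensus,
re-estimated until its Frobenius change falls below `tol`). Parameters and
defaults:

* `tol = 1e-8` — consensus change at which iteration stops; dimensionless
  (shapes live on the unit-size sphere).
* `max_iter = 100` — non-convergence is flagged in the result
  (`converged = FALSE`), never silently ignored.
* `tangent = FALSE` — optional orthogonal projection onto the tangent plane
  at the consensus. Whether the original protocol projected to tangent
  space is unknowable from the outside; all component analyses here operate
  on aligned coordinates, and the switch exists to quantify the (tiny, at
  these Procrustes distances) difference.

Rotations come from the sign-corrected SVD, so reflections are impossible —
vertebrae are chirally consistent and an improper "alignment" would be an
artifact. The initial reference is the first configuration; invariance of
the result to that choice is covered by a test, not assumed. After
convergence every configuration is rotated onto the final consensus once
more and the stored consensus is the arithmetic mean of the aligned set, so
the documented invariants (centroid at origin and unit size to 1e-9,
consensus = mean to 1e-9) hold exactly on the output object.

Species means are computed **after** superimposition (`species_mean_shapes()`):
averaging unaligned configurations would conflate orientation with shape.
Because the protocol could also be read as averaging first, the pipeline
config exposes `species_mean = "before_gpa"`, implemented as per-species
GPA → mean → global GPA.

## Shape spaces

`fit_pca()` is covariance-matrix PCA (divisor *n* − 1) of the vectorized
aligned coordinates, retaining all `min(n − 1, 3p)` components, with a
deterministic sign convention (each eigenvector's largest-magnitude loading
is positive) so regression tests and reruns are stable.

`combine_blocks()` builds the multi-element consensus space: separate GPA
per element, vectorize, center, scale each block to unit total variance,
concatenate, one global PCA. The scaling prevents landmark-rich or
high-variance elements from dominating the combined space; because the
normalization conventions of multi-element analyses differ between
implementations, `scale_blocks` is a config switch and both settings are
exercised in tests. Combined variance fractions are sensitive to this
choice; any comparison against externally reported combined-space numbers
should sweep it.

## Group-separation tests

`permanova()` implements the distance-based pseudo-F
(`SS_total = (1/N) Σ_{i<j} d²`, within-group terms weighted `1/n_g`),
verified against a brute-force double-loop oracle and against
`vegan::adonis2`. Distances default to Euclidean on vectorized aligned
coordinates — the tangent-space approximation of Procrustes distance, which
at the small Procrustes radii of congeneric vertebrae is indistinguishable —
with exact Procrustes distance available (`distance = "procrustes"`).
Inputs are species means, one point per species. Permutations are uniform
relabelings; `p = (1 + #{F* ≥ F}) / (1 + n_perm)` with `n_perm = 999` by
default, so the smallest attainable p is 0.001. Pairwise tests run per
unordered level pair (lexicographic order) with per-pair seeds derived as
`seed + pair index`, making each pair's p independent of which other levels
exist. Raw p-values are primary; a Bonferroni column is appended because the
multiplicity convention of the source analyses is unstated. The reporting
threshold defaults to p ≤ 0.005.

## Phylogenetic regression

`pgls_fit()` regresses the multivariate shape matrix on one predictor under
Brownian motion: residual covariance proportional to `C`, the shared
root-to-ancestor branch-length matrix (`bm_covariance()`, via `ape`). The
fit transforms response and design by `C^{-1/2}` (eigendecomposition), and
reports `R² = SS_effect / SS_total` from the transformed sums of squares —
invariant to rotations of shape space, as a shape statistic must be.
Numerical choices: `C` is scaled to unit determinant before inversion
(stabilizes the decomposition; provably changes neither R², F nor p — there
is a test), and a ridge of `1e-8 × mean(diag(C))` is added only if `C` is
numerically singular. Categorical predictors use full-rank indicator
contrasts and one overall test, since one effect size per predictor is the
quantity of interest. Significance is by residual randomization (RRPP):
intercept-only residuals in the transformed space are re-assigned to fitted
values, 999 permutations by default, seeded. Centroid size enters as
`log(CS)` — the conventional scale for size covariates, since size varies
multiplicatively across a clade spanning mustelids to big cats. Whether the
original analysis combined size with ecology in one model is unstated;
separate fits are the default and a combined model is a one-line extension
the API permits.

## Classification and fossil prediction

`fit_cva()` solves the between/within generalized eigenproblem on the first
`k` PC scores, scaling canonical vectors so the pooled within-group
covariance of canonical scores is the identity. Euclidean distance in
canonical space therefore equals Mahalanobis distance in the retained-PC
space, restricted to the discriminant subspace (`r ≤ min(k, g − 1)` axes).

* **PC retention.** The protocol's `k` is unstated, and accuracies and
  posteriors depend on it. Default: smallest `k` reaching 95% cumulative
  variance, capped at `N − g − 1` to keep the within-group covariance
  well-conditioned; always configurable, and the published-value tests
  sweep `k` rather than trusting any single choice.
* **Membership probability.** Softmax posterior over groups with equal
  priors, `p_g = exp(−d²_g/2)/Σ_h exp(−d²_h/2)` — a *relative* measure that
  always sums to 1 and is invariant to adding a constant to all `d²`. The
  chi-square typicality `1 − F_{χ²(r)}(d²_g)` is reported alongside: it is
  an *absolute* measure that can be near zero for every group (a fossil far
  outside the extant cloud), which the posterior by construction cannot
  express. Reading both columns guards against overconfident posteriors.
* **Accuracy.** Headline accuracies are leave-one-out (the model is refit
  without the held-out species each time); resubstitution is available and
  is optimistically biased, which a test asserts on average.
* **Strong support** (posterior > 0.95) is a reporting flag, not a
  computation.
* Combined-element fossil prediction restricts the multi-block space to the
  positions actually preserved in the fossil, then follows the same CVA
  path.

## The synthetic generator

`simulation_truth()` / `simulate_dataset()` emulate the statistical
structure the analyses assume: a pure-birth phylogeny (depth normalized to
1), species shape deviations evolving by Brownian motion with rate
`sigma_bm²` per unit depth, i.i.d. across the 3p shape coordinates;
additive per-level effect vectors for speed and hunting, constructed
orthogonal to the translation and scale directions so they are pure shape
displacements; isotropic digitizing noise `sigma_noise` per specimen; and a
random rigid motion plus scanner scale (log-size itself Brownian around
scale 50) per specimen so superimposition is genuinely exercised.

Default conditions mirror the empirical study design: 43 species (52
specimens when two specimens are drawn for some species), 10 positions, 30
landmarks. The magnitudes — `sigma_bm = 0.03` Procrustes units over the
tree depth, `sigma_noise = 0.01` (digitizing error an order of magnitude
below evolutionary signal), a speed-effect displacement of `3 × sigma_bm`
and a hunting effect of `1.5 × sigma_bm` — encode a system where running
speed carries the stronger vertebral signal, at separations (≈3 within-group
SDs) where recovery should be reliable but not trivial. They were fixed
once, from those considerations, as the package's study conditions.

What the generator does **not** emulate: correlated evolution among
landmarks (real integration is strongly structured; deviates here are
i.i.d. per coordinate), covariation between vertebral positions along the
column, biomechanically realistic vertebra geometry (the template is a
deterministic helix), allometry (shape effects are size-independent), and
non-Brownian evolutionary models. Passing tests therefore demonstrate the
*statistical machinery* — superimposition, effect recovery, calibrated
type-I error, classifier geometry — not that real vertebrae behave this
way.

## Problem sizes used in the test suite

Simulation-based checks run at deliberately modest sizes chosen to make the
distributional claims sharp while keeping the suite quick: type-I
calibration uses 1000 null replicates at 24 observations (PERMANOVA) and 30
tips (PGLS) with 199 permutations each; end-to-end fossil recovery uses 100
seeds at the full 43-species condition; oracle equalities use N ≤ 12–20
where brute force is exact. The acceptance script runs the complete
pipeline at the 43-species / 52-specimen condition with 999 permutations.

## Known limitations

* PERMANOVA assumes exchangeability under the null; with strong phylogenetic
  structure its p-values conflate clade and ecology (that is exactly why
  the PGLS stage exists). No PERMDISP-style dispersion test is included.
* PGLS fixes the Brownian model; no Pagel's λ or OU estimation.
* CVA with many retained PCs and few species per group inflates Mahalanobis
  distances; the `N − g − 1` cap mitigates but does not remove this, and
  typicality values for external specimens are then conservative.
* Missing landmarks are not estimated; configurations must be complete.
* The Morphologika reader accepts the bracketed and bare-count dialects
  with `[names]`/`[labels]` metadata; exotic dialect extensions (pixel
  sizes, wireframes) are ignored territory.
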