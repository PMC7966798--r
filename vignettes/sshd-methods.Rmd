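---
title: "Measuring facial sexual shape dimorphism: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial sexual shape dimorphism: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dimorph)
```

This vignette is the package's account of its own methods: the shape
model, the estimators, the numerical decisions, and — just as important —
what the synthetic validation does and does not demonstrate about real
landmark data.

## The shape model

A specimen is an ordered set of k two-dimensional landmarks. Everything
downstream assumes that after generalized Procrustes analysis (GPA) the
data live in a space where Euclidean operations are meaningful:

1. **Translation** is removed by centering each configuration.
2. **Size** is removed by scaling to unit centroid size (the square root
   of summed squared distances to the centroid). Size itself is retained
   in a `centroid_size` column.
3. **Rotation** is removed by iteratively rotating every configuration to
   the running consensus until the consensus root-mean-square change
   drops below `tol = 1e-10` (at most `max_iter = 100` iterations; the
   2D optimal rotation has a closed form, so each pass is exact).
4. **Tangent projection.** Aligned shapes are projected orthogonally into
   the linear tangent space at the consensus (`project_tangent = TRUE`
   by default, toggleable). For the small shape variation typical of
   faces the projection is a tiny correction, but it guarantees that the
   means, regressions and projections used later are honest linear
   operations.

The assumptions, then: landmark correspondence across specimens, shape
variation small relative to the curvature of shape space, and errors
roughly isotropic at the landmark level. Gross violations (a mislabeled
landmark, a flipped photograph) are caught earlier: `read_tps()` has an
explicit `flip_y` switch because a silent y-axis flip reverses every
sex-difference vector, and `detect_outliers()` flags specimens beyond
Q3 + 1.5 IQR of the Procrustes distance to the consensus.

## Semilandmark sliding

Outline points carry information only perpendicular to their curve, so
semilandmarks are allowed to slide. Each semilandmark's direction is the
normalized chord between its two flanking points on that specimen; the
sliding amounts of all semilandmarks of a specimen are solved jointly by
minimizing the thin-plate-spline bending energy of the specimen relative
to the consensus — a small linear system per specimen, since the energy
is an explicit quadratic form (the upper-left block of the inverted TPS
system matrix, kernel U(r) = r² log r²). After each pass the dataset is
re-superimposed and the consensus updated.

Two design choices deserve a note:

* **Tangent-direction sliding, not full relaxation.** The criterion being
  minimized (bending energy) is standard; the algorithmic variant is not
  uniquely determined by it. Sliding along the local tangent with three
  outer passes is the dominant convention and keeps each step a convex
  quadratic problem.
* **Monotone acceptance.** Because re-superimposition moves the reference
  consensus, a later pass can otherwise start marginally above the
  previous minimum (relative changes around 1e-3 at convergence). A pass
  is therefore accepted only if its post-slide total energy improves on
  the previous pass minimum; otherwise the state is rolled back and the
  iteration reports convergence. This makes the energy trace
  non-increasing by construction, which is also the property the test
  suite asserts.
* **Grand consensus as the sliding target.** Sliding against
  per-population consensuses is conceivable; the package uses the grand
  consensus, which keeps all specimens in a single commensurable frame.

## Symmetrization

Faces are bilaterally structured, and digitization asymmetry is mostly
noise. The symmetrized shape is the average of the configuration and its
reflected, pair-relabeled, optimally rotated copy. The construction
exploits a small algebraic fact: reflection-plus-relabeling followed by a
*fixed* rotation is a linear involution, so the average of a shape and
its image is an exact fixed point. The output is mirror-symmetric to
machine precision and symmetrization is idempotent — both are asserted as
invariants rather than approximations. The reflection axis is x-negation
in the aligned frame; the relabel–align–average construction makes the
choice immaterial.

## The sexscore and its decomposition

With male and female mean shapes MM and FM (computed within a scope:
one population, or globally), the dimorphism axis is v1 = MM − FM and an
individual's score is the raw dot product A · v1. It is deliberately
**not** normalized by ‖v1‖: the score's units are squared Procrustes
units and scores are comparable only within a fixed axis. Female scores
are multiplied by −1 so that larger always means more sex-typical; the
inversion is flag-guarded against double application.

The allometric decomposition regresses each coordinate on body height
(centered within scope, so the intercept is the mean shape and fitted
values stay on shape scale), then

* projects the **fitted values** on v1 → allometric scores, with
  v2 = the vector of height-regression coefficients,
* projects the **residuals** on v3 = MM_res − FM_res → non-allometric
  scores,
* reports α = ∠(v1, v2) and ν = ∠(v1, v3) in degrees (cosines clipped to
  [−1, 1] before arccos).

Scope defaults to per-population: population-specific means, regressions
and angles, which is what the cross-population comparisons need. The
height regression pools the sexes within scope (a sex-specific option
exists but is off by default): pooling is what makes the decomposition
interesting, because stature itself is dimorphic. With a 13 cm stature
gap and within-sex SD 6.5 cm, the pooled regression coefficient vector is
not b (the per-cm allometric field) but approximately b + λd with
λ = cov(sex, height)/var(height) ≈ 0.04 per cm — the regression absorbs
the portion of the sex difference that height can predict. This is a
feature, not a bug: it is exactly what "allometric component of SShD"
means. The synthetic generator's truth record therefore stores the
model-implied expected vectors (v1 = d + gap·b, v2 = b + λd,
v3 ∝ d) rather than naive d and b.

Two estimator properties worth knowing:

* **Angle noise floors.** v2 and v3 are estimated vectors; their sampling
  noise inflates angle estimates away from 0° and 90°. With b = 0 but a
  13 cm stature gap, ν has a floor of roughly 6° at 200 individuals per
  sex; without the stature gap the floor is a fraction of a degree. The
  validation tests the ν → 0 limit in the no-gap configuration for this
  reason.
* **Scale invariance.** α and ν are invariant to positive rescaling of
  the height units (the coefficient vector rescales, its direction does
  not); the suite asserts this to 1e-9 degrees.

## Resampling inference

All permutation machinery uses the add-one convention
p = (#{null ≥ observed} + 1)/(n_perm + 1) and an explicit, logged seed.

* **Disparity.** Procrustes variance with denominator n (the dominant
  morphometrics convention; `denominator = "n-1"` is available), with a
  sex-partialled variant that measures deviations from sex-specific
  means within group. Pairwise contrasts permute group labels.
* **Trajectory analysis.** Per-population sex vectors compared in
  magnitude (absolute difference) and direction (angle), against a null
  that permutes population labels within sex, holding every
  population × sex cell size fixed.
* **Median-distance contrast.** Per population, the absolute distance
  between male and female medians of the pre-inversion overall scores;
  regions are compared as mean(other regions) − mean(focal region),
  tested one-sided with the same stratified randomization (a directional
  hypothesis about the focal region's deficit).
* **Split-sample test.** Each population is repeatedly halved within sex;
  a scalar statistic (pluggable: α, ν, magnitude) is computed per half,
  and p is the proportion of replicates in which the mean within-
  population difference is at least the mean between-population
  difference. The comparison rule between the two difference
  distributions is not uniquely fixed by the verbal description; the
  proportion-based rule is implemented and flagged here as the package's
  interpretation.

Calibration was verified by simulation: on exchangeable null data
(populations sharing the same sex effect) both the randomization and the
trajectory magnitude tests reject at 5.0% ± MC error at α = 0.05
(400 datasets in the acceptance suite; an independent 600-dataset check
gave 0.05).

## Preference models

Ratings are averaged per face upstream and standardized (mean 0, SD 1)
within population, using the sample SD (n − 1) convention. The mixed
model is `rating ~ score × sex + (1 + score | population)`, REML, with
females as the reference category, so the four fixed effects are the
women's intercept and slope and the men's changes in each. Satterthwaite
degrees of freedom come from lmerTest. When the random-effects
covariance is singular the model falls back to uncorrelated random
effects and says so; with fewer than two populations it degenerates to
OLS (flagged `"ols"`), which the tests pin to the closed-form fit.

A methodological caveat the synthetic experiments made quantitative:
regressing ratings on **re-estimated** scores (projections onto an axis
estimated from the same data) attenuates slopes — classical regression
dilution. In the generator, where within-sex score variation is pure
landmark noise projected on the axis, the attenuation reaches tens of
percent; in real data, where within-sex dimorphism variation is
biological and large relative to axis-estimation error, it is far
smaller. The module-level validation therefore feeds the model the
generator's own standardized scores, and the pipeline-level check uses
wider (3 SE) bands.

The population-level regressions (e.g. stature gap vs. sex-vector
magnitude) use a Bayesian quadratic approximation: MAP of intercept,
slope and log noise scale under Normal(0, 1) priors on standardized
variables, Gaussian posterior at the mode via the inverse Hessian, 89%
compatibility intervals (MAP ± qnorm(0.945) · SD ≈ 1.598 SD), and
corridor bands from 1000 seeded posterior draws. With no data the
posterior reproduces the prior exactly; with n = 10⁴ the MAP matches OLS
to 1e-3 — both are tested, along with a dense-grid posterior oracle at
small n.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defines an eight-population study: 100 individuals per
sex per population, a shared 20-landmark bilateral face template (8
bilateral pairs, 4 midline points, 6 semilandmarks on the two outline
curves), population mean offsets (isotropic, tangent-projected, SD 0.01),
a sex-difference field of magnitude 0.03 Procrustes units (lowered brows,
wider jaw and nose, longer chin, smaller eyes), an allometric field of
3e-4 per cm (facial elongation with a more robust lower face), stature
Normal(165, 6.5) for women and Normal(178, 6.5) for men, isotropic
landmark noise SD 0.005, and attractiveness built as sex-specific slopes
(0.2 women, 0.0 men) on the standardized within-population-and-sex true
sexscore plus unit noise. The sex effect is applied as ±d/2 about the
population mean so MM − FM = d in expectation; allometry is centered on
the pooled height mean; every written specimen receives an arbitrary
rotation, translation and scaling so superimposition has real work to do.
Magnitudes were chosen so the allometric sex displacement
(13 cm × 3e-4 ≈ 0.004) sits an order below the direct sex effect,
mirroring the empirical finding that allometry is the weaker component of
facial dimorphism. The attractiveness signal is standardized within
population × sex because population mean offsets have random components
along d; pooling the sexes would leave a sex-specific between-population
score structure that no sex-shared random effect absorbs.

The generator is a validation instrument, not a face model. It lacks:
biological within-sex variation in dimorphism (individual variation along
d beyond isotropic noise — hence the regression-dilution caveat above),
non-Gaussian and landmark-specific digitizing error, curved outlines
denser than three semilandmarks per side, population differences in
allometric direction unless explicitly specified, rater-level structure
in attractiveness, and any association between shape and skin texture or
color. Passing the synthetic suite therefore demonstrates that the
estimators recover what their formulas promise under the stated model —
it does not certify performance under correspondence errors or model
misspecification in real photographs.

## Numerical and edge-case decisions

* Landmark indices are 1-based everywhere, matching both R and the
  morphometrics file conventions.
* GPA rejects configurations with zero centroid size; degenerate
  (rank-0) rotation problems return the identity with a warning.
* The TPS system matrix is inverted once per consensus; duplicate
  landmarks raise an error naming the pair; the sliding system carries a
  1e-12 ridge.
* Unit-size scaling contracts a tangent offset d by exactly
  √(1 + ‖d/2‖²); the noise-free recovery test asserts this identity
  rather than pretending the contraction does not exist.
* Median of an even count is the midpoint; split halves of odd strata
  differ by one individual, assigned to a random half.
* Permutation p-values are never 0 (add-one convention); every
  stochastic function takes an explicit seed and restores the caller's
  RNG state.
* Problem sizes in the validation suite: alignment orbit n = 200;
  sliding/symmetrization n = 100; decomposition recovery 8 × 200/sex;
  permutation calibration 400 null datasets at n_perm = 499;
  split-sample 100 datasets × 200 splits (60/sex per population for the
  angle statistic, whose half-sample sampling error must sit well below
  the 60° contrast under test); LMM recovery 100 datasets of 8 × 75/sex;
  repeatability 200 × 2 replicates. These sizes were chosen so each
  experiment's Monte-Carlo error is small against the property it
  checks.

## Known limitations

* 2D landmarks only; no 3D superimposition.
* The sexscore's raw-dot-product scale means scores from different axes
  (different scopes, different datasets) are not directly comparable;
  comparisons should go through angles, magnitudes, or standardized
  scores.
* The allometric score inherits the mean-shape projection as a constant
  offset (the formula projects fitted values, intercept included); its
  between-sex mean difference is therefore not a pure allometry signal —
  within-cell spreads are.
* Exact degrees of freedom of the mixed model depend on the
  Satterthwaite approximation; estimates and standard errors, not df,
  are the stable contract.
* The split-sample p-value implements one defensible reading of the
  within-vs-between comparison; other readings (e.g. distribution
  overlap measures) would give different numbers.
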