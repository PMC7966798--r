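# dimorph

Geometric-morphometric analysis of sexual shape dimorphism (SShD) in 2D
landmark data, built for cross-population studies of facial shape.

Human faces differ between the sexes, and the size and direction of that
difference varies across populations. Quantifying it from landmark data
takes a chain of shape-statistical steps, each easy to get subtly wrong:
superimposing configurations, letting outline semilandmarks slide,
symmetrizing bilateral structure, projecting individuals onto the
male–female axis, separating the stature-driven (allometric) part of the
difference from the rest, and testing everything against permutation
nulls. `dimorph` implements that chain as composable, data-frame-first R
functions, together with a synthetic multi-population face generator that
provides known ground truth for every stage.

## The statistics at the core

* **Generalized Procrustes analysis (GPA).** Configurations are translated
  to a common centroid, scaled to unit centroid size, and iteratively
  rotated to the running consensus; aligned shapes are then projected
  orthogonally into the tangent space at the consensus.
* **Semilandmark sliding.** Semilandmarks move along their local curve
  tangent by the amount that minimizes the thin-plate-spline bending
  energy relative to the consensus (the quadratic form given by the
  upper-left block of the inverted TPS system matrix). Passes iterate with
  re-superimposition while the total energy keeps dropping.
* **Bilateral symmetrization.** Each configuration is averaged with its
  reflected, relabeled, optimally rotated copy; because reflect–relabel
  followed by a fixed rotation is a linear involution, the output is
  exactly mirror-symmetric and the operation is idempotent.
* **Sexscore.** With male mean `MM` and female mean `FM` in the aligned
  frame, an individual shape `A` scores
  `sexscore(A) = A · (MM − FM)` — the raw dot product, in squared
  Procrustes units. Female scores are inverted so that higher always means
  more sex-typical.
* **Allometric decomposition.** Shape is regressed coordinate-wise on body
  height; projecting the fitted values on `v1 = MM − FM` gives the
  allometric score, and projecting the residuals on the residual sex
  difference `v3` gives the non-allometric score. The angles
  `α = ∠(v1, v2)` (with `v2` the height-regression coefficient vector) and
  `ν = ∠(v1, v3)` summarize how much of the dimorphism rides on stature.
* **Disparity and permutation inference.** Morphological disparity is the
  Procrustes variance `PV_g = Σ‖s_i − mean_g‖² / n_g`; group contrasts,
  trajectory (magnitude/direction) differences, and the region-level
  median-distance contrast are tested by permuting labels within sex,
  with add-one p-values.
* **Preference models.** Attractiveness is regressed on SShD with
  `rating ~ score × sex` and fully specified random intercepts and slopes
  by population (REML via lmerTest); population-level regressions use a
  Bayesian quadratic approximation with Normal(0, 1) priors and 89%
  compatibility intervals.

## A worked example

Simulate a three-population study (60 faces per sex per population, known
sex-difference vectors of magnitude 0.03), run the full superimposition,
and decompose the dimorphism:

```r
library(dimorph)

faces <- simulate_faces(synthetic_spec(n_populations = 3, n_per_sex = 60,
                                       seed = 42))
aligned <- gpa(faces$data) |>
  slide_semilandmarks(faces$template) |>
  symmetrize(faces$template)

dec <- sshd_decompose(aligned)
tidy(dec)
#> # A tibble: 3 × 5
#>   population alpha_deg nu_deg magnitude     n
#>   <chr>          <dbl>  <dbl>     <dbl> <int>
#> 1 CMR             9.66   9.44    0.0286   120
#> 2 NAM             8.07  10.2     0.0268   120
#> 3 TR              9.44   9.45    0.0260   120
```

The recovered per-population magnitudes (0.026–0.029) track the generated
`‖d‖ = 0.03`, and the small α angles reflect a stature gap that couples
height to sex, pulling the allometric axis toward the sex axis. A
trajectory analysis tests whether populations differ in the size or
direction of their sex-difference vectors:

```r
traj <- trajectory_analysis(aligned, n_perm = 499, seed = 42)
tidy(traj)
#> # A tibble: 3 × 6
#>   population_1 population_2 magnitude_diff magnitude_p angle_deg angle_p
#>   <chr>        <chr>                 <dbl>       <dbl>     <dbl>   <dbl>
#> 1 CMR          NAM                0.00175        0.32       13.7   0.828
#> 2 CMR          TR                 0.00259        0.132      11.9   0.884
#> 3 NAM          TR                 0.000843       0.632      10.0   0.964
```

All three populations share the same generating vector, and none of the
magnitude or angle contrasts is significant — as it should be.
`autoplot(dec)` draws the violin plots of overall/allometric/
non-allometric scores by population and sex; `run_pipeline()` chains every
stage (including nuisance-covariate residualization, disparity,
median-distance randomization, and preference models) from a single YAML
config and writes CSV/JSON outputs.

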