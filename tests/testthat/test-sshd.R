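test_that("sexscore is the raw dot product with the sex axis", {
  a <- c(3, 1, 0, 0)
  v <- c(2, 0, 0, 0)
  expect_equal(sexscore(a, v), 6)
})

test_that("sexscore(MM) - sexscore(FM) equals the squared axis norm", {
  set.seed(51)
  m <- matrix(rnorm(40 * 12), 40, 12)
  sex <- rep(c("female", "male"), each = 20)
  d <- shape_tbl(m, id = as.character(1:40), sex = sex)
  v <- sex_difference_vector(d)
  expect_equal(v$v1, v$MM - v$FM)
  gap <- sexscore(v$MM, v) - sexscore(v$FM, v)
  expect_equal(gap, sum(v$v1^2), tolerance = 1e-12)
})

test_that("sexscore is linear and refuses a degenerate axis", {
  set.seed(52)
  v <- rnorm(10)
  a <- rnorm(10); b <- rnorm(10)
  for (w in list(c(2, 3), c(-1, 0.5), c(0, 0))) {
    expect_equal(sexscore(w[1] * a + w[2] * b, v),
                 w[1] * sexscore(a, v) + w[2] * sexscore(b, v),
                 tolerance = 1e-10)
  }
  ## affine in t along the axis with slope ||v1||^2
  fm <- rnorm(10)
  sc <- sapply(c(0, 1, 2.5), function(t) sexscore(fm + t * v, v))
  expect_equal(diff(sc) / diff(c(0, 1, 2.5)), rep(sum(v^2), 2),
               tolerance = 1e-10)
  expect_error(sexscore(a, rep(0, 10)), "degenerate")
})

test_that("female score inversion flips females only and guards reapplication", {
  scores <- c(-0.3, 0.5, 0.2)
  sex <- c("female", "male", "female")
  out <- invert_female_scores(scores, sex)
  expect_equal(as.numeric(out), c(0.3, 0.5, -0.2))
  expect_error(invert_female_scores(out, sex), "already")
  males <- invert_female_scores(c(1, 2), c("male", "male"))
  expect_equal(as.numeric(males), c(1, 2))
})

test_that("shape-on-covariate regression recovers exact structure", {
  set.seed(53)
  k2 <- 16
  n <- 25
  base <- rnorm(k2)
  b <- rnorm(k2, 0, 0.01)
  h <- rnorm(n, 170, 7)
  m <- outer(rep(1, n), base) + outer(h, b)   # noise-free
  reg <- regress_shape_on_covariate(m, h)
  expect_equal(reg$coefficients, b, tolerance = 1e-10)
  expect_equal(reg$fitted + reg$residuals, m, tolerance = 1e-12)

  ## closed-form per-column simple-regression oracle on noisy data
  m2 <- m + matrix(rnorm(n * k2, 0, 0.05), n, k2)
  reg2 <- regress_shape_on_covariate(m2, h)
  oracle <- apply(m2, 2, function(col) cov(col, h) / var(h))
  expect_equal(reg2$coefficients, unname(oracle), tolerance = 1e-10)

  ## orthogonalized covariate: zero slope, residuals are centered originals
  hc <- h - mean(h)
  m3 <- m2 - outer(hc, reg2$coefficients)
  reg3 <- regress_shape_on_covariate(m3, h)
  expect_lt(max(abs(reg3$coefficients)), 1e-10)
  expect_equal(reg3$residuals, sweep(m3, 2, colMeans(m3)), tolerance = 1e-8)

  expect_error(regress_shape_on_covariate(m, rep(1, n)), "constant")
})

test_that("angle_between matches hand-computed angles exactly", {
  expect_equal(angle_between(c(1, 0), c(0, 1)), 90, tolerance = 1e-10)
  expect_equal(angle_between(c(1, 0), c(1, 1)), 45, tolerance = 1e-10)
  expect_equal(angle_between(c(1, 0), c(2, 0)), 0, tolerance = 1e-10)
  v <- rnorm(6)
  expect_lt(angle_between(v, v), 1e-5)      # arccos near 1 loses precision
  expect_lt(angle_between(v, 2 * v), 1e-5)
  expect_error(angle_between(c(0, 0), c(1, 0)), "zero")
})

test_that("with no allometry and no stature gap, v2 and nu collapse", {
  spec <- synthetic_spec(
    n_populations = 2, n_per_sex = 150, b_scale = 0,
    height_mean_f = 170, height_mean_m = 170, seed = 54
  )
  f <- simulate_faces(spec)
  dec <- sshd_decompose(gpa(f$data))
  d_norm <- vec_norm(f$truth$d[[1]])
  for (g in names(dec$vectors)) {
    ## v2 is pure noise, far smaller than the sex effect
    expect_lt(vec_norm(dec$vectors[[g]]$v2), 0.1 * d_norm)
    ## v3 ~ v1: nu near zero
    expect_lt(dec$angles$nu_deg[dec$angles$population == g], 10)
  }
  ## allometric scores carry no individual signal: within every
  ## population x sex cell their spread is negligible next to the overall
  ## scores (the cell means reflect the mean-shape projection, which the
  ## raw dot-product formulation keeps)
  cells <- split(dec$scores,
                 interaction(dec$scores$population, dec$scores$sex))
  for (cell in cells) {
    ## under real allometry this ratio is well above 1
    expect_lt(sd(cell$score_allometric), 0.3 * sd(cell$score_overall))
  }
})

test_that("orthogonal sex and allometry vectors give alpha near 90 degrees", {
  tf <- template_face()
  d_unit <- masculinity_field(tf$base)
  b_perp <- field_at_angle(tf$base, d_unit, 90)
  expect_equal(angle_between(d_unit, b_perp), 90, tolerance = 1e-8)
  pops <- tibble::tibble(
    name = "A", n_per_sex = 1000,
    height_mean_f = 170, height_mean_m = 170, height_sd = 6.5,
    d = list(0.03 * d_unit),
    b = list(1.5e-3 * b_perp)
  )
  spec <- synthetic_spec(populations = pops, shape_noise_sd = 0.003, seed = 55)
  f <- simulate_faces(spec)
  dec <- sshd_decompose(gpa(f$data))
  expect_true(all(abs(dec$angles$alpha_deg - 90) < 10))
  ## non-allometric scores track overall scores within sex when the
  ## allometric direction is orthogonal to the sex axis
  cells <- split(dec$scores,
                 interaction(dec$scores$population, dec$scores$sex))
  for (cell in cells) {
    expect_gt(cor(cell$score_overall, cell$score_nonallometric), 0.9)
  }
})

test_that("angles are invariant to rescaling the height units", {
  set.seed(56)
  f <- simulate_faces(synthetic_spec(n_populations = 2, n_per_sex = 60,
                                     seed = 56))
  aligned <- gpa(f$data)
  dec_cm <- sshd_decompose(aligned)
  inches <- aligned
  inches$height <- inches$height / 2.54
  dec_in <- sshd_decompose(inches)
  expect_equal(dec_cm$angles$alpha_deg, dec_in$angles$alpha_deg,
               tolerance = 1e-9)
  expect_equal(dec_cm$angles$nu_deg, dec_in$angles$nu_deg, tolerance = 1e-9)
})

test_that("the alpha/nu ratio inversely tracks the component SD ratio", {
  ## populations trading direct sex effect for allometric effect: the
  ## ratio of the angles should be inversely (monotonically) related to
  ## the ratio of total score SDs in the two components
  tf <- template_face()
  d_unit <- masculinity_field(tf$base)
  b_unit <- allometry_field(tf$base)
  n_pop <- 6
  pops <- tibble::tibble(
    name = paste0("P", seq_len(n_pop)),
    n_per_sex = 200,
    height_mean_f = 165, height_mean_m = 178, height_sd = 6.5,
    d = lapply(seq(0.035, 0.01, length.out = n_pop), function(s) s * d_unit),
    b = lapply(seq(2e-4, 2e-3, length.out = n_pop), function(s) s * b_unit)
  )
  f <- simulate_faces(synthetic_spec(populations = pops,
                                     shape_noise_sd = 0.004, seed = 57))
  dec <- sshd_decompose(gpa(f$data))
  ratios <- dec$scores |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(sd_ratio = sd(.data$score_allometric) /
                       sd(.data$score_nonallometric), .groups = "drop")
  ang <- dec$angles
  angle_ratio <- ang$alpha_deg / ang$nu_deg
  sd_ratio <- ratios$sd_ratio[match(ang$population, ratios$population)]
  expect_lt(cor(angle_ratio, sd_ratio, method = "spearman"), -0.8)
})

test_that("sex_difference_vector validates scope", {
  set.seed(58)
  m <- matrix(rnorm(20 * 8), 20, 8)
  d <- shape_tbl(m, sex = rep("female", 20), population = "CZ")
  expect_error(sex_difference_vector(d), "both sexes")
})
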