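test_that("Procrustes variance matches hand values and homogeneity", {
  ## two shapes at squared distance 0.5 each from their mean -> PV = 0.5
  a <- c(1, 0, 0, 0, 0, 0)
  b <- a + c(sqrt(2), 0, 0, 0, 0, 0)   # |a-b|^2 = 2, each dev^2 = 0.5
  d <- shape_tbl(rbind(a, b, a, a), population = c("g1", "g1", "g2", "g2"))
  res <- morphological_disparity(d, n_perm = 0)
  expect_equal(res$disparity$procrustes_variance[
    res$disparity$group == "g1"], 0.5, tolerance = 1e-12)
  ## identical shapes -> zero disparity
  expect_equal(res$disparity$procrustes_variance[
    res$disparity$group == "g2"], 0, tolerance = 1e-15)

  ## scaling deviations by c multiplies PV by c^2
  set.seed(61)
  m <- matrix(rnorm(20 * 8), 20, 8)
  mc <- sweep(m, 2, colMeans(m))
  d1 <- shape_tbl(m, population = "g")
  d2 <- shape_tbl(sweep(3 * mc, 2, colMeans(m), "+"), population = "g")
  pv1 <- morphological_disparity(d1, n_perm = 0)$disparity$procrustes_variance
  pv2 <- morphological_disparity(d2, n_perm = 0)$disparity$procrustes_variance
  expect_equal(pv2, 9 * pv1, tolerance = 1e-10)
})

test_that("disparity equals a brute-force sum of squares on random shapes", {
  set.seed(62)
  m <- matrix(rnorm(50 * 12), 50, 12)
  g <- sample(c("u", "v"), 50, replace = TRUE)
  res <- morphological_disparity(shape_tbl(m, population = g), n_perm = 0)
  for (lev in c("u", "v")) {
    rows <- m[g == lev, , drop = FALSE]
    mu <- colMeans(rows)
    pv <- sum(apply(rows, 1, function(r) sum((r - mu)^2))) / nrow(rows)
    expect_equal(
      res$disparity$procrustes_variance[res$disparity$group == lev],
      pv, tolerance = 1e-12
    )
  }
})

test_that("disparity is invariant to relabeling and joint rotation", {
  set.seed(63)
  m <- matrix(rnorm(30 * 10, 0, 0.1), 30, 10)
  g <- rep(c("a", "b", "c"), each = 10)
  pv <- morphological_disparity(shape_tbl(m, population = g),
                                n_perm = 0)$disparity
  ## relabel: swap group names
  g2 <- c(a = "b", b = "a", c = "c")[g]
  pv2 <- morphological_disparity(shape_tbl(m, population = g2),
                                 n_perm = 0)$disparity
  expect_equal(sort(pv$procrustes_variance), sort(pv2$procrustes_variance),
               tolerance = 1e-12)
  ## rotate the whole aligned dataset rigidly
  r <- rot2(0.7)
  m_rot <- t(apply(m, 1, function(v) flat(unflat(v) %*% r)))
  pv3 <- morphological_disparity(shape_tbl(m_rot, population = g),
                                 n_perm = 0)$disparity
  expect_equal(pv$procrustes_variance, pv3$procrustes_variance,
               tolerance = 1e-10)
})

test_that("sex-partialled disparity removes the dimorphism contribution", {
  set.seed(64)
  f <- simulate_faces(synthetic_spec(n_populations = 2, n_per_sex = 80,
                                     seed = 64))
  aligned <- gpa(f$data)
  full <- morphological_disparity(aligned, n_perm = 0)
  nosex <- morphological_disparity(aligned, partial_out_sex = TRUE, n_perm = 0)
  expect_true(all(nosex$disparity$procrustes_variance <
                    full$disparity$procrustes_variance))
})

test_that("median distance statistic matches hand computation", {
  scores <- tibble::tibble(
    population = rep(c("P", "Q"), each = 6),
    sex = rep(rep(c("male", "female"), each = 3), 2),
    score = c(1, 2, 3, 0, 1, 2,   # P: |2 - 1| = 1
              5, 5, 5, 5, 5, 5)   # Q: identical -> 0
  )
  res <- median_distance_statistic(scores, c(P = "africa", Q = "europe"),
                                   focal_region = "africa")
  expect_equal(res$per_population$median_distance[
    res$per_population$population == "P"], 1)
  expect_equal(res$per_population$median_distance[
    res$per_population$population == "Q"], 0)
  expect_equal(res$contrast, 0 - 1)
  expect_error(
    median_distance_statistic(scores, c(P = "africa", Q = "europe"), "asia"),
    "asia"
  )
})

test_that("the region contrast recovers a generated dimorphism deficit", {
  ## region A populations carry half the sex effect of region B
  tf <- template_face()
  d_unit <- masculinity_field(tf$base)
  pops <- tibble::tibble(
    name = c("A1", "A2", "B1", "B2"), n_per_sex = 150,
    height_mean_f = 170, height_mean_m = 170, height_sd = 6.5,
    d = list(0.015 * d_unit, 0.015 * d_unit, 0.03 * d_unit, 0.03 * d_unit),
    b = list(0 * d_unit, 0 * d_unit, 0 * d_unit, 0 * d_unit)
  )
  f <- simulate_faces(synthetic_spec(populations = pops,
                                     shape_noise_sd = 0.004, seed = 65))
  aligned <- gpa(f$data)
  dec <- sshd_decompose(aligned)
  sc <- dec$scores
  sc$score <- ifelse(sc$sex == "female", -sc$score_overall, sc$score_overall)
  res <- median_distance_statistic(
    sc, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"), focal_region = "A"
  )
  ## expected contrast: median gap ~ ||d||^2, so ~ 0.03^2 - 0.015*0.03
  ## computed per-population against its own v1; both regions' gaps are
  ## ||v1_p||^2 with ||v1|| = 0.015 vs 0.03
  expected <- 0.03^2 - 0.015^2
  expect_equal(res$contrast, expected, tolerance = 0.35)
  expect_gt(res$contrast, 0)
})

test_that("randomization test is degenerate for a label-blind statistic", {
  set.seed(66)
  d <- tibble::tibble(
    population = rep(c("P", "Q"), each = 10),
    sex = rep(c("female", "male"), 10),
    y = rnorm(20)
  )
  res <- randomization_test(d, function(dd) 42, n_perm = 99, seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$null_sd, 0)
})

test_that("randomization preserves every population x sex cell count", {
  set.seed(67)
  d <- tibble::tibble(
    population = sample(rep(c("P", "Q", "R"), times = c(8, 12, 6))),
    sex = sample(rep(c("female", "male"), 13)),
    y = rnorm(26)
  )
  ref <- table(d$population, d$sex)
  seen <- list()
  stat <- function(dd) {
    seen[[length(seen) + 1]] <<- table(dd$population, dd$sex)
    mean(dd$y[dd$population == "P"])
  }
  invisible(randomization_test(d, stat, n_perm = 20, seed = 2))
  for (tab in seen[-1]) expect_equal(tab, ref)
})

test_that("randomization detects a true population difference in magnitude", {
  tf <- template_face()
  d_unit <- masculinity_field(tf$base)
  pops <- tibble::tibble(
    name = c("P", "Q"), n_per_sex = 150,
    height_mean_f = 170, height_mean_m = 170, height_sd = 6.5,
    d = list(0.02 * d_unit, 0.04 * d_unit),
    b = list(0 * d_unit, 0 * d_unit)
  )
  f <- simulate_faces(synthetic_spec(populations = pops,
                                     shape_noise_sd = 0.003, seed = 68))
  aligned <- gpa(f$data)
  stat <- function(dd) {
    vs <- sapply(c("P", "Q"), function(p) {
      stat_sshd_magnitude(dd[dd$population == p, ])
    })
    unname(abs(vs[1] - vs[2]))
  }
  res <- randomization_test(aligned, stat, n_perm = 199, seed = 3)
  expect_lt(res$p, 0.05)
  expect_equal(res$observed, 0.02, tolerance = 0.25)
})

test_that("split-sample halves differ by at most one individual per stratum", {
  set.seed(69)
  d <- tibble::tibble(
    population = rep(c("P", "Q"), times = c(11, 9)),
    sex = c(rep(c("female", "male"), c(5, 6)), rep(c("female", "male"), c(5, 4))),
    y = rnorm(20)
  )
  sizes <- list()
  stat <- function(dd) {
    sizes[[length(sizes) + 1]] <<- nrow(dd)
    mean(dd$y)
  }
  invisible(split_sample_test(d, stat, n_perm = 10, seed = 4))
  sz <- matrix(unlist(sizes), ncol = 4, byrow = TRUE)  # P1 P2 Q1 Q2
  expect_true(all(abs(sz[, 1] - sz[, 2]) <= 2))  # one odd sex stratum each
  expect_true(all(sz[, 1] + sz[, 2] == 11))
  expect_true(all(sz[, 3] + sz[, 4] == 9))
})

test_that("pearson_cor matches the textbook formula and edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_cor(x, -x)$estimate, -1)
  set.seed(70)
  a <- rnorm(50); b <- rnorm(50)
  two_pass <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_cor(a, b)$estimate, two_pass, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 4)), "variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})
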