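test_that("centroid size: unit square, single point, homogeneity", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(matrix(c(3, 7), 1, 2)), 0)
  set.seed(1)
  cfg <- random_config(7)
  expect_equal(centroid_size(3.7 * cfg), 3.7 * centroid_size(cfg),
               tolerance = 1e-12)
})

test_that("optimal rotation recovers a known rotation and the identity", {
  set.seed(2)
  a <- random_config(6)
  r30 <- rot2(30 * pi / 180)
  r <- optimal_rotation(a, a %*% r30)
  expect_lt(sum((a %*% r - a %*% r30)^2), 1e-20)
  expect_equal(det(r), 1, tolerance = 1e-12)
  expect_equal(optimal_rotation(a, a), diag(2), tolerance = 1e-12)
})

test_that("optimal rotation matches a fine grid search", {
  set.seed(3)
  for (rep in 1:5) {
    a <- random_config(5)
    b <- random_config(5)
    r <- optimal_rotation(a, b)
    theta_hat <- atan2(r[2, 1], r[1, 1])
    obj <- function(th) sum((a %*% rot2(th) - b)^2)
    coarse <- seq(-pi, pi, by = 0.1 * pi / 180)
    vals <- vapply(coarse, obj, numeric(1))
    t0 <- coarse[which.min(vals)]
    fine <- seq(t0 - 0.2 * pi / 180, t0 + 0.2 * pi / 180,
                by = 0.001 * pi / 180)
    t_star <- fine[which.min(vapply(fine, obj, numeric(1)))]
    delta <- abs(theta_hat - t_star) %% (2 * pi)
    delta <- min(delta, 2 * pi - delta)
    expect_lt(delta * 180 / pi, 0.01)
  }
})

test_that("GPA aligns the rigid-motion orbit of one shape to a point", {
  set.seed(4)
  cfg <- random_config(8)
  n <- 50
  m <- do.call(rbind, lapply(seq_len(n), function(i) flat(random_similarity(cfg))))
  aligned <- gpa(shape_tbl(m, id = sprintf("s%02d", 1:n)))
  s <- shape_matrix(aligned)
  d <- as.matrix(dist(s))
  expect_lt(max(d), 1e-8)
})

test_that("GPA with n = 2 agrees with a direct pairwise alignment", {
  set.seed(5)
  a <- random_config(9)
  b <- random_config(9)
  norm_cfg <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  an <- norm_cfg(a)
  bn <- norm_cfg(b)
  bn_al <- bn %*% optimal_rotation(bn, an)
  d_direct <- sqrt(sum((an - bn_al)^2))
  aligned <- gpa(shape_tbl(rbind(flat(a), flat(b)), id = c("a", "b")),
                 project_tangent = FALSE)
  s <- shape_matrix(aligned)
  d_gpa <- sqrt(sum((s[1, ] - s[2, ])^2))
  expect_equal(d_gpa, d_direct, tolerance = 1e-8)
})

test_that("GPA sum of squares to consensus is non-increasing", {
  set.seed(6)
  cfg <- random_config(10)
  m <- do.call(rbind, lapply(1:30, function(i) {
    flat(random_similarity(cfg + matrix(rnorm(20, 0, 0.1), 10, 2)))
  }))
  aligned <- gpa(shape_tbl(m))
  tr <- attr(aligned, "ss_trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("GPA output is invariant to similarity transforms of the input", {
  set.seed(7)
  cfg <- random_config(10)
  m <- do.call(rbind, lapply(1:20, function(i) {
    flat(cfg + matrix(rnorm(20, 0, 0.05), 10, 2))
  }))
  m_t <- do.call(rbind, lapply(1:20, function(i) {
    flat(random_similarity(unflat(m[i, ])))
  }))
  a1 <- gpa(shape_tbl(m))
  a2 <- gpa(shape_tbl(m_t))
  s1 <- shape_matrix(a1)
  s2 <- shape_matrix(a2)
  ## frames agree up to one joint rotation
  c1 <- unflat(consensus_shape(a1))
  c2 <- unflat(consensus_shape(a2))
  r <- optimal_rotation(c2, c1)
  s2r <- t(apply(s2, 1, function(v) flat(unflat(v) %*% r)))
  expect_lt(max(abs(s1 - s2r)), 1e-8)
})

test_that("every row has unit centroid size after the scaling step", {
  set.seed(8)
  cfg <- random_config(6)
  m <- do.call(rbind, lapply(1:15, function(i) {
    flat(random_similarity(cfg + matrix(rnorm(12, 0, 0.05), 6, 2)))
  }))
  aligned <- gpa(shape_tbl(m), project_tangent = FALSE)
  cs <- apply(shape_matrix(aligned), 1, function(v) centroid_size(unflat(v)))
  expect_true(all(abs(cs - 1) < 1e-10))
})

test_that("procrustes distance is a metric on random triples", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12); c <- rnorm(12)
    expect_equal(procrustes_distance(a, a), 0)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
    expect_lte(procrustes_distance(a, c),
               procrustes_distance(a, b) + procrustes_distance(b, c) + 1e-12)
  }
  expect_error(procrustes_distance(1:4, 1:6), "length")
})

test_that("outlier detection flags a displaced specimen and matches the rule", {
  set.seed(10)
  cfg <- random_config(8)
  cfg <- cfg / centroid_size(cfg)
  m <- do.call(rbind, lapply(1:30, function(i) {
    flat(cfg + matrix(rnorm(16, 0, 0.002), 8, 2))
  }))
  bad <- cfg
  bad[1, ] <- bad[1, ] + c(0.5, 0.5)
  m <- rbind(m, flat(bad))
  ids <- c(sprintf("ok%02d", 1:30), "weird")
  aligned <- gpa(shape_tbl(m, id = ids))
  out <- detect_outliers(aligned)
  expect_equal(out$id, "weird")

  ## huge multiplier: nothing flagged in a homogeneous cloud
  aligned2 <- gpa(shape_tbl(m[1:30, ], id = ids[1:30]))
  expect_equal(nrow(detect_outliers(aligned2, multiplier = 10)), 0)

  ## brute-force recomputation of the quartile rule
  s <- shape_matrix(aligned)
  d <- sqrt(rowSums(sweep(s, 2, consensus_shape(aligned))^2))
  thr <- quantile(d, 0.75) + 1.5 * (quantile(d, 0.75) - quantile(d, 0.25))
  expect_setequal(out$id, ids[d > unname(thr)])
})

test_that("aligned datasets persist to CSV + JSON sidecar and back", {
  set.seed(11)
  cfg <- random_config(5)
  m <- do.call(rbind, lapply(1:6, function(i) {
    flat(random_similarity(cfg + matrix(rnorm(10, 0, 0.03), 5, 2)))
  }))
  aligned <- gpa(shape_tbl(m, id = letters[1:6]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_aligned(aligned, path)
  back <- read_aligned(path)
  expect_equal(shape_matrix(back), shape_matrix(aligned), tolerance = 1e-12)
  expect_equal(consensus_shape(back), as.numeric(consensus_shape(aligned)),
               tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
})
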