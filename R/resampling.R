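#' Morphological disparity as Procrustes variance
#'
#' For each group g, the Procrustes variance
#' \deqn{PV_g = \sum_i \| s_i - \bar{s}_g \|^2 / n_g,}
#' the mean squared Procrustes distance of group members to their group
#' mean (denominator n by morphometrics convention; switchable). With
#' `partial_out_sex = TRUE`, deviations are taken from sex-specific means
#' within each group, i.e. disparity with sex variation removed. Pairwise
#' group differences are tested by permuting group labels.
#'
#' @param aligned An `aligned_faces` tibble.
#' @param group Column name holding group labels (default "population").
#' @param partial_out_sex Remove sex variation before measuring dispersion
#'   (requires a `sex` column).
#' @param n_perm Number of label permutations for the pairwise tests
#'   (default 999; set 0 to skip).
#' @param seed RNG seed.
#' @param denominator "n" (convention, default) or "n-1".
#' @return An object of class `disparity_result`: `disparity` (tibble:
#'   group, n, procrustes_variance), `pairwise` (tibble: group_1, group_2,
#'   abs_diff, p), `n_perm`, `seed`.
#' @export
morphological_disparity <- function(aligned, group = "population",
                                    partial_out_sex = FALSE,
                                    n_perm = 999, seed = NULL,
                                    denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  s <- shape_matrix(aligned)
  g <- factor(aligned[[group]])
  counts <- table(g)
  if (any(counts < 2)) {
    abort(paste0("group(s) of size < 2: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  sex <- if (partial_out_sex) check_sex(aligned$sex) else NULL

  pv_all <- function(labels) {
    labels <- factor(labels, levels = levels(g))
    cell <- if (partial_out_sex) {
      interaction(labels, sex, drop = TRUE)
    } else {
      labels
    }
    means <- group_row_means(s, cell)
    dev2 <- rowSums((s - means[as.integer(factor(cell)), , drop = FALSE])^2)
    ss <- rowsum(dev2, labels)
    n_g <- as.vector(table(labels))
    den <- if (denominator == "n") n_g else n_g - 1
    as.vector(ss) / den
  }

  pv <- pv_all(g)
  lev <- levels(g)
  np <- length(lev)
  pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  obs_diff <- abs(pv[pairs[, 1]] - pv[pairs[, 2]])

  pairwise <- NULL
  if (n_perm > 0 && np > 1) {
    ge <- rep(0L, nrow(pairs))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        nul_pv <- pv_all(g[sample.int(length(g))])
        nul_diff <- abs(nul_pv[pairs[, 1]] - nul_pv[pairs[, 2]])
        ge <- ge + (nul_diff >= obs_diff)
      }
    })
    pairwise <- tibble::tibble(
      group_1 = lev[pairs[, 1]],
      group_2 = lev[pairs[, 2]],
      abs_diff = obs_diff,
      p = (ge + 1) / (n_perm + 1)
    )
  }

  structure(
    list(
      disparity = tibble::tibble(
        group = lev,
        n = as.vector(counts),
        procrustes_variance = pv
      ),
      pairwise = pairwise,
      partial_out_sex = partial_out_sex,
      n_perm = n_perm,
      seed = seed
    ),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Morphological disparity (Procrustes variance",
      if (x$partial_out_sex) ", sex variation removed", ")\n", sep = "")
  print(x$disparity)
  invisible(x)
}

#' Median-distance contrast of sexual dimorphism between regions
#'
#' For every population, the absolute distance between the male and female
#' medians of the (pre-inversion) overall sexscore distribution; per region,
#' the mean of its populations' distances; and the contrast
#' mean(other regions) - mean(focal region). Used as the statistic of the
#' population-label randomization test.
#'
#' @param scores Tibble with columns `population`, `sex` and `score`
#'   (pre-inversion overall sexscores).
#' @param region_map Named character vector mapping population -> region.
#' @param focal_region Region whose deficit/excess is contrasted against
#'   the rest.
#' @return A list: `per_population` (tibble: population, region,
#'   median_distance), `region_means` (tibble), `contrast`, `focal_region`.
#' @export
median_distance_statistic <- function(scores, region_map, focal_region) {
  if (!all(c("population", "sex", "score") %in% names(scores))) {
    abort("scores must have population, sex, score columns")
  }
  sex <- check_sex(scores$sex)
  per_pop <- scores |>
    dplyr::mutate(sex = sex) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      median_distance = abs(
        median(.data$score[.data$sex == "male"]) -
          median(.data$score[.data$sex == "female"])
      ),
      .groups = "drop"
    )
  regions <- region_map[per_pop$population]
  if (any(is.na(regions))) {
    abort(paste0("population(s) missing from region_map: ",
                 paste(per_pop$population[is.na(regions)], collapse = ", ")))
  }
  per_pop$region <- unname(regions)
  if (!focal_region %in% per_pop$region) {
    abort(paste0("no populations in focal region ", focal_region))
  }
  region_means <- per_pop |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_median_distance = mean(.data$median_distance),
                     .groups = "drop")
  contrast <- mean(per_pop$median_distance[per_pop$region != focal_region]) -
    mean(per_pop$median_distance[per_pop$region == focal_region])
  list(
    per_population = per_pop,
    region_means = region_means,
    contrast = contrast,
    focal_region = focal_region
  )
}

#' Randomization test with population labels shuffled within sex
#'
#' Populations are reassigned at random to individuals while each
#' individual's sex and every population x sex sample size remain fixed;
#' the statistic is recomputed on each relabeled dataset. One-sided
#' add-one p: p = (#\{null >= observed\} + 1)/(n_perm + 1).
#'
#' @param data A data frame with `population` and `sex` columns (rows are
#'   individuals; any other columns the statistic needs are carried along).
#' @param statistic Function of the (relabeled) data frame returning one
#'   number.
#' @param n_perm Number of randomized samples (default 10000).
#' @param seed RNG seed.
#' @param label Statistic label stored in the result.
#' @return An object of class `permutation_result`: `observed`,
#'   `null_mean`, `null_sd`, `p`, `n_perm`, `seed`, `label`, `null` (the
#'   null draws).
#' @export
randomization_test <- function(data, statistic, n_perm = 10000, seed = NULL,
                               label = "statistic") {
  sex <- check_sex(data$sex)
  observed <- statistic(data)
  if (!is.finite(observed)) abort("statistic is not finite on the observed data")
  null <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- data
      for (lv in levels(sex)) {
        i <- which(sex == lv)
        perm$population[i] <- data$population[i][sample.int(length(i))]
      }
      val <- tryCatch(statistic(perm), error = function(e) {
        abort(paste0("statistic failed on permutation ", b, ": ",
                     conditionMessage(e)))
      })
      null[b] <- val
    }
  })
  structure(
    list(
      observed = observed,
      null_mean = mean(null),
      null_sd = sd(null),
      p = (sum(null >= observed) + 1) / (n_perm + 1),
      n_perm = n_perm,
      seed = seed,
      label = label,
      null = null
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test: ", x$label, "\n", sep = "")
  cat("  observed:", format(x$observed, digits = 4),
      " null mean:", format(x$null_mean, digits = 4),
      " (sd ", format(x$null_sd, digits = 4), ")\n", sep = "")
  cat("  p =", format(x$p, digits = 4), "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Random split-sample test
#'
#' Each population is repeatedly divided into two random half-samples
#' (split within sex, so both halves keep both sexes; halves of odd strata
#' differ by one individual). A scalar statistic is computed on every
#' half-sample; each replicate records the mean absolute difference between
#' the two halves of the same population ("within") and the mean absolute
#' difference between halves of different populations ("between"). The
#' p-value is the proportion of replicates in which the within-population
#' difference is at least the between-population difference,
#' p = (#\{within >= between\} + 1)/(n_perm + 1): small p means population
#' identity carries real signal for the statistic.
#'
#' @param data A data frame with `population` and `sex` columns.
#' @param statistic Function of a data-frame subsample returning a scalar
#'   (e.g. [stat_alpha()]).
#' @param n_perm Number of random splits (default 10000).
#' @param seed RNG seed.
#' @param retry_cap Maximum resplits per replicate when a half lacks a sex
#'   or the statistic fails.
#' @param label Statistic label.
#' @return An object of class `split_sample_result`: `within_mean`,
#'   `within_sd`, `between_mean`, `between_sd`, `p`, `n_perm`, `seed`,
#'   `replicates` (tibble of per-replicate within/between means).
#' @export
split_sample_test <- function(data, statistic, n_perm = 10000, seed = NULL,
                              retry_cap = 100, label = "statistic") {
  sex <- check_sex(data$sex)
  pops <- unique(as.character(data$population))
  if (length(pops) < 2) abort("need >= 2 populations")
  cnt <- table(data$population, sex)
  if (any(cnt < 2)) {
    abort("each population needs >= 2 individuals of each sex to split")
  }
  idx_by <- split(seq_len(nrow(data)), list(data$population, sex), drop = TRUE)

  one_split <- function() {
    halves <- lapply(pops, function(p) list(integer(), integer()))
    names(halves) <- pops
    for (nm in names(idx_by)) {
      i <- idx_by[[nm]]
      p <- sub("\\.(female|male)$", "", nm)
      i <- i[sample.int(length(i))]
      h <- length(i) %/% 2
      extra <- length(i) %% 2
      ## the odd individual goes to a random half
      cut <- h + (extra && runif(1) < 0.5)
      halves[[p]][[1]] <- c(halves[[p]][[1]], i[seq_len(cut)])
      halves[[p]][[2]] <- c(halves[[p]][[2]], i[-seq_len(cut)])
    }
    halves
  }

  np <- length(pops)
  within <- between <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ok <- FALSE
      for (try in seq_len(retry_cap)) {
        halves <- one_split()
        vals <- matrix(NA_real_, np, 2)
        good <- TRUE
        for (pi in seq_len(np)) {
          for (hi in 1:2) {
            sub <- data[halves[[pops[pi]]][[hi]], , drop = FALSE]
            v <- tryCatch(statistic(sub), error = function(e) NA_real_)
            if (!is.finite(v)) {
              good <- FALSE
              break
            }
            vals[pi, hi] <- v
          }
          if (!good) break
        }
        if (good) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("retry cap exceeded while splitting (samples too small for the statistic?)")
      }
      within[b] <- mean(abs(vals[, 1] - vals[, 2]))
      cross <- c()
      for (pi in seq_len(np - 1)) {
        for (qi in (pi + 1):np) {
          cross <- c(cross, abs(vals[pi, ] - rep(vals[qi, ], each = 2)))
        }
      }
      between[b] <- mean(cross)
    }
  })
  structure(
    list(
      within_mean = mean(within), within_sd = sd(within),
      between_mean = mean(between), between_sd = sd(between),
      p = (sum(within >= between) + 1) / (n_perm + 1),
      n_perm = n_perm, seed = seed, label = label,
      replicates = tibble::tibble(within = within, between = between)
    ),
    class = "split_sample_result"
  )
}

#' @export
print.split_sample_result <- function(x, ...) {
  cat("Split-sample test: ", x$label, "\n", sep = "")
  cat("  within-population mean diff: ", format(x$within_mean, digits = 4),
      " (sd ", format(x$within_sd, digits = 4), ")\n", sep = "")
  cat("  between-population mean diff:", format(x$between_mean, digits = 4),
      " (sd ", format(x$between_sd, digits = 4), ")\n", sep = "")
  cat("  p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Subsample statistics for the split-sample test
#'
#' Scalar summaries of a landmark data subsample, suitable as `statistic`
#' arguments: the allometric angle alpha, the non-allometric angle nu, and
#' the magnitude of the sex-difference vector.
#'
#' @param data A data frame with coordinate columns plus `sex` (and
#'   `height` for the angle statistics).
#' @return A single number.
#' @export
stat_alpha <- function(data) {
  s <- shape_matrix(data)
  sex <- check_sex(data$sex)
  v1 <- colMeans(s[sex == "male", , drop = FALSE]) -
    colMeans(s[sex == "female", , drop = FALSE])
  reg <- regress_shape_on_covariate(s, data$height)
  angle_between(v1, reg$coefficients)
}

#' @rdname stat_alpha
#' @export
stat_nu <- function(data) {
  s <- shape_matrix(data)
  sex <- check_sex(data$sex)
  v1 <- colMeans(s[sex == "male", , drop = FALSE]) -
    colMeans(s[sex == "female", , drop = FALSE])
  reg <- regress_shape_on_covariate(s, data$height)
  res <- reg$residuals
  v3 <- colMeans(res[sex == "male", , drop = FALSE]) -
    colMeans(res[sex == "female", , drop = FALSE])
  angle_between(v1, v3)
}

#' @rdname stat_alpha
#' @export
stat_sshd_magnitude <- function(data) {
  s <- shape_matrix(data)
  sex <- check_sex(data$sex)
  vec_norm(
    colMeans(s[sex == "male", , drop = FALSE]) -
      colMeans(s[sex == "female", , drop = FALSE])
  )
}

#' Pearson product-moment correlation with validation
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy one-row tibble.
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return Tibble with `estimate`, `statistic`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y differ in length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    n = length(x)
  )
}
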