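#' Trajectory analysis of sex-difference vectors across populations
#'
#' Compares the per-population sexual dimorphism vectors v1_p = MM_p - FM_p
#' in magnitude and direction: for every population pair the absolute
#' difference of magnitudes and the angle between the vectors, each tested
#' against a permutation null built by shuffling population labels across
#' individuals within sex (holding every population x sex cell size fixed).
#' P-values use the add-one convention
#' p = (#\{null >= observed\} + 1) / (n_perm + 1).
#'
#' @param aligned An `aligned_faces` tibble with `sex` and `population`
#'   columns. Populations lacking a sex are excluded with a warning.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed (required for reproducibility).
#' @return An object of class `trajectory_result`: `magnitudes` (tibble:
#'   population, magnitude, n_female, n_male), `pairwise` (tibble:
#'   population_1, population_2, magnitude_diff, magnitude_p, angle_deg,
#'   angle_p), `n_perm`, `seed`.
#' @export
trajectory_analysis <- function(aligned, n_perm = 999, seed = NULL) {
  sex <- check_sex(aligned$sex)
  pop <- as.character(aligned$population)
  tab <- table(pop, sex)
  ok_pops <- rownames(tab)[tab[, "female"] > 0 & tab[, "male"] > 0]
  dropped <- setdiff(rownames(tab), ok_pops)
  if (length(dropped)) {
    warn(paste0("population(s) lacking a sex excluded: ",
                paste(dropped, collapse = ", ")))
  }
  if (length(ok_pops) < 2) abort("need >= 2 populations with both sexes")
  keep <- pop %in% ok_pops
  s <- shape_matrix(aligned)[keep, , drop = FALSE]
  sex <- droplevels(sex[keep])
  pop <- factor(pop[keep], levels = ok_pops)

  sex_vectors <- function(pop_labels) {
    g <- interaction(pop_labels, sex, drop = FALSE, lex.order = TRUE)
    means <- group_row_means(s, g)
    np <- length(ok_pops)
    ## lex.order=TRUE: rows ordered pop1.female, pop1.male, pop2.female, ...
    males <- means[seq(2, 2 * np, by = 2), , drop = FALSE]
    females <- means[seq(1, 2 * np, by = 2), , drop = FALSE]
    males - females
  }
  pair_stats <- function(v) {
    mags <- unname(sqrt(rowSums(v^2)))
    np <- nrow(v)
    pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    md <- abs(mags[pairs[, 1]] - mags[pairs[, 2]])
    ang <- vapply(seq_len(nrow(pairs)), function(i) {
      angle_between(v[pairs[i, 1], ], v[pairs[i, 2], ])
    }, numeric(1))
    list(mags = mags, pairs = pairs, mag_diff = md, angle = ang)
  }

  obs_v <- sex_vectors(pop)
  obs <- pair_stats(obs_v)

  ge_mag <- rep(0L, length(obs$mag_diff))
  ge_ang <- rep(0L, length(obs$angle))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_pop <- pop
      for (lv in levels(sex)) {
        i <- which(sex == lv)
        perm_pop[i] <- pop[i][sample.int(length(i))]
      }
      nul <- pair_stats(sex_vectors(perm_pop))
      ge_mag <- ge_mag + (nul$mag_diff >= obs$mag_diff)
      ge_ang <- ge_ang + (nul$angle >= obs$angle)
    }
  })

  tibble::tibble(
    population_1 = ok_pops[obs$pairs[, 1]],
    population_2 = ok_pops[obs$pairs[, 2]],
    magnitude_diff = obs$mag_diff,
    magnitude_p = (ge_mag + 1) / (n_perm + 1),
    angle_deg = obs$angle,
    angle_p = (ge_ang + 1) / (n_perm + 1)
  ) -> pairwise

  structure(
    list(
      magnitudes = tibble::tibble(
        population = ok_pops,
        magnitude = obs$mags,
        n_female = as.vector(tab[ok_pops, "female"]),
        n_male = as.vector(tab[ok_pops, "male"])
      ),
      pairwise = pairwise,
      n_perm = n_perm,
      seed = seed
    ),
    class = "trajectory_result"
  )
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("Trajectory analysis of sex-difference vectors (",
      x$n_perm, " permutations)\n", sep = "")
  print(x$magnitudes)
  print(x$pairwise)
  invisible(x)
}
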