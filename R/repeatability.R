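#' Digitization repeatability from replicate landmarkings
#'
#' Procrustes ANOVA with individual as the grouping factor: the total
#' Procrustes sum of squares of a jointly superimposed replicate dataset is
#' partitioned into between-individual and within-individual (replicate)
#' components, and the intraclass correlation
#' \deqn{R = \sigma^2_{between} / (\sigma^2_{between} + \sigma^2_{within})}
#' is computed from the mean squares, with
#' \eqn{\sigma^2_{between} = (MS_b - MS_w)/r} (clipped at 0) and r the
#' (effective) number of replicates per individual.
#'
#' @param aligned An `aligned_faces` tibble in which each individual appears
#'   two or more times (replicate digitizations superimposed together).
#' @param individual Column name identifying the individual (default "id").
#' @return A list of class `repeatability_result`: `repeatability`,
#'   `measurement_error` (= 1 - repeatability), `variance_components`,
#'   `mean_squares`, `n_individuals`, `replicates`.
#' @export
repeatability <- function(aligned, individual = "id") {
  s <- shape_matrix(aligned)
  g <- factor(aligned[[individual]])
  counts <- table(g)
  if (any(counts < 2)) {
    abort(paste0(
      "individual(s) with < 2 replicates: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  n <- nlevels(g)
  if (n < 2) abort("need at least 2 individuals")
  big_n <- nrow(s)
  means <- group_row_means(s, g)
  grand <- colMeans(s)
  ni <- as.vector(counts)
  ss_between <- sum(ni * rowSums(sweep(means, 2, grand)^2))
  ss_within <- sum((s - means[as.integer(g), , drop = FALSE])^2)
  ms_between <- ss_between / (n - 1)
  ms_within <- ss_within / (big_n - n)
  ## effective replicate number (exact r when balanced)
  r0 <- (big_n - sum(ni^2) / big_n) / (n - 1)
  s2_within <- ms_within
  s2_between <- max((ms_between - ms_within) / r0, 0)
  rep_val <- if (s2_between + s2_within == 0) 1 else {
    s2_between / (s2_between + s2_within)
  }
  structure(
    list(
      repeatability = rep_val,
      measurement_error = 1 - rep_val,
      variance_components = c(between = s2_between, within = s2_within),
      mean_squares = c(between = ms_between, within = ms_within),
      n_individuals = n,
      replicates = r0
    ),
    class = "repeatability_result"
  )
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("Procrustes ANOVA repeatability\n")
  cat("  individuals:", x$n_individuals,
      " replicates (effective):", format(x$replicates, digits = 4), "\n")
  cat("  repeatability:", format(x$repeatability, digits = 4),
      " measurement error:", format(x$measurement_error, digits = 4), "\n")
  invisible(x)
}
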