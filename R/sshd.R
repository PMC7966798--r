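#' Sex-difference vector
#'
#' The axis of sexual shape dimorphism: the difference between the male
#' mean shape (MM) and the female mean shape (FM) of an aligned dataset,
#' either pooled across populations (`scope = "global"`) or within one
#' population.
#'
#' @param aligned An `aligned_faces` tibble with a `sex` column
#'   (female/male) and, for population scope, a `population` column.
#' @param scope "global" or "population".
#' @param population Population name when `scope = "population"`.
#' @return A list of class `sex_vector`: `v1` (= MM - FM), `MM`, `FM`,
#'   `scope`, `population`, `n` (per-sex counts).
#' @export
sex_difference_vector <- function(aligned, scope = c("global", "population"),
                                  population = NULL) {
  scope <- match.arg(scope)
  data <- aligned
  if (scope == "population") {
    if (is.null(population)) abort("population must be given for population scope")
    data <- data[data$population == population, , drop = FALSE]
  }
  sex <- check_sex(data$sex)
  if (!all(c("female", "male") %in% levels(droplevels(sex)))) {
    abort(paste0("both sexes required in scope",
                 if (!is.null(population)) paste0(" (population ", population, ")")))
  }
  s <- shape_matrix(data)
  mm <- colMeans(s[sex == "male", , drop = FALSE])
  fm <- colMeans(s[sex == "female", , drop = FALSE])
  structure(
    list(
      v1 = mm - fm, MM = mm, FM = fm,
      scope = scope, population = population,
      n = c(female = sum(sex == "female"), male = sum(sex == "male"))
    ),
    class = "sex_vector"
  )
}

#' Sexscore: projection of a shape onto the sex-difference axis
#'
#' The raw (un-normalized) dot product of a shape vector with the
#' male-minus-female mean vector,
#' \deqn{sexscore(A) = A \cdot (MM - FM).}
#' There is no division by the norm of the axis, so scores are in squared
#' Procrustes units and comparable only for a fixed axis.
#'
#' @param shapes A flat shape vector, an n x 2k matrix, or an
#'   `aligned_faces` tibble.
#' @param v A `sex_vector` from [sex_difference_vector()], or a plain
#'   numeric axis vector.
#' @return A numeric vector of scores (one per shape).
#' @export
sexscore <- function(shapes, v) {
  axis <- if (inherits(v, "sex_vector")) v$v1 else as.numeric(v)
  if (vec_norm(axis) < .Machine$double.eps) {
    abort("degenerate sex vector (male and female means coincide)")
  }
  m <- if (is.data.frame(shapes)) {
    shape_matrix(shapes)
  } else if (is.matrix(shapes)) {
    shapes
  } else {
    matrix(shapes, nrow = 1)
  }
  if (ncol(m) != length(axis)) abort("shape and axis dimensions differ")
  as.vector(m %*% axis)
}

#' Invert female scores
#'
#' Multiplies female scores by -1 so that, for both sexes, higher values
#' mean a more sex-typical face (more masculine for men, more feminine for
#' women). Guarded against double application via an attribute flag.
#'
#' @param scores Numeric score vector.
#' @param sex Sex labels aligned with `scores`.
#' @return The score vector with female entries negated and attribute
#'   `sex_inverted = TRUE`.
#' @export
invert_female_scores <- function(scores, sex) {
  if (isTRUE(attr(scores, "sex_inverted"))) {
    abort("scores are already female-inverted")
  }
  sex <- check_sex(sex)
  if (length(scores) != length(sex)) abort("scores and sex differ in length")
  out <- ifelse(sex == "female", -scores, scores)
  attr(out, "sex_inverted") <- TRUE
  out
}

#' Per-coordinate regression of shape on a covariate
#'
#' Ordinary least squares of every shape coordinate on a single covariate
#' (with intercept), the workhorse behind the allometric decomposition and
#' nuisance-covariate residualization (log focal length, body weight). The
#' covariate is mean-centered first, so fitted values stay on shape scale
#' and the intercept equals the mean shape.
#'
#' @param aligned An `aligned_faces` tibble (or shape matrix).
#' @param covariate Numeric covariate, one value per row. Rows with missing
#'   covariate are excluded (with a message).
#' @return A list: `fitted` and `residuals` (n x 2k, rows with missing
#'   covariate dropped), `coefficients` (2k slope vector), `kept` (logical
#'   row filter), `n_dropped`.
#' @export
regress_shape_on_covariate <- function(aligned, covariate) {
  m <- if (is.data.frame(aligned)) shape_matrix(aligned) else as.matrix(aligned)
  if (length(covariate) != nrow(m)) abort("covariate length != number of rows")
  kept <- !is.na(covariate)
  n_dropped <- sum(!kept)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " row(s) with missing covariate")
  }
  m <- m[kept, , drop = FALSE]
  h <- covariate[kept]
  if (length(unique(h)) < 2) abort("covariate is constant (or nearly empty)")
  hc <- h - mean(h)
  denom <- sum(hc^2)
  coefs <- as.vector(crossprod(m, hc)) / denom
  center <- colMeans(m)
  fitted <- outer(rep(1, length(hc)), center) + outer(hc, coefs)
  list(
    fitted = fitted,
    residuals = m - fitted,
    coefficients = coefs,
    kept = kept,
    n_dropped = n_dropped
  )
}

#' Angle between two shape-space vectors
#'
#' Degrees in \[0, 180\], from the arccosine of the dot product over the
#' product of norms (cosine clipped to \[-1, 1\]).
#'
#' @param v,w Numeric vectors of equal length, both nonzero.
#' @return Angle in degrees.
#' @export
angle_between <- function(v, w) {
  nv <- vec_norm(v)
  nw <- vec_norm(w)
  if (nv < .Machine$double.eps || nw < .Machine$double.eps) {
    abort("angle undefined for a zero vector")
  }
  cosa <- sum(v * w) / (nv * nw)
  acos(min(1, max(-1, cosa))) * 180 / pi
}

#' Decompose sexual shape dimorphism into allometric and non-allometric parts
#'
#' Within each scope group (one population at a time, or the pooled
#' dataset):
#' \itemize{
#'   \item the overall sexscore projects each raw shape onto
#'     v1 = MM - FM;
#'   \item shape is regressed on body height; the allometric score projects
#'     the fitted values onto v1, and v2 is the vector of height
#'     regression coefficients;
#'   \item the non-allometric score projects the height residuals onto
#'     v3 = MM_res - FM_res, the sex-difference vector of the residuals;
#'   \item alpha = angle(v1, v2) and nu = angle(v1, v3).
#' }
#' Female scores of all three components are inverted (higher = more
#' sex-typical). Rows with missing height are excluded from the
#' decomposition (they still contributed to the superimposition).
#'
#' @param aligned An `aligned_faces` tibble with `sex`, `height` and (for
#'   population scope) `population` columns.
#' @param scope "population" (default; per-population means, regressions
#'   and angles, as used for the per-population analyses) or "global".
#' @return An object of class `sshd_decomposition`: `scores` (tibble: id,
#'   population, sex, height, score_overall, score_allometric,
#'   score_nonallometric; post-inversion), `angles` (tibble: population,
#'   alpha_deg, nu_deg, magnitude, n), `vectors` (per-group list with v1,
#'   v2, v3, MM, FM), `scope`, `female_inverted`.
#' @export
sshd_decompose <- function(aligned, scope = c("population", "global")) {
  scope <- match.arg(scope)
  if (!"height" %in% names(aligned)) abort("height column required")
  sex <- check_sex(aligned$sex)
  groups <- if (scope == "population") {
    if (!"population" %in% names(aligned)) abort("population column required")
    split(seq_len(nrow(aligned)), aligned$population)
  } else {
    list(global = seq_len(nrow(aligned)))
  }

  scores_list <- list()
  angles_list <- list()
  vectors <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    rows <- aligned[idx, , drop = FALSE]
    keep <- !is.na(rows$height)
    rows <- rows[keep, , drop = FALSE]
    gsex <- sex[idx][keep]
    if (!all(c("female", "male") %in% as.character(unique(gsex)))) {
      warn(paste0("group ", gname, " lacks a sex after height filtering; skipped"))
      next
    }
    s <- shape_matrix(rows)
    mm <- colMeans(s[gsex == "male", , drop = FALSE])
    fm <- colMeans(s[gsex == "female", , drop = FALSE])
    v1 <- mm - fm
    if (vec_norm(v1) < .Machine$double.eps) {
      abort(paste0("degenerate sex vector in group ", gname))
    }
    reg <- regress_shape_on_covariate(s, rows$height)
    v2 <- reg$coefficients
    res <- reg$residuals
    mm_res <- colMeans(res[gsex == "male", , drop = FALSE])
    fm_res <- colMeans(res[gsex == "female", , drop = FALSE])
    v3 <- mm_res - fm_res

    overall <- invert_female_scores(as.vector(s %*% v1), gsex)
    allometric <- invert_female_scores(as.vector(reg$fitted %*% v1), gsex)
    nonallo <- if (vec_norm(v3) < .Machine$double.eps) {
      rep(0, nrow(res))
    } else {
      invert_female_scores(as.vector(res %*% v3), gsex)
    }

    scores_list[[gname]] <- tibble::tibble(
      id = if ("id" %in% names(rows)) as.character(rows$id) else NA_character_,
      population = if ("population" %in% names(rows)) rows$population else gname,
      sex = as.character(gsex),
      height = rows$height,
      score_overall = as.numeric(overall),
      score_allometric = as.numeric(allometric),
      score_nonallometric = as.numeric(nonallo)
    )
    angles_list[[gname]] <- tibble::tibble(
      population = gname,
      alpha_deg = if (vec_norm(v2) < .Machine$double.eps) NA_real_ else angle_between(v1, v2),
      nu_deg = if (vec_norm(v3) < .Machine$double.eps) NA_real_ else angle_between(v1, v3),
      magnitude = vec_norm(v1),
      n = nrow(rows)
    )
    vectors[[gname]] <- list(v1 = v1, v2 = v2, v3 = v3,
                             MM = mm, FM = fm,
                             MM_res = mm_res, FM_res = fm_res)
  }
  if (!length(scores_list)) abort("no group with both sexes and heights")
  structure(
    list(
      scores = dplyr::bind_rows(scores_list),
      angles = dplyr::bind_rows(angles_list),
      vectors = vectors,
      scope = scope,
      female_inverted = TRUE
    ),
    class = "sshd_decomposition"
  )
}

#' @export
print.sshd_decomposition <- function(x, ...) {
  cat("Sexual shape dimorphism decomposition (scope:", x$scope, ")\n")
  print(x$angles)
  invisible(x)
}
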