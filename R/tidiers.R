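#' Tidiers for dimorph result objects
#'
#' broom-style `tidy()` / `glance()` methods so results drop straight into
#' dplyr/ggplot2 workflows.
#'
#' @param x A dimorph result object.
#' @param ... Unused.
#' @return A tibble.
#' @name dimorph-tidiers
NULL

#' @rdname dimorph-tidiers
#' @export
tidy.sshd_decomposition <- function(x, ...) x$angles

#' @rdname dimorph-tidiers
#' @export
glance.sshd_decomposition <- function(x, ...) {
  tibble::tibble(
    scope = x$scope,
    n_groups = nrow(x$angles),
    n = sum(x$angles$n),
    mean_alpha_deg = mean(x$angles$alpha_deg, na.rm = TRUE),
    mean_nu_deg = mean(x$angles$nu_deg, na.rm = TRUE),
    mean_magnitude = mean(x$angles$magnitude),
    female_inverted = x$female_inverted
  )
}

#' @rdname dimorph-tidiers
#' @export
tidy.sshd_lmm <- function(x, ...) x$fixed

#' @rdname dimorph-tidiers
#' @export
glance.sshd_lmm <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    singular = x$singular,
    n = if (x$method == "ols") length(x$model$residuals) else lme4::ngrps(x$model)[[1]]
  )
}

#' @rdname dimorph-tidiers
#' @export
tidy.quap_fit <- function(x, ...) x$coefficients

#' @rdname dimorph-tidiers
#' @export
glance.quap_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma = x$sigma, prior_sd = x$prior_sd)
}

#' @rdname dimorph-tidiers
#' @export
tidy.disparity_result <- function(x, ...) x$disparity

#' @rdname dimorph-tidiers
#' @export
tidy.trajectory_result <- function(x, ...) x$pairwise

#' @rdname dimorph-tidiers
#' @export
glance.trajectory_result <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x$magnitudes),
    n_perm = x$n_perm,
    mean_magnitude = mean(x$magnitudes$magnitude)
  )
}

#' @rdname dimorph-tidiers
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    observed = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    p_value = x$p,
    n_perm = x$n_perm
  )
}

#' @rdname dimorph-tidiers
#' @export
tidy.split_sample_result <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    within_mean = x$within_mean,
    within_sd = x$within_sd,
    between_mean = x$between_mean,
    between_sd = x$between_sd,
    p_value = x$p,
    n_perm = x$n_perm
  )
}

#' @rdname dimorph-tidiers
#' @export
tidy.repeatability_result <- function(x, ...) {
  tibble::tibble(
    repeatability = x$repeatability,
    measurement_error = x$measurement_error,
    var_between = x$variance_components[["between"]],
    var_within = x$variance_components[["within"]],
    n_individuals = x$n_individuals,
    replicates = x$replicates
  )
}
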