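#' Standardize attractiveness ratings within population
#'
#' Centers and scales ratings to mean 0, SD 1 within each population
#' (sample SD, n-1 denominator), making rating scales comparable across
#' populations that used different instruments.
#'
#' @param ratings Numeric vector of per-face mean ratings.
#' @param population Population labels aligned with `ratings`.
#' @return Numeric vector of standardized ratings.
#' @export
standardize_ratings <- function(ratings, population) {
  if (length(ratings) != length(population)) {
    abort("ratings and population differ in length")
  }
  out <- numeric(length(ratings))
  for (p in unique(population)) {
    i <- which(population == p)
    if (sum(!is.na(ratings[i])) < 2) {
      abort(paste0("population ", p, " has < 2 rated faces"))
    }
    s <- sd(ratings[i], na.rm = TRUE)
    if (is.na(s) || s == 0) {
      abort(paste0("zero rating SD in population ", p))
    }
    out[i] <- (ratings[i] - mean(ratings[i], na.rm = TRUE)) / s
  }
  out
}

#' Mixed-effects model of attractiveness on sexual shape dimorphism
#'
#' Fits `rating ~ score * sex` with correlated random intercepts and slopes
#' by population (REML, via lmerTest for Satterthwaite degrees of freedom).
#' Females are the reference category, so the four fixed effects are the
#' women's intercept, the women's SShD slope, and the changes in intercept
#' and slope for men. If the random-effect covariance is singular the model
#' is refit with uncorrelated random effects and flagged; with fewer than
#' two populations an ordinary least squares fit is returned instead
#' (flagged `"ols"`).
#'
#' @param data Data frame with the score, rating, sex and population
#'   columns.
#' @param score,rating,sex,population Column names (strings).
#' @return An object of class `sshd_lmm`: `fixed` (tibble: term, estimate,
#'   std_error, df, t_value, p_value), `varcorr`, `singular`, `method`,
#'   `model` (the underlying fit).
#' @export
fit_attractiveness_lmm <- function(data, score = "score", rating = "rating",
                                   sex = "sex", population = "population") {
  d <- tibble::tibble(
    rating = data[[rating]],
    score = data[[score]],
    sex = check_sex(data[[sex]]),  # female is the reference level
    population = factor(data[[population]])
  )
  d <- d[complete.cases(d), , drop = FALSE]
  term_names <- c(
    "Intercept (women)", "SShD slope (women)",
    "Change in intercept (men)", "Change in slope (men)"
  )

  if (nlevels(droplevels(d$population)) < 2) {
    fit <- lm(rating ~ score * sex, data = d)
    sm <- unname(summary(fit)$coefficients)
    fixed <- tibble::tibble(
      term = term_names,
      estimate = sm[, 1], std_error = sm[, 2],
      df = fit$df.residual, t_value = sm[, 3], p_value = sm[, 4]
    )
    return(structure(
      list(fixed = fixed, varcorr = NULL, singular = FALSE,
           method = "ols", model = fit),
      class = "sshd_lmm"
    ))
  }

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(rating ~ score * sex + (1 + score | population),
                   data = d, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit)
  method <- "lmm"
  if (singular) {
    fit2 <- suppressMessages(suppressWarnings(
      lmerTest::lmer(rating ~ score * sex + (1 + score || population),
                     data = d, REML = TRUE)
    ))
    fit <- fit2
    method <- "lmm_uncorrelated"
  }
  sm <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = term_names,
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    df = unname(sm[, "df"]),
    t_value = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  structure(
    list(
      fixed = fixed,
      varcorr = lme4::VarCorr(fit),
      singular = lme4::isSingular(fit),
      method = method,
      model = fit
    ),
    class = "sshd_lmm"
  )
}

#' @export
print.sshd_lmm <- function(x, ...) {
  cat("Attractiveness ~ SShD x sex (", x$method,
      if (x$singular) ", singular fit" , ")\n", sep = "")
  print(x$fixed)
  invisible(x)
}

#' Bayesian linear regression by quadratic approximation
#'
#' Maximum a posteriori fit of `y ~ x` with Normal(0, prior_sd) priors on
#' the (standardized) intercept and slope and a Normal(0, 1) prior on the
#' log noise scale, followed by a Gaussian approximation of the posterior
#' at the mode (inverse curvature). The 89% compatibility interval is
#' MAP +/- qnorm(0.945) * SD. With no data the posterior equals the prior.
#'
#' @param x,y Numeric vectors (standardized variables); may be empty for a
#'   prior-only posterior.
#' @param prior_sd Prior SD of intercept and slope (default 1).
#' @param sigma "estimate" (default) to infer the noise scale, or a fixed
#'   positive number for a known-noise fit.
#' @return An object of class `quap_fit`: `coefficients` (tibble: term,
#'   map, sd, lower_89, upper_89), `vcov`, `map`, `sigma`, `n`.
#' @export
bayes_linear_quap <- function(x, y, prior_sd = 1, sigma = "estimate") {
  if (length(x) != length(y)) abort("x and y differ in length")
  n <- length(x)
  estimate_sigma <- identical(sigma, "estimate")
  sigma_fixed <- if (!estimate_sigma) {
    if (!is.numeric(sigma) || sigma <= 0) abort("sigma must be 'estimate' or a positive number")
    sigma
  }

  nlpost <- function(par) {
    a <- par[1]; b <- par[2]
    s <- if (estimate_sigma) exp(par[3]) else sigma_fixed
    nll <- if (n > 0) -sum(dnorm(y, a + b * x, s, log = TRUE)) else 0
    npr <- -dnorm(a, 0, prior_sd, log = TRUE) - dnorm(b, 0, prior_sd, log = TRUE)
    if (estimate_sigma) npr <- npr - dnorm(par[3], 0, 1, log = TRUE)
    nll + npr
  }
  npar <- if (estimate_sigma) 3L else 2L
  start <- rep(0, npar)
  opt <- optim(start, nlpost, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  ## polish once from the first optimum
  opt <- optim(opt$par, nlpost, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  grad_norm <- vec_norm(numeric_grad(nlpost, opt$par))
  if (opt$convergence != 0 || !is.finite(opt$value) ||
      grad_norm > 1e-5 * (1 + abs(opt$value))) {
    abort(paste0("quadratic approximation did not converge (gradient norm ",
                 format(grad_norm), ")"))
  }
  hess <- optimHess(opt$par, nlpost)
  vc <- solve(hess)
  sds <- sqrt(diag(vc))
  terms <- c("intercept", "slope", if (estimate_sigma) "log_sigma")
  zq <- qnorm(0.945)
  coefs <- tibble::tibble(
    term = terms,
    map = opt$par,
    sd = sds,
    lower_89 = opt$par - zq * sds,
    upper_89 = opt$par + zq * sds
  )
  structure(
    list(
      coefficients = coefs,
      vcov = vc,
      map = setNames(opt$par, terms),
      sigma = if (estimate_sigma) exp(opt$par[3]) else sigma_fixed,
      n = n,
      prior_sd = prior_sd
    ),
    class = "quap_fit"
  )
}

numeric_grad <- function(f, par, eps = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- eps
    (f(par + e) - f(par - e)) / (2 * eps)
  }, numeric(1))
}

#' @export
print.quap_fit <- function(x, ...) {
  cat("Quadratic-approximation Bayesian regression (n = ", x$n, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Posterior compatibility corridor of a quap regression line
#'
#' Draws coefficient vectors from the Gaussian posterior approximation and
#' evaluates the regression line on a grid; the corridor is the pointwise
#' 5.5%/94.5% band (89% compatibility).
#'
#' @param fit A `quap_fit`.
#' @param x_grid Grid of predictor values.
#' @param draws Number of posterior draws (default 1000).
#' @param seed RNG seed.
#' @return Tibble: `x`, `mean`, `lower_89`, `upper_89`.
#' @export
posterior_corridor <- function(fit, x_grid, draws = 1000, seed = NULL) {
  mu <- fit$map[1:2]
  vc <- fit$vcov[1:2, 1:2, drop = FALSE]
  sims <- with_seed(seed, MASS::mvrnorm(draws, mu, vc))
  lines <- sims[, 1] + outer(sims[, 2], x_grid)
  tibble::tibble(
    x = x_grid,
    mean = colMeans(lines),
    lower_89 = apply(lines, 2, quantile, probs = 0.055, names = FALSE),
    upper_89 = apply(lines, 2, quantile, probs = 0.945, names = FALSE)
  )
}
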