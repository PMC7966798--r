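#' Stylized bilateral face template and base shape
#'
#' A 20-landmark schematic frontal face: 4 midline points (forehead, nose
#' tip, philtrum, chin), 8 bilateral pairs (brows, inner/outer eye corners,
#' nose wings, mouth corners, cheeks, jaw, chin sides), and 6 semilandmarks
#' on the two facial outline curves. The base shape is exactly bilaterally
#' symmetric with unit centroid size.
#'
#' @param k Number of landmarks; only the default 20 is defined.
#' @return A list: `template` (a [landmark_template()]) and `base` (flat 2k
#'   base shape vector).
#' @export
template_face <- function(k = 20) {
  if (k != 20) abort("only the 20-landmark face template is defined")
  pts <- rbind(
    c(0, 1.00),     # 1 forehead
    c(0, 0.10),     # 2 nose tip
    c(0, -0.35),    # 3 philtrum
    c(0, -0.90),    # 4 chin
    c(-0.25, 0.45), c(0.25, 0.45),   # 5/6 inner eye corners
    c(-0.55, 0.48), c(0.55, 0.48),   # 7/8 outer eye corners
    c(-0.40, 0.65), c(0.40, 0.65),   # 9/10 brows
    c(-0.18, 0.05), c(0.18, 0.05),   # 11/12 nose wings
    c(-0.30, -0.35), c(0.30, -0.35), # 13/14 mouth corners
    c(-0.80, 0.20), c(0.80, 0.20),   # 15/16 cheeks
    c(-0.65, -0.45), c(0.65, -0.45), # 17/18 jaw
    c(-0.30, -0.80), c(0.30, -0.80)  # 19/20 chin sides
  )
  template <- landmark_template(
    n_landmarks = 20,
    semilandmarks = c(15, 17, 19, 16, 18, 20),
    curves = list(c(1, 15, 17, 19, 4), c(1, 16, 18, 20, 4)),
    bilateral_pairs = cbind(
      c(5, 7, 9, 11, 13, 15, 17, 19),
      c(6, 8, 10, 12, 14, 16, 18, 20)
    ),
    midline = 1:4
  )
  pts <- centered_rows(pts)
  pts <- pts / centroid_size(pts)
  list(template = template, base = as_flat(pts))
}

#' Project a displacement field into the tangent space of a base shape
#'
#' Removes the components of a flat displacement field along the similarity
#' transformations of the base shape (x/y translation, scaling, rotation),
#' so that the field survives Procrustes superimposition unchanged to first
#' order.
#'
#' @param field Flat 2k displacement vector.
#' @param base Flat 2k base shape (centered, unit centroid size).
#' @return The projected flat vector.
#' @export
tangent_field <- function(field, base) {
  k <- length(base) / 2
  xi <- seq(1, 2 * k, by = 2)
  yi <- xi + 1
  tx <- rep(0, 2 * k); tx[xi] <- 1
  ty <- rep(0, 2 * k); ty[yi] <- 1
  rot <- rep(0, 2 * k); rot[xi] <- -base[yi]; rot[yi] <- base[xi]
  basis <- cbind(tx, ty, base, rot)
  q <- qr.Q(qr(basis))
  as.vector(field - q %*% crossprod(q, field))
}

#' Canonical effect fields on the stylized face
#'
#' Unit tangent-space displacement fields used as generator defaults:
#' `masculinity_field()` lowers the brows, widens jaw and nose, lengthens
#' the chin and shrinks the eyes; `allometry_field()` elongates the face
#' with a more robust lower face (per unit covariate).
#'
#' @param base Flat base shape from [template_face()].
#' @return A unit flat 2k vector in the tangent space of `base`.
#' @export
masculinity_field <- function(base) {
  k <- length(base) / 2
  d <- matrix(0, k, 2)
  d[9, ] <- c(0, -1.0); d[10, ] <- c(0, -1.0)       # brows down
  d[17, ] <- c(-0.8, 0); d[18, ] <- c(0.8, 0)       # jaw out
  d[4, ] <- c(0, -0.8)                               # chin down
  d[19, ] <- c(0, -0.5); d[20, ] <- c(0, -0.5)       # chin sides down
  d[11, ] <- c(-0.4, 0); d[12, ] <- c(0.4, 0)        # nose wider
  d[5, ] <- c(0.2, -0.1); d[6, ] <- c(-0.2, -0.1)    # eyes smaller
  d[7, ] <- c(0.2, -0.1); d[8, ] <- c(-0.2, -0.1)
  f <- tangent_field(as_flat(d), base)
  f / vec_norm(f)
}

#' @rdname masculinity_field
#' @export
allometry_field <- function(base) {
  k <- length(base) / 2
  cfg <- as_config(base)
  d <- matrix(0, k, 2)
  d[, 2] <- cfg[, 2] * 1.0                           # elongation
  d[17, 1] <- d[17, 1] - 0.3; d[18, 1] <- d[18, 1] + 0.3
  d[15, 1] <- d[15, 1] - 0.15; d[16, 1] <- d[16, 1] + 0.15
  d[9, 2] <- d[9, 2] + 0.2; d[10, 2] <- d[10, 2] + 0.2
  f <- tangent_field(as_flat(d), base)
  f / vec_norm(f)
}

#' Construct a unit tangent field at a chosen angle to a reference field
#'
#' Useful for generating populations whose allometric vector sits at a
#' known angle to the sex-difference vector.
#'
#' @param base Flat base shape.
#' @param ref Unit reference field (flat).
#' @param angle_deg Desired angle in degrees.
#' @param other A second independent field supplying the orthogonal
#'   direction (default: the canonical allometry field).
#' @return A unit flat vector at `angle_deg` to `ref`.
#' @export
field_at_angle <- function(base, ref, angle_deg, other = NULL) {
  ref <- ref / vec_norm(ref)
  other <- other %||% allometry_field(base)
  perp <- other - sum(other * ref) * ref
  if (vec_norm(perp) < 1e-12) abort("other field is collinear with ref")
  perp <- perp / vec_norm(perp)
  th <- angle_deg * pi / 180
  cos(th) * ref + sin(th) * perp
}

#' Specification of a synthetic multi-population landmark dataset
#'
#' Defines the generative ground truth: a population's individual i of sex
#' s has flat shape
#' `base + offset_p + (+/- d_p/2) + (height_i - pooled mean height) * b_p
#'  + noise`,
#' the sex effect applied as +d/2 for males and -d/2 for females so that
#' MM - FM = d in expectation; heights are Normal with sex-specific means;
#' attractiveness is a linear function of the (standardized, female-
#' inverted) realized sexscore with sex-specific slopes. An arbitrary
#' rotation/translation/scaling is applied to every written specimen so the
#' superimposition has real work to do.
#'
#' Defaults emulate an eight-population cross-cultural face sample:
#' 100 individuals per sex per population, isotropic landmark noise
#' SD 0.005, sex-difference magnitude 0.03 (Procrustes units), allometric
#' magnitude 3e-4 per cm, stature means 165 (f) / 178 (m) cm with SD 6.5,
#' attractiveness slopes 0.2 (women) / 0 (men).
#'
#' @param n_populations Number of populations (default 8; ignored when
#'   `populations` is supplied).
#' @param n_per_sex Individuals per sex per population.
#' @param d_scale Magnitude of the sex-difference vector; scalar or one per
#'   population.
#' @param b_scale Magnitude of the allometric vector per cm; scalar or one
#'   per population.
#' @param shape_noise_sd Isotropic per-coordinate landmark noise SD.
#' @param mean_offset_sd SD of the random population mean offsets
#'   (tangent-projected); 0 for identical population means.
#' @param height_mean_f,height_mean_m,height_sd Stature distribution (cm).
#' @param slope_women,slope_men,attract_noise_sd Attractiveness model.
#' @param replicate_noise_sd If non-NULL, a second digitization of every
#'   specimen is generated with this extra landmark noise.
#' @param rigid Apply random rotation/translation/scale per specimen
#'   (default TRUE).
#' @param populations Optional full populations tibble overriding the
#'   scalar arguments: columns `name`, `n_per_sex`, `height_mean_f`,
#'   `height_mean_m`, `height_sd` and list-columns `d`, `b` (flat vectors),
#'   optionally `mean_offset`.
#' @param seed Integer seed; the same seed yields byte-identical data.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_populations = 8,
                           n_per_sex = 100,
                           d_scale = 0.03,
                           b_scale = 3e-4,
                           shape_noise_sd = 0.005,
                           mean_offset_sd = 0.01,
                           height_mean_f = 165,
                           height_mean_m = 178,
                           height_sd = 6.5,
                           slope_women = 0.2,
                           slope_men = 0,
                           attract_noise_sd = 1,
                           replicate_noise_sd = NULL,
                           rigid = TRUE,
                           populations = NULL,
                           seed = 1L) {
  tf <- template_face()
  base <- tf$base
  if (is.null(populations)) {
    names_default <- c("NAM", "CMR", "TR", "RO", "CZ", "UK", "COL", "BRAZ")
    nm <- if (n_populations <= 8) {
      names_default[seq_len(n_populations)]
    } else {
      paste0("POP", seq_len(n_populations))
    }
    d_unit <- masculinity_field(base)
    b_unit <- allometry_field(base)
    d_scale <- rep_len(d_scale, n_populations)
    b_scale <- rep_len(b_scale, n_populations)
    populations <- tibble::tibble(
      name = nm,
      n_per_sex = rep_len(n_per_sex, n_populations),
      height_mean_f = rep_len(height_mean_f, n_populations),
      height_mean_m = rep_len(height_mean_m, n_populations),
      height_sd = rep_len(height_sd, n_populations),
      d = lapply(d_scale, function(s) s * d_unit),
      b = lapply(b_scale, function(s) s * b_unit)
    )
  }
  if (!"mean_offset" %in% names(populations)) {
    populations$mean_offset <- vector("list", nrow(populations))
  }
  structure(
    list(
      template = tf$template,
      base = base,
      populations = populations,
      shape_noise_sd = shape_noise_sd,
      mean_offset_sd = mean_offset_sd,
      attractiveness = list(
        slope_women = slope_women,
        slope_men = slope_men,
        noise_sd = attract_noise_sd
      ),
      replicate_noise_sd = replicate_noise_sd,
      rigid = rigid,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic landmark dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_faces`: `data` (tibble: id,
#'   population, sex, height, attractiveness + flat coordinate columns,
#'   post rigid motion), `replicates` (NULL, or a tibble with a `replicate`
#'   column stacking two digitizations of every specimen), `truth` (list
#'   with per-population `d`, `b`, `mean_offset`, `expected_v1` = d +
#'   realized height gap * b, `true_alpha_deg`, `true_magnitude`, plus
#'   `scores`: per-individual true sexscores), `template`, `base`, `spec`.
#' @export
simulate_faces <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- spec$base
  k2 <- length(base)
  pops <- spec$populations

  with_seed(spec$seed, {
    offsets <- lapply(seq_len(nrow(pops)), function(i) {
      off <- pops$mean_offset[[i]]
      if (is.null(off)) {
        off <- if (spec$mean_offset_sd > 0) {
          tangent_field(rnorm(k2, 0, spec$mean_offset_sd), base)
        } else {
          rep(0, k2)
        }
      }
      off
    })

    rows <- list()
    for (i in seq_len(nrow(pops))) {
      n <- pops$n_per_sex[i]
      sex <- rep(c("female", "male"), each = n)
      h <- c(
        rnorm(n, pops$height_mean_f[i], pops$height_sd[i]),
        rnorm(n, pops$height_mean_m[i], pops$height_sd[i])
      )
      rows[[i]] <- tibble::tibble(
        id = sprintf("%s_%s%04d", pops$name[i],
                     substr(sex, 1, 1), seq_len(2 * n)),
        population = pops$name[i],
        sex = sex,
        height = h
      )
    }
    meta <- dplyr::bind_rows(rows)
    pooled_mean_h <- mean(meta$height)

    n_all <- nrow(meta)
    shapes <- matrix(0, n_all, k2)
    true_score <- numeric(n_all)
    pop_index <- match(meta$population, pops$name)
    for (i in seq_len(n_all)) {
      p <- pop_index[i]
      d <- pops$d[[p]]
      b <- pops$b[[p]]
      sgn <- if (meta$sex[i] == "male") 0.5 else -0.5
      mu <- base + offsets[[p]] + sgn * d +
        (meta$height[i] - pooled_mean_h) * b
      shapes[i, ] <- mu + rnorm(k2, 0, spec$shape_noise_sd)
      true_score[i] <- sum((shapes[i, ] - base) * d)
    }

    ## attractiveness: sex-specific slope on the female-inverted realized
    ## sexscore standardized within population x sex (sex-typicality
    ## relative to same-sex peers of one's own population, the quantity
    ## opposite-sex raters of that population effectively judge);
    ## degenerate (zero-variance) score distributions carry no signal
    inv <- ifelse(meta$sex == "female", -true_score, true_score)
    z <- numeric(n_all)
    for (p in pops$name) {
      for (sx in c("female", "male")) {
        cell <- meta$population == p & meta$sex == sx
        s_c <- sd(inv[cell])
        z[cell] <- if (is.na(s_c) || s_c == 0) 0 else {
          (inv[cell] - mean(inv[cell])) / s_c
        }
      }
    }
    slope <- ifelse(meta$sex == "female",
                    spec$attractiveness$slope_women,
                    spec$attractiveness$slope_men)
    meta$attractiveness <- slope * z +
      rnorm(n_all, 0, spec$attractiveness$noise_sd)

    rep2 <- if (!is.null(spec$replicate_noise_sd)) {
      shapes + matrix(rnorm(n_all * k2, 0, spec$replicate_noise_sd),
                      n_all, k2)
    }

    apply_rigid <- function(m) {
      for (i in seq_len(nrow(m))) {
        cfg <- as_config(m[i, ])
        th <- runif(1, 0, 2 * pi)
        sc <- exp(runif(1, log(0.5), log(2)))
        tr <- runif(2, -2, 2)
        r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
        cfg <- sc * cfg %*% r
        cfg[, 1] <- cfg[, 1] + tr[1]
        cfg[, 2] <- cfg[, 2] + tr[2]
        m[i, ] <- as_flat(cfg)
      }
      m
    }
    if (spec$rigid) {
      shapes <- apply_rigid(shapes)
      if (!is.null(rep2)) rep2 <- apply_rigid(rep2)
    }
  })

  data <- dplyr::bind_cols(meta, shapes_tibble(shapes))
  attr(data, "template") <- spec$template
  class(data) <- c("face_dataset", class(data))

  replicates <- NULL
  if (!is.null(rep2)) {
    r1 <- dplyr::bind_cols(meta[c("id", "population", "sex")],
                           tibble::tibble(replicate = 1L),
                           shapes_tibble(shapes))
    r2 <- dplyr::bind_cols(meta[c("id", "population", "sex")],
                           tibble::tibble(replicate = 2L),
                           shapes_tibble(rep2))
    replicates <- dplyr::bind_rows(r1, r2)
    attr(replicates, "template") <- spec$template
    class(replicates) <- c("face_dataset", class(replicates))
  }

  ## Exact model-implied truth of the per-population decomposition.
  ## v1 = MM - FM = d + (realized height gap) b. The pooled-sex height
  ## regression leaks the direct sex effect into its coefficient vector
  ## because stature is itself dimorphic: with sex coded +/- 1/2 and
  ## heights centered within population, the expected coefficient vector
  ## is v2 = b + lambda d with lambda = sum(hc * sexsign) / sum(hc^2).
  ## The residual sex difference is then v3 = (1 - gap * lambda) d.
  gap <- numeric(nrow(pops))
  lambda <- numeric(nrow(pops))
  for (p in seq_len(nrow(pops))) {
    rows_p <- meta$population == pops$name[p]
    h <- meta$height[rows_p]
    ss <- ifelse(meta$sex[rows_p] == "male", 0.5, -0.5)
    gap[p] <- mean(h[ss > 0]) - mean(h[ss < 0])
    hc <- h - mean(h)
    lambda[p] <- sum(hc * ss) / sum(hc^2)
  }
  expected_v1 <- lapply(seq_len(nrow(pops)), function(p) {
    pops$d[[p]] + gap[p] * pops$b[[p]]
  })
  expected_v2 <- lapply(seq_len(nrow(pops)), function(p) {
    pops$b[[p]] + lambda[p] * pops$d[[p]]
  })
  truth <- list(
    d = setNames(pops$d, pops$name),
    b = setNames(pops$b, pops$name),
    mean_offset = setNames(offsets, pops$name),
    height_gap = setNames(gap, pops$name),
    expected_v1 = setNames(expected_v1, pops$name),
    expected_v2 = setNames(expected_v2, pops$name),
    true_magnitude = setNames(
      vapply(expected_v1, vec_norm, numeric(1)), pops$name
    ),
    true_alpha_deg = setNames(vapply(seq_len(nrow(pops)), function(p) {
      if (vec_norm(expected_v2[[p]]) < 1e-15 ||
          vec_norm(expected_v1[[p]]) < 1e-15) return(NA_real_)
      angle_between(expected_v1[[p]], expected_v2[[p]])
    }, numeric(1)), pops$name),
    true_nu_deg = setNames(vapply(seq_len(nrow(pops)), function(p) {
      if (vec_norm(pops$d[[p]]) < 1e-15 ||
          vec_norm(expected_v1[[p]]) < 1e-15) return(NA_real_)
      angle_between(expected_v1[[p]], pops$d[[p]])
    }, numeric(1)), pops$name),
    scores = tibble::tibble(
      id = meta$id,
      population = meta$population,
      sex = meta$sex,
      true_score = true_score
    ),
    pooled_mean_height = pooled_mean_h
  )

  structure(
    list(
      data = data,
      replicates = replicates,
      truth = truth,
      template = spec$template,
      base = base,
      spec = spec
    ),
    class = "synthetic_faces"
  )
}

#' Write a synthetic dataset to standard files
#'
#' TPS landmarks, CSV metadata, YAML template and JSON truth record.
#'
#' @param faces A `synthetic_faces` object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(faces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- shape_matrix(faces$data)
  configs <- tibble::tibble(
    id = faces$data$id,
    points = lapply(seq_len(nrow(m)), function(i) as_config(m[i, ]))
  )
  write_tps(configs, file.path(dir, "landmarks.tps"))
  readr::write_csv(
    faces$data[c("id", "population", "sex", "height", "attractiveness")],
    file.path(dir, "metadata.csv")
  )
  write_template(faces$template, file.path(dir, "template.yaml"))
  truth <- faces$truth
  truth$scores <- as.list(truth$scores)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
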