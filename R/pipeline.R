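#' Read a pipeline run configuration
#'
#' YAML (or JSON) with the run parameters; see [run_pipeline()] for the
#' recognized fields. The configuration is persisted verbatim alongside the
#' outputs so a run is fully reproducible from its output directory.
#'
#' @param path Config file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full dimorphism analysis pipeline
#'
#' Stages, mirroring the method's order: superimpose (GPA), slide
#' semilandmarks, symmetrize, optionally residualize nuisance covariates,
#' decompose sexual shape dimorphism (scores + angles), morphological
#' disparity, median-distance randomization test (when a region map is
#' given), trajectory analysis, and attractiveness preference models.
#' Every stochastic stage takes its seed from the config; rerunning the
#' same config reproduces the summary bit for bit.
#'
#' @param config A named list / `run_config`. Recognized fields:
#'   \describe{
#'     \item{tps, metadata, template}{input file paths, or}
#'     \item{synthetic}{list of [synthetic_spec()] arguments,}
#'     \item{slide, symmetrize}{logical stage toggles (default TRUE),}
#'     \item{slide_iterations}{outer sliding passes (default 3),}
#'     \item{residualize}{character vector of metadata covariates to
#'       regress out of shape (e.g. "log_focal_length", "weight"),}
#'     \item{scope}{"population" (default) or "global",}
#'     \item{n_perm}{permutations for disparity/trajectory/randomization
#'       (default 999),}
#'     \item{region_map, focal_region}{population -> region map and the
#'       focal region for the median-distance contrast,}
#'     \item{seed}{integer master seed,}
#'     \item{output_dir}{where results are written (NULL: nothing written).}
#'   }
#' @return A list of class `pipeline_result` with elements `aligned`,
#'   `decomposition`, `disparity`, `trajectory`, `median_distance`,
#'   `randomization`, `preference`, `summary` (plain list, what gets
#'   serialized to JSON).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  seed <- cfg[["seed"]] %||% 1L
  n_perm <- cfg[["n_perm"]] %||% 999L
  scope <- cfg[["scope"]] %||% "population"
  out_dir <- cfg[["output_dir"]]
  log_stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)

  ## ---- input ----
  if (!is.null(cfg[["synthetic"]])) {
    log_stage("stage: simulate")
    spec <- do.call(synthetic_spec, c(cfg[["synthetic"]], list(seed = seed)))
    faces <- simulate_faces(spec)
    dataset <- faces$data
    template <- faces$template
  } else {
    log_stage("stage: load")
    configs <- read_tps(cfg[["tps"]], flip_y = isTRUE(cfg[["flip_y"]]))
    metadata <- read_metadata(cfg[["metadata"]], delim = cfg[["delim"]] %||% ",")
    template <- read_template(cfg[["template"]])
    dataset <- assemble_dataset(configs, metadata, template, quiet = TRUE)
  }

  ## ---- superimposition ----
  log_stage("stage: gpa (n = ", nrow(dataset), ")")
  aligned <- gpa(dataset)
  if (isTRUE(cfg[["slide"]] %||% TRUE) && length(template$semilandmarks)) {
    log_stage("stage: slide semilandmarks")
    aligned <- slide_semilandmarks(aligned, template,
                                   iterations = cfg[["slide_iterations"]] %||% 3)
  }
  if (isTRUE(cfg[["symmetrize"]] %||% TRUE) && !is.null(template$bilateral_pairs)) {
    log_stage("stage: symmetrize")
    aligned <- symmetrize(aligned, template)
  }

  ## ---- nuisance covariates ----
  for (cov in cfg[["residualize"]] %||% character()) {
    col <- sub("^log_", "", cov)
    if (!col %in% names(aligned)) {
      abort(paste0("residualize: no metadata column ", col))
    }
    v <- aligned[[col]]
    if (grepl("^log_", cov)) v <- log(v)
    log_stage("stage: residualize on ", cov)
    reg <- regress_shape_on_covariate(aligned, v)
    s <- shape_matrix(aligned)
    s[reg$kept, ] <- sweep(reg$residuals, 2, colMeans(s[reg$kept, , drop = FALSE]), "+")
    aligned <- set_coords(aligned, s)
    prov <- attr(aligned, "provenance")
    prov$residualized_on <- c(prov$residualized_on, cov)
    attr(aligned, "provenance") <- prov
  }

  ## ---- SShD ----
  log_stage("stage: sshd decomposition (scope: ", scope, ")")
  decomp <- sshd_decompose(aligned, scope = scope)

  ## ---- disparity ----
  log_stage("stage: morphological disparity")
  disparity <- morphological_disparity(aligned, n_perm = n_perm, seed = seed)

  ## ---- median-distance contrast + randomization test ----
  median_distance <- NULL
  randomization <- NULL
  if (!is.null(cfg[["region_map"]])) {
    log_stage("stage: median-distance randomization test")
    region_map <- unlist(cfg[["region_map"]])
    focal <- cfg[["focal_region"]]
    score_frame <- function(d) {
      dec <- sshd_decompose(d, scope = "population")
      sc <- dec$scores
      ## pre-inversion overall scores
      sc$score <- ifelse(sc$sex == "female", -sc$score_overall, sc$score_overall)
      sc
    }
    base_scores <- score_frame(aligned)
    median_distance <- median_distance_statistic(base_scores, region_map, focal)
    stat_fun <- function(d) {
      median_distance_statistic(score_frame(d), region_map, focal)$contrast
    }
    randomization <- randomization_test(
      aligned, stat_fun, n_perm = n_perm, seed = seed,
      label = paste0("median-distance contrast vs ", focal)
    )
  }

  ## ---- trajectory ----
  log_stage("stage: trajectory analysis")
  trajectory <- trajectory_analysis(aligned, n_perm = n_perm, seed = seed)

  ## ---- preference models ----
  preference <- NULL
  if ("attractiveness" %in% names(aligned) &&
      any(!is.na(aligned$attractiveness))) {
    log_stage("stage: preference models")
    sc <- decomp$scores
    att <- aligned$attractiveness[match(sc$id, aligned$id)]
    sc$rating <- standardize_ratings(att, sc$population)
    preference <- lapply(
      c(overall = "score_overall", allometric = "score_allometric",
        nonallometric = "score_nonallometric"),
      function(col) {
        d <- sc
        d$score <- standardize_ratings(d[[col]], d$population)
        fit_attractiveness_lmm(d)
      }
    )
  }

  summary <- list(
    n = nrow(aligned),
    scope = scope,
    seed = seed,
    n_perm = n_perm,
    provenance = attr(aligned, "provenance"),
    angles = as.list(decomp$angles),
    disparity = as.list(disparity$disparity),
    trajectory_magnitudes = as.list(trajectory$magnitudes),
    median_distance = if (!is.null(median_distance)) list(
      contrast = median_distance$contrast,
      region_means = as.list(median_distance$region_means),
      p = randomization$p
    ),
    preference = if (!is.null(preference)) {
      lapply(preference, function(f) as.list(f$fixed))
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    write_aligned(aligned, file.path(out_dir, "aligned.csv"))
    readr::write_csv(decomp$scores, file.path(out_dir, "scores.csv"))
    jsonlite::write_json(as.list(decomp$angles),
                         file.path(out_dir, "angles.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(disparity$disparity, file.path(out_dir, "disparity.csv"))
    if (!is.null(preference)) {
      readr::write_csv(
        dplyr::bind_rows(lapply(preference, function(f) f$fixed),
                         .id = "component"),
        file.path(out_dir, "preference_models.csv")
      )
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("outputs written to ", out_dir)
  }

  structure(
    list(
      aligned = aligned,
      decomposition = decomp,
      disparity = disparity,
      trajectory = trajectory,
      median_distance = median_distance,
      randomization = randomization,
      preference = preference,
      summary = summary
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("dimorph pipeline result: n =", x$summary$n,
      "| scope:", x$summary$scope, "\n")
  print(x$decomposition$angles)
  invisible(x)
}
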