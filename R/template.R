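#' Landmark template
#'
#' A template declares, for a fixed landmark numbering, which points are
#' semilandmarks (and along which curves they slide), which points form
#' left/right bilateral pairs, and which lie on the midline. Indices are
#' 1-based, matching morphometrics convention in configuration files.
#'
#' @param n_landmarks Number of landmarks k (>= 3).
#' @param semilandmarks Integer vector of semilandmark indices. Each must be
#'   an interior point of one of `curves`, so it has two sliding neighbours.
#' @param curves List of integer vectors; each vector is an ordered run of
#'   landmark indices along an outline. Only curve-interior points may slide.
#' @param bilateral_pairs Two-column integer matrix (or list of length-2
#'   vectors) of (left, right) index pairs.
#' @param midline Integer vector of landmarks on the bilateral symmetry axis.
#'
#' `bilateral_pairs` and `midline`, when supplied, must together partition
#' all landmark indices (needed by [symmetrize()]). They may be omitted for
#' templates used only for sliding.
#'
#' @return An object of class `landmark_template`.
#' @export
landmark_template <- function(n_landmarks,
                              semilandmarks = integer(),
                              curves = list(),
                              bilateral_pairs = NULL,
                              midline = NULL) {
  k <- as.integer(n_landmarks)
  if (is.na(k) || k < 3) abort("n_landmarks must be an integer >= 3")
  semilandmarks <- sort(unique(as.integer(semilandmarks)))
  curves <- lapply(curves, as.integer)

  check_idx <- function(i, what) {
    if (length(i) && (any(is.na(i)) || any(i < 1) || any(i > k))) {
      abort(paste0(what, " contains indices outside 1..", k))
    }
  }
  check_idx(semilandmarks, "semilandmarks")
  for (cv in curves) {
    check_idx(cv, "curves")
    if (anyDuplicated(cv)) abort("a curve visits the same landmark twice")
  }

  interior <- unlist(lapply(curves, function(cv) {
    if (length(cv) >= 3) cv[-c(1, length(cv))] else integer()
  }))
  missing_nb <- setdiff(semilandmarks, interior)
  if (length(missing_nb)) {
    abort(paste0(
      "semilandmark(s) without two curve neighbours: ",
      paste(missing_nb, collapse = ", ")
    ))
  }

  if (!is.null(bilateral_pairs)) {
    if (is.list(bilateral_pairs)) {
      bilateral_pairs <- do.call(rbind, lapply(bilateral_pairs, as.integer))
    }
    bilateral_pairs <- matrix(as.integer(bilateral_pairs), ncol = 2)
    check_idx(as.vector(bilateral_pairs), "bilateral_pairs")
  }
  if (!is.null(midline)) {
    midline <- sort(unique(as.integer(midline)))
    check_idx(midline, "midline")
  }
  if (!is.null(bilateral_pairs) || !is.null(midline)) {
    lab <- c(as.vector(bilateral_pairs), midline)
    if (anyDuplicated(lab)) {
      abort("an index appears in more than one of bilateral_pairs/midline")
    }
    unpaired <- setdiff(seq_len(k), lab)
    if (length(unpaired)) {
      abort(paste0(
        "unpaired non-midline landmark(s): ",
        paste(unpaired, collapse = ", "),
        " (bilateral_pairs and midline must cover every landmark)"
      ))
    }
  }

  structure(
    list(
      n_landmarks = k,
      semilandmarks = semilandmarks,
      curves = curves,
      bilateral_pairs = bilateral_pairs,
      midline = midline
    ),
    class = "landmark_template"
  )
}

#' @export
print.landmark_template <- function(x, ...) {
  cat("<landmark_template> k =", x$n_landmarks,
      "|", length(x$semilandmarks), "semilandmarks on",
      length(x$curves), "curve(s)")
  if (!is.null(x$bilateral_pairs)) {
    cat(" |", nrow(x$bilateral_pairs), "bilateral pairs,",
        length(x$midline), "midline points")
  }
  cat("\n")
  invisible(x)
}

## semilandmark -> (previous, next) neighbour lookup
semilandmark_neighbours <- function(template) {
  nb <- list()
  for (cv in template$curves) {
    if (length(cv) < 3) next
    for (j in 2:(length(cv) - 1)) {
      nb[[as.character(cv[j])]] <- c(cv[j - 1], cv[j + 1])
    }
  }
  out <- lapply(as.character(template$semilandmarks), function(s) nb[[s]])
  names(out) <- as.character(template$semilandmarks)
  out
}

#' Read / write a landmark template configuration file
#'
#' Templates are stored as YAML (or JSON) with 1-based indices and keys
#' `n_landmarks`, `semilandmarks`, `curves`, `bilateral_pairs`, `midline`.
#'
#' @param path File path.
#' @return [read_template()] returns a `landmark_template`.
#' @export
read_template <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pairs <- spec$bilateral_pairs
  if (!is.null(pairs) && is.data.frame(pairs)) pairs <- as.matrix(pairs)
  landmark_template(
    n_landmarks = spec$n_landmarks,
    semilandmarks = spec$semilandmarks %||% integer(),
    curves = spec$curves %||% list(),
    bilateral_pairs = pairs,
    midline = spec$midline
  )
}

#' @rdname read_template
#' @param template A `landmark_template`.
#' @export
write_template <- function(template, path) {
  out <- list(
    n_landmarks = template$n_landmarks,
    semilandmarks = template$semilandmarks,
    curves = template$curves,
    bilateral_pairs = if (!is.null(template$bilateral_pairs)) {
      lapply(seq_len(nrow(template$bilateral_pairs)),
             function(i) template$bilateral_pairs[i, ])
    },
    midline = template$midline
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
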