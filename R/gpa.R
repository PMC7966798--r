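#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; the size measure removed by the Procrustes scaling step.
#'
#' @param points k x 2 coordinate matrix.
#' @return A non-negative number (0 for coincident points; the GPA scaling
#'   step rejects 0).
#' @export
centroid_size <- function(points) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) abort("non-finite coordinates")
  sqrt(sum(centered_rows(points)^2))
}

#' Optimal rotation of one centered configuration onto another
#'
#' The proper (determinant +1) rotation minimizing the summed squared
#' distance of `a %*% R` to `b`. Reflections are disallowed; in 2D the
#' optimum has the closed form (cos, sin) proportional to
#' (tr M, M21 - M12) with M = t(a) b.
#'
#' @param a,b Centered k x 2 coordinate matrices.
#' @return A 2 x 2 rotation matrix.
#' @export
optimal_rotation <- function(a, b) {
  m <- crossprod(as.matrix(a), as.matrix(b))
  co <- m[1, 1] + m[2, 2]
  si <- m[2, 1] - m[1, 2]
  nr <- sqrt(co^2 + si^2)
  if (nr < .Machine$double.eps) {
    warn("degenerate configurations: returning identity rotation")
    return(diag(2))
  }
  co <- co / nr
  si <- si / nr
  matrix(c(co, -si, si, co), 2, 2, byrow = TRUE)
}

## Rotate every row (flat 2k shape vector) of S to best match consensus c.
## Vectorized over specimens; returns the rotated matrix.
rotate_rows_to <- function(s, cons) {
  k <- ncol(s) / 2
  xi <- seq(1, 2 * k, by = 2)
  yi <- xi + 1
  sx <- s[, xi, drop = FALSE]
  sy <- s[, yi, drop = FALSE]
  cx <- cons[xi]
  cy <- cons[yi]
  a <- as.vector(sx %*% cx + sy %*% cy)   # tr(M)
  b <- as.vector(sy %*% cx - sx %*% cy)   # M21 - M12
  nr <- sqrt(a^2 + b^2)
  nr[nr < .Machine$double.eps] <- 1
  co <- a / nr
  si <- b / nr
  out <- s
  out[, xi] <- co * sx + si * sy
  out[, yi] <- -si * sx + co * sy
  out
}

#' Generalized Procrustes analysis
#'
#' Translates every configuration to a common centroid, scales to unit
#' centroid size, and iteratively rotates all configurations to the running
#' consensus until the consensus stabilizes. Optionally projects the
#' aligned shapes orthogonally into the tangent space at the consensus,
#' where downstream linear operations (regressions, projections, means)
#' are well behaved.
#'
#' @param data A `face_dataset` (or any tibble with coordinate columns
#'   `x1..yk`; metadata columns are carried through).
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter Maximum GPA iterations.
#' @param project_tangent Apply orthogonal tangent-space projection after
#'   alignment (default TRUE).
#' @return An `aligned_faces` tibble: the input metadata, aligned
#'   coordinates, and a `centroid_size` column; the consensus, iteration
#'   trace and provenance flags are attached as attributes.
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100, project_tangent = TRUE) {
  s <- shape_matrix(data)
  n <- nrow(s)
  k <- ncol(s) / 2
  if (n < 2) abort("GPA needs at least 2 configurations")
  if (k < 3) abort("GPA needs at least 3 landmarks")

  xi <- seq(1, 2 * k, by = 2)
  yi <- xi + 1
  ## translate: centroid to origin
  s[, xi] <- s[, xi] - rowMeans(s[, xi, drop = FALSE])
  s[, yi] <- s[, yi] - rowMeans(s[, yi, drop = FALSE])
  ## scale: unit centroid size
  cs <- sqrt(rowSums(s^2))
  if (any(cs < .Machine$double.eps)) {
    abort(paste0("zero centroid size for row(s): ",
                 paste(which(cs < .Machine$double.eps), collapse = ", ")))
  }
  s <- s / cs

  cons <- s[1, ]
  cons <- cons / vec_norm(cons)
  ss_trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rotate_rows_to(s, cons)
    new_cons <- colMeans(s)  # rows are centered, so the mean is too
    new_cons <- new_cons / vec_norm(new_cons)
    ss_trace <- c(ss_trace, sum(sweep(s, 2, new_cons)^2))
    delta <- sqrt(mean((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("GPA did not converge in ", max_iter,
                 " iterations (last consensus RMS change ",
                 format(delta), ")"))
  }
  if (project_tangent) {
    proj <- as.vector(s %*% cons)
    s <- s - outer(proj - 1, cons)
  }

  out <- set_coords(tibble::as_tibble(as.data.frame(data)), s)
  out$centroid_size <- cs
  as_aligned(
    out,
    consensus = cons,
    template = attr(data, "template"),
    provenance = list(
      slid = FALSE, symmetrized = FALSE,
      residualized_on = character(0),
      tangent_projected = project_tangent
    ),
    iterations = it,
    ss_trace = ss_trace
  )
}

as_aligned <- function(data, consensus, template = NULL, provenance = NULL,
                       iterations = NA_integer_, ss_trace = NULL) {
  attr(data, "consensus") <- consensus
  attr(data, "template") <- template
  attr(data, "provenance") <- provenance %||% list(
    slid = FALSE, symmetrized = FALSE,
    residualized_on = character(0), tangent_projected = FALSE
  )
  attr(data, "iterations") <- iterations
  attr(data, "ss_trace") <- ss_trace
  class(data) <- unique(c("aligned_faces", class(data)))
  data
}

#' Consensus (mean) shape of an aligned dataset
#' @param aligned An `aligned_faces` tibble.
#' @return A flat 2k numeric vector.
#' @export
consensus_shape <- function(aligned) {
  attr(aligned, "consensus") %||% colMeans(shape_matrix(aligned))
}

#' Procrustes distance between two aligned shape vectors
#'
#' Euclidean norm of the difference of two flat shape vectors in a common
#' aligned frame.
#'
#' @param a,b Flat shape vectors of equal length.
#' @return A non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  if (length(a) != length(b)) abort("shape vectors differ in length")
  vec_norm(a - b)
}

#' Flag shape outliers by distance to the consensus
#'
#' Specimens whose Procrustes distance to the consensus exceeds
#' Q3 + multiplier * IQR of the distance distribution are flagged —
#' the usual screen for gross digitizing errors.
#'
#' @param aligned An `aligned_faces` tibble.
#' @param multiplier IQR multiplier (default 1.5).
#' @return A tibble with columns `id` and `distance` of flagged specimens
#'   (possibly empty).
#' @export
detect_outliers <- function(aligned, multiplier = 1.5) {
  s <- shape_matrix(aligned)
  cons <- consensus_shape(aligned)
  d <- sqrt(rowSums(sweep(s, 2, cons)^2))
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + multiplier * (q[2] - q[1])
  flag <- d > thr
  tibble::tibble(
    id = if ("id" %in% names(aligned)) as.character(aligned$id)[flag] else which(flag),
    distance = d[flag]
  )
}

#' Persist / restore an aligned dataset
#'
#' The aligned shapes go to a wide CSV (id + metadata + coordinates +
#' centroid size) and the consensus/provenance to a JSON sidecar
#' (`<path>.json`).
#'
#' @param aligned An `aligned_faces` tibble.
#' @param path CSV path.
#' @export
write_aligned <- function(aligned, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(aligned)), path)
  side <- list(
    consensus = as.numeric(consensus_shape(aligned)),
    provenance = attr(aligned, "provenance"),
    iterations = attr(aligned, "iterations")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aligned
#' @export
read_aligned <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  as_aligned(
    data,
    consensus = as.numeric(side$consensus),
    provenance = side$provenance,
    iterations = side$iterations
  )
}
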