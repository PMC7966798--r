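#' Bilateral symmetrization of aligned shapes
#'
#' Each specimen is reflected (x negated), its left/right landmark labels
#' swapped, the reflected copy rotated back onto the original by ordinary
#' Procrustes alignment, and the two configurations averaged. Because
#' reflect-relabel followed by a fixed rotation is a linear involution, the
#' average is an exact fixed point: the output is exactly bilaterally
#' symmetric (to machine precision) and symmetrization is idempotent.
#'
#' @param aligned An `aligned_faces` tibble from [gpa()].
#' @param template A [landmark_template()] declaring `bilateral_pairs` and
#'   `midline` (together covering every landmark).
#' @return The symmetrized `aligned_faces` tibble (unit centroid size,
#'   consensus recomputed, provenance flag `symmetrized` set).
#' @export
symmetrize <- function(aligned, template = NULL) {
  template <- template %||% attr(aligned, "template")
  if (is.null(template)) abort("no template supplied or attached")
  if (is.null(template$bilateral_pairs) || is.null(template$midline)) {
    abort("template must declare bilateral_pairs and midline for symmetrization")
  }
  pairs <- template$bilateral_pairs
  k <- template$n_landmarks
  perm <- seq_len(k)
  perm[pairs[, 1]] <- pairs[, 2]
  perm[pairs[, 2]] <- pairs[, 1]

  s <- shape_matrix(aligned)
  if (ncol(s) != 2 * k) abort("template landmark count does not match data")
  for (i in seq_len(nrow(s))) {
    x <- as_config(s[i, ])
    x <- centered_rows(x)
    xr <- x[perm, , drop = FALSE]
    xr[, 1] <- -xr[, 1]
    r <- optimal_rotation(xr, x)
    z <- (x + xr %*% r) / 2
    cs <- centroid_size(z)
    if (cs < .Machine$double.eps) abort("degenerate symmetrized shape")
    s[i, ] <- as_flat(z / cs)
  }
  cons <- colMeans(s)
  cons <- cons / vec_norm(cons)
  prov <- attr(aligned, "provenance")
  prov$symmetrized <- TRUE
  out <- set_coords(tibble::as_tibble(as.data.frame(aligned)), s)
  as_aligned(out, consensus = cons, template = template, provenance = prov,
             iterations = attr(aligned, "iterations"))
}

#' Deviation of a shape from exact bilateral symmetry
#'
#' Reflects and relabels the configuration, aligns the copy back onto the
#' original, and returns the Procrustes distance between the two. Zero for
#' an exactly symmetric shape.
#'
#' @param flat Flat 2k shape vector.
#' @param template A [landmark_template()] with bilateral pairs.
#' @return A non-negative number.
#' @export
asymmetry <- function(flat, template) {
  pairs <- template$bilateral_pairs
  k <- template$n_landmarks
  perm <- seq_len(k)
  perm[pairs[, 1]] <- pairs[, 2]
  perm[pairs[, 2]] <- pairs[, 1]
  x <- centered_rows(as_config(flat))
  xr <- x[perm, , drop = FALSE]
  xr[, 1] <- -xr[, 1]
  r <- optimal_rotation(xr, x)
  vec_norm(as_flat(x - xr %*% r))
}
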