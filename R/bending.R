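#' Thin-plate-spline bending energy matrix
#'
#' The k x k quadratic form measuring the non-affine part of a landmark
#' displacement field relative to a reference configuration: the upper-left
#' block of the inverse of the TPS system matrix L built from the kernel
#' U(r) = r^2 log(r^2). It is symmetric, positive semi-definite, and
#' annihilates affine displacement fields. Semilandmark sliding minimizes
#' this form.
#'
#' @param reference k x 2 reference configuration (no duplicate points).
#' @return A k x k matrix.
#' @export
bending_energy_matrix <- function(reference) {
  p <- as.matrix(reference)
  k <- nrow(p)
  d2 <- as.matrix(stats::dist(p))^2
  dup <- which(d2 < 1e-24 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(dup)) {
    abort(paste0(
      "duplicate landmarks in reference (singular TPS kernel): pair ",
      dup[1, 1], ",", dup[1, 2]
    ))
  }
  kk <- ifelse(d2 > 0, d2 * log(d2), 0)
  q <- cbind(1, p)
  l <- rbind(cbind(kk, q), cbind(t(q), matrix(0, 3, 3)))
  linv <- tryCatch(solve(l), error = function(e) {
    abort("TPS system matrix is singular (degenerate reference)")
  })
  b <- linv[seq_len(k), seq_len(k), drop = FALSE]
  (b + t(b)) / 2
}

#' Bending energy of a displacement field
#'
#' @param be k x k bending energy matrix from [bending_energy_matrix()].
#' @param displacement k x 2 matrix of landmark displacements.
#' @return A non-negative number (up to numerical noise).
#' @export
bending_energy <- function(be, displacement) {
  d <- as.matrix(displacement)
  sum(d[, 1] * (be %*% d[, 1])) + sum(d[, 2] * (be %*% d[, 2]))
}

#' Slide semilandmarks by the minimum bending energy criterion
#'
#' For each specimen, each semilandmark is displaced along its local curve
#' tangent (the normalized chord between its two flanking points on the
#' specimen) by the amount that jointly minimizes the TPS bending energy of
#' the specimen relative to the consensus. After each sliding pass the
#' dataset is re-superimposed and the consensus updated.
#'
#' @param aligned An `aligned_faces` tibble from [gpa()].
#' @param template A [landmark_template()] with curves and semilandmarks.
#' @param iterations Number of outer slide-then-realign passes (default 3).
#' @param ridge Tiny diagonal added to the sliding system for numerical
#'   safety.
#' @return The slid `aligned_faces` tibble; attribute `energy_trace` holds
#'   a tibble of total bending energy before/after each pass.
#' @export
slide_semilandmarks <- function(aligned, template, iterations = 3,
                                ridge = 1e-12) {
  template <- template %||% attr(aligned, "template")
  if (is.null(template)) abort("no template supplied or attached")
  semis <- template$semilandmarks
  if (!length(semis)) abort("template declares no semilandmarks")
  nb <- semilandmark_neighbours(template)
  s <- shape_matrix(aligned)
  n <- nrow(s)
  k <- ncol(s) / 2
  cons <- consensus_shape(aligned)
  m <- length(semis)
  trace_before <- trace_after <- numeric(0)
  prev_after <- Inf
  snapshot <- NULL

  for (pass in seq_len(iterations)) {
    snapshot <- list(s = s, cons = cons)
    cref <- as_config(cons)
    be <- bending_energy_matrix(cref)
    e_before <- 0
    e_after <- 0
    for (i in seq_len(n)) {
      x <- as_config(s[i, ])
      d <- x - cref
      e_before <- e_before + bending_energy(be, d)
      ## unit tangents from the specimen's flanking points
      tg <- matrix(0, m, 2)
      for (u in seq_len(m)) {
        pair <- nb[[as.character(semis[u])]]
        v <- x[pair[2], ] - x[pair[1], ]
        nv <- vec_norm(v)
        if (nv < .Machine$double.eps) abort("coincident curve neighbours")
        tg[u, ] <- v / nv
      }
      bss <- be[semis, semis, drop = FALSE]
      h <- bss * tcrossprod(tg)         # B[s_u,s_v] * (t_u . t_v)
      bdx <- be %*% d[, 1]
      bdy <- be %*% d[, 2]
      g <- tg[, 1] * bdx[semis] + tg[, 2] * bdy[semis]
      a <- tryCatch(
        solve(h + diag(ridge, m), -g),
        error = function(e) rep(0, m)
      )
      x[semis, ] <- x[semis, ] + a * tg
      e_after <- e_after + bending_energy(be, x - cref)
      s[i, ] <- as_flat(x)
    }
    ## a pass is accepted only while it lowers the total bending energy;
    ## once the re-superimposed configuration stops improving on the
    ## previous pass minimum the procedure has converged
    if (e_after > prev_after) {
      s <- snapshot$s
      cons <- snapshot$cons
      break
    }
    trace_before <- c(trace_before, e_before)
    trace_after <- c(trace_after, e_after)
    prev_after <- e_after
    ## re-superimpose: recenter, rescale, rotate to updated consensus
    s <- renormalize_rows(s)
    s <- rotate_rows_to(s, cons)
    for (j in 1:20) {
      new_cons <- colMeans(s)
      new_cons <- new_cons / vec_norm(new_cons)
      s <- rotate_rows_to(s, new_cons)
      if (sqrt(mean((new_cons - cons)^2)) < 1e-12) {
        cons <- new_cons
        break
      }
      cons <- new_cons
    }
  }

  prov <- attr(aligned, "provenance")
  prov$slid <- TRUE
  tangent <- isTRUE(prov$tangent_projected)
  if (tangent) {
    proj <- as.vector(s %*% cons)
    s <- s - outer(proj - 1, cons)
  }
  out <- set_coords(tibble::as_tibble(as.data.frame(aligned)), s)
  out <- as_aligned(out, consensus = cons, template = template,
                    provenance = prov,
                    iterations = attr(aligned, "iterations"))
  attr(out, "energy_trace") <- tibble::tibble(
    pass = seq_along(trace_after),
    energy_before = trace_before,
    energy_after = trace_after
  )
  out
}

## recenter each flat row and rescale to unit centroid size
renormalize_rows <- function(s) {
  k <- ncol(s) / 2
  xi <- seq(1, 2 * k, by = 2)
  yi <- xi + 1
  s[, xi] <- s[, xi] - rowMeans(s[, xi, drop = FALSE])
  s[, yi] <- s[, yi] - rowMeans(s[, yi, drop = FALSE])
  s / sqrt(rowSums(s^2))
}
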