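## Internal helpers shared across modules.
##
## Shape data travels in tibbles whose coordinate columns are named
## x1, y1, x2, y2, ... (flat order), one row per specimen. These helpers
## move between that layout and plain matrices.

coord_names <- function(k) {
  as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
}

#' Extract the coordinate block of a shape tibble as a matrix
#'
#' @param data A data frame with coordinate columns `x1, y1, ..., xk, yk`.
#' @return An n x 2k numeric matrix in flat order, rownames taken from an
#'   `id` column when present.
#' @export
shape_matrix <- function(data) {
  k <- n_landmarks_of(data)
  m <- as.matrix(data[coord_names(k)])
  if ("id" %in% names(data)) rownames(m) <- as.character(data$id)
  storage.mode(m) <- "double"
  m
}

n_landmarks_of <- function(data) {
  xs <- grep("^x[0-9]+$", names(data), value = TRUE)
  k <- length(xs)
  if (k == 0) abort("no coordinate columns (x1, y1, ...) found")
  need <- coord_names(k)
  if (!all(need %in% names(data))) {
    abort("coordinate columns are incomplete: expected x1..y" %+% k)
  }
  k
}

`%+%` <- function(a, b) paste0(a, b)

## flat 2k vector <-> k x 2 matrix
as_config <- function(flat) matrix(flat, ncol = 2, byrow = TRUE)
as_flat <- function(points) as.vector(t(points))

set_coords <- function(data, m) {
  k <- ncol(m) / 2
  data[coord_names(k)] <- as.data.frame(m, col.names = coord_names(k))
  data
}

shapes_tibble <- function(m, id = NULL) {
  k <- ncol(m) / 2
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- coord_names(k)
  if (!is.null(id)) out <- tibble::add_column(out, id = as.character(id), .before = 1)
  out
}

check_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  s[s %in% c("f", "female", "w", "woman")] <- "female"
  s[s %in% c("m", "male", "man")] <- "male"
  bad <- !(s %in% c("female", "male")) & !is.na(s)
  if (any(bad)) {
    abort(paste0(
      "unknown sex token(s): ",
      paste(unique(sex[bad]), collapse = ", ")
    ))
  }
  factor(s, levels = c("female", "male"))
}

## group means of rows of a matrix, returned as a matrix with one row per level
group_row_means <- function(m, g) {
  g <- factor(g)
  sums <- rowsum(m, g)
  sweep(sums, 1, as.vector(table(g)), "/")
}

centered_rows <- function(m) sweep(m, 2, colMeans(m), "-")

vec_norm <- function(v) sqrt(sum(v^2))

## seed helper: everything stochastic funnels through this so a single
## integer seed makes a whole analysis reproducible
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
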