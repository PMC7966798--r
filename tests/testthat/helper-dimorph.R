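# shared fixtures, all generated in code

## build a tibble with coordinate columns from an n x 2k matrix
shape_tbl <- function(m, ...) {
  k <- ncol(m) / 2
  cn <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
  coords <- tibble::as_tibble(as.data.frame(m))
  names(coords) <- cn
  meta <- tibble::tibble(...)
  if (ncol(meta) == 0) coords else dplyr::bind_cols(meta, coords)
}

## random centered k x 2 configuration
random_config <- function(k, sd = 1) {
  m <- matrix(rnorm(2 * k, sd = sd), k, 2)
  sweep(m, 2, colMeans(m))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2, byrow = TRUE)
}

## apply a random similarity transform to a k x 2 configuration
random_similarity <- function(cfg) {
  th <- runif(1, 0, 2 * pi)
  sc <- exp(runif(1, log(0.3), log(3)))
  tr <- runif(2, -5, 5)
  out <- sc * cfg %*% rot2(th)
  out[, 1] <- out[, 1] + tr[1]
  out[, 2] <- out[, 2] + tr[2]
  out
}

flat <- function(cfg) as.vector(t(cfg))
unflat <- function(v) matrix(v, ncol = 2, byrow = TRUE)

## toy 6-landmark bilateral template: pairs (1,2), (3,4); midline 5, 6
toy_bilateral_template <- function() {
  landmark_template(
    n_landmarks = 6,
    bilateral_pairs = rbind(c(1, 2), c(3, 4)),
    midline = c(5, 6)
  )
}

## symmetric 6-landmark configuration for the toy template
toy_symmetric_config <- function() {
  rbind(
    c(-1, 0.5), c(1, 0.5),
    c(-0.6, -0.7), c(0.6, -0.7),
    c(0, 1), c(0, -1)
  )
}
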