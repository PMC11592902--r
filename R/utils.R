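# small shared helpers

#' Evaluate code under a temporary RNG seed, restoring global RNG state
#' @keywords internal
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-item seed from a dataset seed and item coordinates
#'
#' Multiplicative integer hash, stable across platforms and generation order;
#' result lies in 1..(2^31 - 2).
#' @keywords internal
#' @export
derive_seed <- function(seed, a, b = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m) * 48271 %% m
  h <- (h + (as.numeric(a) + 1) * 69621) %% m
  h <- (h * 16807 + (as.numeric(b) + 1) * 49297) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Largest-remainder apportionment of n items into fractions
#'
#' Ties in the fractional remainders are broken toward earlier positions in
#' `fractions` (train > val > test order for splits).
#' @param n total count
#' @param fractions numeric vector summing to 1
#' @return integer vector summing to n
#' @keywords internal
#' @export
largest_remainder <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions > 0))
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Bilinear resize of a numeric matrix
#' @keywords internal
bilinear_resize <- function(img, H, W) {
  h0 <- nrow(img); w0 <- ncol(img)
  if (h0 == H && w0 == W) return(img)
  # map output pixel centres onto input pixel-centre coordinates
  ry <- (seq_len(H) - 0.5) * h0 / H + 0.5 - 0.5
  rx <- (seq_len(W) - 0.5) * w0 / W + 0.5 - 0.5
  y0 <- pmin(pmax(floor(ry), 1), h0); y1 <- pmin(y0 + 1, h0)
  x0 <- pmin(pmax(floor(rx), 1), w0); x1 <- pmin(x0 + 1, w0)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx)
  a <- a + img[y1, x0, drop = FALSE] * outer(wy, 1 - wx)
  a <- a + img[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  a + img[y1, x1, drop = FALSE] * outer(wy, wx)
}

#' Sample a matrix at arbitrary (possibly fractional) coordinates, bilinear,
#' clamped at the border
#' @keywords internal
bilinear_sample <- function(img, ys, xs) {
  h0 <- nrow(img); w0 <- ncol(img)
  ys <- pmin(pmax(ys, 1), h0)
  xs <- pmin(pmax(xs, 1), w0)
  y0 <- pmin(floor(ys), h0 - 1); y1 <- y0 + 1
  x0 <- pmin(floor(xs), w0 - 1); x1 <- x0 + 1
  if (h0 == 1) { y0 <- y1 <- rep(1, length(ys)) }
  if (w0 == 1) { x0 <- x1 <- rep(1, length(xs)) }
  wy <- ys - y0; wx <- xs - x0
  v00 <- img[cbind(y0, x0)]; v10 <- img[cbind(y1, x0)]
  v01 <- img[cbind(y0, x1)]; v11 <- img[cbind(y1, x1)]
  v00 * (1 - wy) * (1 - wx) + v10 * wy * (1 - wx) +
    v01 * (1 - wy) * wx + v11 * wy * wx
}

#' He-style normal initialisation matrix, deterministic given seed
#' @keywords internal
init_mat <- function(nr, nc, seed, sd = sqrt(2 / nr)) {
  with_seed(seed, matrix(stats::rnorm(nr * nc, sd = sd), nr, nc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
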