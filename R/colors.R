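# Exact, vectorised RGB <-> HSV conversions.
#
# grDevices converts HSV through 8-bit colour strings, which quantises
# values; texture composition needs bit-exact round trips, so the
# conversions are implemented directly and tested against grDevices.

#' Convert RGB to HSV
#'
#' @param m numeric matrix with columns r, g, b in `[0, 1]` (a single
#'   colour may be given as a length-3 vector).
#' @return matrix with columns h (in `[0, 1)`), s, v.
#' @export
rgb_to_hsv_mat <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  stopifnot(ncol(m) == 3, all(m >= 0 & m <= 1))
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v == 0, 0, d / v)
  h <- numeric(length(v))
  nz <- d > 0
  rmax <- nz & v == r
  gmax <- nz & !rmax & v == g
  bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g[rmax] - b[rmax]) / d[rmax]) %% 6
  h[gmax] <- (b[gmax] - r[gmax]) / d[gmax] + 2
  h[bmax] <- (r[bmax] - g[bmax]) / d[bmax] + 4
  cbind(h = h / 6, s = s, v = v)
}

#' Convert HSV to RGB
#'
#' @param m numeric matrix with columns h, s, v (h taken modulo 1).
#' @return matrix with columns r, g, b in `[0, 1]`.
#' @export
hsv_to_rgb_mat <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  stopifnot(ncol(m) == 3)
  h <- (m[, 1] %% 1) * 6
  s <- m[, 2]; v <- m[, 3]
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    idx <- i == k
    if (!any(idx)) next
    ch <- switch(k + 1L,
      list(v, t, p), list(q, v, p), list(p, v, t),
      list(p, q, v), list(t, p, v), list(v, p, q))
    r[idx] <- ch[[1]][idx]; g[idx] <- ch[[2]][idx]; b[idx] <- ch[[3]][idx]
  }
  cbind(r = r, g = g, b = b)
}
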