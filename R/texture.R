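# Procedural snake-texture synthesis: smoothed-noise binary patterns,
# boundary detection, edge-enhancement fields and colour composition.

#' Texture synthesis parameters
#'
#' @param width,height raster size in pixels. The default 1024 x 128
#'   raster is mapped along the snake body.
#' @param sigma Gaussian smoothing scale in pixels (default 33).
#' @param threshold binarisation level in `(0, 1)`; values `>= threshold`
#'   map to 1 (default 0.5).
#' @param enh_amplitude peak luminance offset of the enhancement ramp in
#'   value-channel units, in `[0, 0.25]` (default 0.25).
#' @param enh_width ramp extent in pixels (default 10): the gradient
#'   spans distances 0 to `enh_width` from the nearest edge.
#' @param seed integer seed for the noise stage.
#' @return a list of class `camo_texture_params`.
#' @export
texture_params <- function(width = 1024, height = 128, sigma = 33,
                           threshold = 0.5, enh_amplitude = 0.25,
                           enh_width = 10, seed = 1) {
  stopifnot(sigma > 0, threshold > 0, threshold < 1,
            enh_amplitude >= 0, enh_amplitude <= 0.25, enh_width >= 1,
            width >= 1, height >= 1)
  structure(list(width = width, height = height, sigma = sigma,
                 threshold = threshold, enh_amplitude = enh_amplitude,
                 enh_width = enh_width, seed = seed),
            class = "camo_texture_params")
}

# Reflective-boundary Gaussian smoothing matrix for a length-n signal.
# Row i holds the kernel centred at i with out-of-range taps reflected
# back into [1, n]; rows sum to 1 exactly.
gauss_smooth_matrix <- function(n, sigma) {
  r <- ceiling(4 * sigma)
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    # reflect indices about the boundaries (symmetric padding)
    j <- abs(j - 1) %% (2 * n - 2) + 1
    j[j > n] <- 2 * n - j[j > n]
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
  }
  K / rowSums(K)
}

# small cache: the same (n, sigma) matrices recur across textures
.smooth_cache <- new.env(parent = emptyenv())
smooth_matrix_cached <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  if (is.null(.smooth_cache[[key]])) {
    .smooth_cache[[key]] <- gauss_smooth_matrix(n, sigma)
  }
  .smooth_cache[[key]]
}

#' Generate a binary blob pattern from smoothed noise
#'
#' I.i.d. uniform noise on `[0, 1]` is smoothed with a Gaussian kernel
#' (reflective boundaries) and binarised at the threshold; values at
#' exactly the threshold map to 1.
#'
#' @param params a [texture_params()] object.
#' @param noise optional height x width noise matrix, bypassing the
#'   random stage (used for testing the downstream stages).
#' @return integer matrix (height x width) of 0/1 labels.
#' @export
make_binary_pattern <- function(params, noise = NULL) {
  stopifnot(inherits(params, "camo_texture_params"))
  if (params$width < params$sigma || params$height < params$sigma) {
    warning("raster smaller than one smoothing scale; pattern degenerate")
  }
  if (is.null(noise)) {
    noise <- with_seed(params$seed,
                       matrix(runif(params$width * params$height),
                              params$height, params$width))
  }
  stopifnot(nrow(noise) == params$height, ncol(noise) == params$width)
  Kr <- smooth_matrix_cached(params$height, params$sigma)
  Kc <- smooth_matrix_cached(params$width, params$sigma)
  sm <- Kr %*% noise %*% t(Kc)
  m <- matrix(0L, params$height, params$width)
  # the tolerance keeps values at exactly the threshold on the 1 side
  # despite convolution roundoff (measure zero for continuous noise)
  m[sm >= params$threshold - 1e-9] <- 1L
  m
}

#' Locate boundary pixels of a binary map
#'
#' A pixel is an edge pixel if any of its 4-connected neighbours has the
#' opposite label; both sides of each label change are returned, so each
#' region owns its own enhancement ramp. On binary input this is the
#' exact morphological equivalent of Canny edge localisation.
#'
#' @param binary_map integer 0/1 matrix.
#' @return logical matrix of the same size, TRUE at edge pixels.
#' @export
locate_edges <- function(binary_map) {
  stopifnot(all(binary_map %in% c(0L, 1L)))
  m <- binary_map
  nr <- nrow(m); nc <- ncol(m)
  e <- matrix(FALSE, nr, nc)
  if (nr > 1) {
    d <- m[-1, , drop = FALSE] != m[-nr, , drop = FALSE]
    e[-nr, ] <- e[-nr, ] | d
    e[-1, ] <- e[-1, ] | d
  }
  if (nc > 1) {
    d <- m[, -1, drop = FALSE] != m[, -nc, drop = FALSE]
    e[, -nc] <- e[, -nc] | d
    e[, -1] <- e[, -1] | d
  }
  e
}

#' Compute the signed edge-enhancement field
#'
#' Each pixel within `width` (Euclidean distance to the nearest edge
#' pixel) receives magnitude `amplitude * (1 - d / width)`; the sign is
#' positive on the lighter (label 1) side and negative on the darker
#' (label 0) side, so the light region lightens and the dark region
#' darkens towards their shared boundary. Pixels at distance `>= width`
#' are exactly 0.
#'
#' @param binary_map integer 0/1 matrix.
#' @param edges logical edge matrix from [locate_edges()]; recomputed if
#'   missing.
#' @param amplitude peak magnitude (default 0.25).
#' @param width ramp extent in pixels (default 10).
#' @return signed numeric matrix in `[-amplitude, amplitude]`.
#' @export
enhancement_field <- function(binary_map, edges = NULL, amplitude = 0.25,
                              width = 10) {
  if (is.null(edges)) edges <- locate_edges(binary_map)
  stopifnot(identical(dim(edges), dim(binary_map)))
  if (!any(edges)) return(matrix(0, nrow(binary_map), ncol(binary_map)))
  d <- cpp_edt(edges)
  mag <- amplitude * pmax(0, 1 - d / width)
  mag * ifelse(binary_map == 1L, 1, -1)
}

#' Compose a snake texture from a binary pattern and two base colours
#'
#' The binary pattern is painted with the dark/light colour pair; with
#' enhancement, the signed enhancement field is added to the HSV value
#' channel (hue and saturation untouched) and the result converted back
#' to RGB. Because both base colours satisfy `0.25 < v < 0.75`, the
#' value channel never leaves `[0, 1]`.
#'
#' @param params a [texture_params()] object.
#' @param colors a `camo_colorpair` from [select_base_colors()].
#' @param enhanced logical: apply edge enhancement?
#' @param binary_map optional precomputed pattern (else generated from
#'   `params`).
#' @return an object of class `camo_texture`: list with `binary_map`,
#'   `colors`, `enhancement` (signed field, identically 0 when
#'   `enhanced = FALSE`), `rgb` (height x width x 3 array) and
#'   `enhanced`.
#' @export
compose_texture <- function(params, colors, enhanced = FALSE,
                            binary_map = NULL) {
  stopifnot(inherits(params, "camo_texture_params"),
            inherits(colors, "camo_colorpair"))
  for (side in list(colors$dark, colors$light)) {
    if (!(side$v > 0.25 && side$v < 0.75)) {
      stop("base colours must satisfy 0.25 < v < 0.75")
    }
  }
  if (colors$dark$v >= colors$light$v) stop("dark colour must be darker")
  if (is.null(binary_map)) binary_map <- make_binary_pattern(params)
  h <- ifelse(binary_map == 1L, colors$light$h, colors$dark$h)
  s <- ifelse(binary_map == 1L, colors$light$s, colors$dark$s)
  v <- ifelse(binary_map == 1L, colors$light$v, colors$dark$v)
  enh <- if (enhanced) {
    enhancement_field(binary_map, amplitude = params$enh_amplitude,
                      width = params$enh_width)
  } else {
    matrix(0, nrow(binary_map), ncol(binary_map))
  }
  v <- v + enh
  rgb <- hsv_to_rgb_mat(cbind(as.vector(h), as.vector(s), as.vector(v)))
  dimr <- c(nrow(binary_map), ncol(binary_map))
  structure(list(binary_map = binary_map, colors = colors,
                 enhancement = enh,
                 rgb = array(rgb, dim = c(dimr, 3)),
                 enhanced = enhanced, params = params),
            class = "camo_texture")
}

#' @export
print.camo_texture <- function(x, ...) {
  cat(sprintf("<camo_texture> %dx%d, %s\n", ncol(x$binary_map),
              nrow(x$binary_map),
              if (x$enhanced) "edge-enhanced" else "unenhanced"))
  invisible(x)
}

#' Export an enhancement field as CSV
#'
#' @param texture a `camo_texture`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enhancement_csv <- function(texture, path) {
  write.csv(texture$enhancement, path, row.names = FALSE)
  invisible(path)
}
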