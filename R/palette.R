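# Natural-colour palette: synthetic forest sampling, CSV loading, and
# base-colour selection for snake textures.

#' Construct a palette object
#'
#' A palette is an ordered collection of colour samples, each carrying
#' its RGB reflectance in `[0, 1]` and the exact HSV conversion.
#'
#' @param rgb numeric matrix with columns r, g, b in `[0, 1]`.
#' @param provenance `"synthetic"` or `"file"`.
#' @return an object of class `camo_palette`: a list with `samples`
#'   (data.frame with columns r, g, b, h, s, v) and `provenance`.
#' @export
camo_palette <- function(rgb, provenance = c("synthetic", "file")) {
  provenance <- match.arg(provenance)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  if (ncol(rgb) != 3 || any(!is.finite(rgb)) || any(rgb < 0 | rgb > 1)) {
    stop("palette RGB values must be a 3-column matrix within [0, 1]")
  }
  hsv <- rgb_to_hsv_mat(rgb)
  samples <- data.frame(r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                        h = hsv[, 1], s = hsv[, 2], v = hsv[, 3])
  structure(list(samples = samples, provenance = provenance),
            class = "camo_palette")
}

#' @export
print.camo_palette <- function(x, ...) {
  cat(sprintf("<camo_palette> %d samples (%s)\n", nrow(x$samples),
              x$provenance))
  invisible(x)
}

#' Generate a synthetic forest-colour palette
#'
#' Emulates sampling RGB triplets from below-horizon regions of forest
#' scenes: a fixed number of scene groups, each contributing the same
#' number of random samples. Hue mass is concentrated in the
#' green/yellow/brown bands, saturation straddles 0.3 and value spans a
#' broad range, so the downstream luminance/saturation filters always
#' retain usable colours. Group-level hue/value offsets emulate
#' scene-to-scene differences (deciduous vs coniferous stands).
#'
#' @param n_groups number of scene groups (default 8).
#' @param n_per_group samples per group (default 100).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a [camo_palette()] with `n_groups * n_per_group` samples.
#' @export
generate_synthetic_palette <- function(n_groups = 8, n_per_group = 100,
                                       seed = 1) {
  stopifnot(n_groups >= 1, n_per_group >= 1)
  hsv <- with_seed(seed, {
    out <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      hue_shift <- rnorm(1, 0, 0.02)
      val_shift <- rnorm(1, 0, 0.05)
      n <- n_per_group
      green <- runif(n) < 0.55
      h <- ifelse(green, rnorm(n, 0.26, 0.05), rnorm(n, 0.10, 0.04))
      h <- (h + hue_shift) %% 1
      s <- 0.05 + 0.9 * rbeta_local(n, 2, 2)
      v <- pmin(0.98, pmax(0.02, rbeta_local(n, 2.2, 2.8) + val_shift))
      out[[g]] <- cbind(h, s, v)
    }
    do.call(rbind, out)
  })
  camo_palette(hsv_to_rgb_mat(hsv), provenance = "synthetic")
}

# rbeta without importing extra stats symbols into docs
rbeta_local <- function(n, a, b) stats::rbeta(n, a, b)

#' Load a palette from a CSV of RGB triplets
#'
#' The file must contain three numeric columns (header optional).
#' Values on a 0-255 scale are auto-detected (any value above 1) and
#' rescaled to `[0, 1]`.
#'
#' @param path CSV file path.
#' @return a [camo_palette()] with provenance `"file"`.
#' @export
load_palette_csv <- function(path) {
  raw <- tryCatch(read.csv(path, header = FALSE, strip.white = TRUE),
                  error = function(e) stop("cannot parse palette CSV: ",
                                           conditionMessage(e)))
  # tolerate a single header line of non-numeric labels
  first <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  if (all(is.na(first))) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) != 3) stop("palette CSV must have exactly 3 columns")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), ncol = 3))
  bad <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    stop(sprintf("malformed palette row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  mx <- max(m)
  if (mx > 1) m <- m / if (mx <= 255) 255 else mx
  camo_palette(pmin(pmax(m, 0), 1), provenance = "file")
}

# rank percentile of each element: (rank - 0.5) / n * 100, ties by order
centile_rank <- function(v) {
  (rank(v, ties.method = "first") - 0.5) / length(v) * 100
}

#' Select the two snake base colours from a palette
#'
#' Applies the luminance filter (keep `0.25 < v < 0.75`, strict) and the
#' saturation filter (keep `s > 0.3`), then draws one colour uniformly
#' from each of two centile bands of the filtered value distribution:
#' the 10th-45th centiles (dark) and the 55th-90th centiles (light).
#' Band membership uses rank percentiles `(rank - 0.5) / n * 100` with
#' inclusive bounds; ties are broken by sample order.
#'
#' @param palette a [camo_palette()].
#' @param seed integer seed for the random draws.
#' @return a list of class `camo_colorpair` with elements `dark` and
#'   `light`, each a one-row data.frame (r, g, b, h, s, v), ordered so
#'   that `dark$v < light$v`.
#' @export
select_base_colors <- function(palette, seed = 1) {
  stopifnot(inherits(palette, "camo_palette"))
  s <- palette$samples
  keep <- s$v > 0.25 & s$v < 0.75 & s$s > 0.3
  f <- s[keep, , drop = FALSE]
  if (nrow(f) < 2) {
    stop("palette too restrictive: fewer than 2 samples pass the ",
         "luminance/saturation filters")
  }
  ctl <- centile_rank(f$v)
  low <- which(ctl >= 10 & ctl <= 45)
  high <- which(ctl >= 55 & ctl <= 90)
  if (!length(low) || !length(high)) {
    stop("palette too restrictive: empty centile band after filtering")
  }
  idx <- with_seed(seed, c(low[sample.int(length(low), 1)],
                           high[sample.int(length(high), 1)]))
  pair <- f[idx, , drop = FALSE]
  pair <- pair[order(pair$v), , drop = FALSE]
  if (pair$v[1] == pair$v[2]) {
    stop("selected colours have identical luminance; supply a palette ",
         "with more luminance spread")
  }
  structure(list(dark = pair[1, , drop = FALSE],
                 light = pair[2, , drop = FALSE]),
            class = "camo_colorpair")
}

#' @export
print.camo_colorpair <- function(x, ...) {
  cat(sprintf("<camo_colorpair> dark v=%.3f, light v=%.3f\n",
              x$dark$v, x$light$v))
  invisible(x)
}
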