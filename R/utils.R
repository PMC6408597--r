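# misc internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library calls never disturb user-level streams.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds (< 2^31) from a master seed
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Convert between visual angle and metric size
#'
#' Uses the exact relation `size = 2 * distance * tan(theta / 2)` for a
#' frontoparallel extent centred on the line of sight.
#'
#' @param deg angular extent in degrees.
#' @param cm metric extent in cm.
#' @param distance viewing distance in cm (default 57).
#' @return the converted extent.
#' @export
deg_to_cm <- function(deg, distance = 57) {
  2 * distance * tan(deg / 2 * pi / 180)
}

#' @rdname deg_to_cm
#' @export
cm_to_deg <- function(cm, distance = 57) {
  2 * atan(cm / (2 * distance)) * 180 / pi
}

#' Write an RGB image as plain-text PPM (P3)
#'
#' @param img numeric array `[rows, cols, 3]` with values in `[0, 1]`.
#' @param path output file path.
#' @param maxval maximum sample value (default 255).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  # interleave channels row-major
  px <- aperm(q, c(3, 2, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  writeLines(paste(as.integer(px), collapse = " "), con)
  invisible(path)
}
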