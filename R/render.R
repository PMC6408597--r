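# Stereo rendering of scene layouts: z-buffer rasterisation with
# Lambertian Gouraud shading, height-field cast shadows, ground-truth
# masks, depth and disparity, and anaglyph export.

#' Camera rig description
#'
#' Two virtual cameras 6.5 cm apart, 57 cm from the image plane (the
#' ground plane); the stimulus window subtends 39.64 x 28.74 degrees.
#' `res_scale` multiplies the pixel raster while keeping the field
#' fixed, for sub-percent geometric measurements.
#'
#' @param ipd inter-camera separation in cm (default 6.5).
#' @param distance eye to image plane in cm (default 57).
#' @param image_px pixel raster (width, height), default 1200 x 870.
#' @param field_deg angular window (width, height) in degrees.
#' @param mode `"stereoscopic"` or `"monoscopic"`.
#' @param res_scale integer raster multiplier (default 1).
#' @return a list of class `camo_rig`.
#' @export
camera_rig <- function(ipd = 6.5, distance = 57, image_px = c(1200, 870),
                       field_deg = c(39.64, 28.74),
                       mode = c("stereoscopic", "monoscopic"),
                       res_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(ipd > 0, distance > 0, all(image_px >= 1), all(field_deg > 0))
  structure(list(ipd = ipd, distance = distance,
                 image_px = as.integer(round(image_px * res_scale)),
                 field_deg = field_deg, mode = mode),
            class = "camo_rig")
}

#' Illumination model
#'
#' Ambient: light emitted uniformly from the upper hemisphere,
#' approximated by a cosine-weighted term with no cast shadows.
#' Directional: a collimated source (default 45 degrees elevation, 350
#' degrees azimuth) with per-pixel cast shadows and a small ambient
#' floor. Azimuth is measured clockwise from the +Y (screen-up) axis
#' seen from above, so 350 places the light slightly left of up and
#' shadows fall down-right.
#'
#' @param kind `"ambient"` or `"directional"`.
#' @param elevation,azimuth light direction in degrees (directional).
#' @param ambient_floor residual illumination inside shadows (default
#'   0.15).
#' @return a list of class `camo_light`; `casts_shadows` is TRUE iff
#'   directional.
#' @export
light_model <- function(kind = c("ambient", "directional"), elevation = 45,
                        azimuth = 350, ambient_floor = 0.15) {
  kind <- match.arg(kind)
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  horiz <- c(sin(az), cos(az))
  dir <- c(horiz * cos(el), sin(el))
  structure(list(kind = kind, elevation = elevation, azimuth = azimuth,
                 dir = dir, horiz = horiz, ambient_floor = ambient_floor,
                 casts_shadows = kind == "directional"),
            class = "camo_light")
}

# half-extents of the image-plane window in cm
rig_window <- function(rig) {
  c(rig$distance * tan(rig$field_deg[1] / 2 * pi / 180),
    rig$distance * tan(rig$field_deg[2] / 2 * pi / 180))
}

# Assemble the full scene mesh (ground + leaves + snake) in world
# coordinates. Object ids: 1 ground, 2 leaves, 3 snake.
scene_mesh <- function(layout) {
  p <- layout$params
  hw <- p$bounds[1] / 2 * 1.4; hh <- p$bounds[2] / 2 * 1.4
  V <- rbind(c(-hw, -hh, 0), c(hw, -hh, 0), c(hw, hh, 0), c(-hw, hh, 0))
  F <- rbind(c(1, 2, 3), c(1, 3, 4))
  C <- matrix(rep(p$ground_color, each = 4), 4, 3)
  N <- matrix(rep(c(0, 0, 1), each = 4), 4, 3)
  obj <- c(1L, 1L)
  nL <- nrow(layout$leaves)
  if (nL > 0) {
    tmpl <- build_leaf_mesh(p$leaf_major, p$leaf_minor, p$leaf_thickness,
                            p$leaf_curl)
    nv <- nrow(tmpl$V); nf <- nrow(tmpl$F)
    lv <- layout$leaves
    ct <- cos(lv$rot); st <- sin(lv$rot)
    # replicate template across instances (vectorised transform)
    vx <- rep(tmpl$V[, 1], nL); vy <- rep(tmpl$V[, 2], nL)
    vz <- rep(tmpl$V[, 3], nL)
    ict <- rep(ct, each = nv); ist <- rep(st, each = nv)
    # sheets render at their top surface (rest + thickness + curl) so a
    # ground-level leaf never z-fights the background plane
    Vl <- cbind(vx * ict - vy * ist + rep(lv$x, each = nv),
                vx * ist + vy * ict + rep(lv$y, each = nv),
                vz + rep(lv$rest, each = nv) + p$leaf_thickness)
    nx <- rep(tmpl$N[, 1], nL); ny <- rep(tmpl$N[, 2], nL)
    Nl <- cbind(nx * ict - ny * ist, nx * ist + ny * ict,
                rep(tmpl$N[, 3], nL))
    Cl <- cbind(rep(lv$r, each = nv), rep(lv$g, each = nv),
                rep(lv$b, each = nv))
    Fl <- tmpl$F[rep(seq_len(nf), nL), ] +
      rep((seq_len(nL) - 1L) * nv, each = nf) + nrow(V)
    obj <- c(obj, rep(2L, nf * nL))
    V <- rbind(V, Vl); F <- rbind(F, Fl); C <- rbind(C, Cl)
    N <- rbind(N, Nl)
  }
  if (!is.null(layout$snake)) {
    sn <- layout$snake
    m <- sn$mesh
    xy <- pose_transform(m$V[, 1:2, drop = FALSE], sn$rot, c(sn$x, sn$y))
    # 20 um contact lift so the belly ring never z-fights its support
    Vs <- cbind(xy, m$V[, 3] + sn$rest + 0.002)
    nxy <- pose_transform(m$N[, 1:2, drop = FALSE], sn$rot, c(0, 0))
    Ns <- cbind(nxy, m$N[, 3])
    Fs <- m$F + nrow(V)
    obj <- c(obj, rep(3L, nrow(m$F)))
    V <- rbind(V, Vs); F <- rbind(F, Fs); C <- rbind(C, m$C)
    N <- rbind(N, Ns)
  }
  list(V = V, F = F, C = C, N = N, obj = obj)
}

#' Render one view of a layout
#'
#' Perspective projection through the given optical centre onto the
#' ground-plane window, hidden surfaces removed by depth, Lambertian
#' shading interpolated between vertices; under directional light each
#' pixel is tested for shadow by marching the height field towards the
#' light.
#'
#' @param layout a `camo_layout`.
#' @param eye optical centre `c(x, y, z)` in cm; defaults to the
#'   cyclopean point of `rig`.
#' @param light a [light_model()].
#' @param rig a [camera_rig()].
#' @return list with `rgb` (H x W x 3), `depth` (cm from the eye along
#'   the viewing axis; NA off-geometry), `obj` (0 none, 1 ground,
#'   2 leaf, 3 snake) and `mask` (logical snake mask).
#' @export
render_view <- function(layout, eye = NULL, light = light_model(),
                        rig = camera_rig()) {
  stopifnot(inherits(layout, "camo_layout"), inherits(light, "camo_light"))
  if (is.null(eye)) eye <- c(0, 0, rig$distance)
  win <- rig_window(rig)
  mesh <- scene_mesh(layout)
  hf <- layout$height_field
  res <- cpp_render(mesh$V, mesh$F, mesh$C, mesh$N, mesh$obj, eye,
                    win[1], win[2], rig$image_px[1], rig$image_px[2],
                    if (light$kind == "ambient") 0L else 1L, light$dir,
                    light$ambient_floor, light$casts_shadows, hf,
                    -layout$params$bounds[1] / 2,
                    -layout$params$bounds[2] / 2, layout$params$cell,
                    tan(light$elevation * pi / 180), light$horiz[1],
                    light$horiz[2], 0.03)
  rgb <- array(0, dim = c(rig$image_px[2], rig$image_px[1], 3))
  rgb[, , 1] <- res$r; rgb[, , 2] <- res$g; rgb[, , 3] <- res$b
  list(rgb = rgb, depth = res$depth, obj = res$obj, mask = res$obj == 3L)
}

#' Analytic disparity from depth
#'
#' Signed horizontal disparity in degrees for a point at the given
#' depth (cm from the eyes): the difference between the vergence angle
#' at that depth and at the fixation (image-plane) distance. Crossed
#' disparities (nearer than fixation) are positive.
#'
#' @param depth depth values in cm (vector/matrix).
#' @param rig a [camera_rig()].
#' @return disparity in degrees, same shape as `depth`.
#' @export
disparity_from_depth <- function(depth, rig = camera_rig()) {
  (2 * atan((rig$ipd / 2) / depth) -
     2 * atan((rig$ipd / 2) / rig$distance)) * 180 / pi
}

#' Render a full trial (stereo pair plus ground truth)
#'
#' Stereoscopic mode renders left/right views from eyes offset by
#' half the inter-camera distance about the cyclopean point, plus the
#' cyclopean view for ground truth; monoscopic mode renders the
#' cyclopean view once and duplicates it.
#'
#' @param layout a `camo_layout` (with the snake placed, normally).
#' @param rig a [camera_rig()].
#' @param light a [light_model()].
#' @return object of class `camo_render`: list with `left`, `right`
#'   (H x W x 3 RGB), `masks` (list cyclopean/left/right), `depth`
#'   (cyclopean, cm), `disparity` (degrees), `rig`, `light`.
#' @export
render_trial <- function(layout, rig = camera_rig(), light = light_model()) {
  D <- rig$distance
  cyc <- render_view(layout, c(0, 0, D), light, rig)
  if (rig$mode == "monoscopic") {
    left <- right <- cyc
  } else {
    left <- render_view(layout, c(-rig$ipd / 2, 0, D), light, rig)
    right <- render_view(layout, c(rig$ipd / 2, 0, D), light, rig)
  }
  structure(list(left = left$rgb, right = right$rgb,
                 masks = list(cyclopean = cyc$mask, left = left$mask,
                              right = right$mask),
                 depth = cyc$depth,
                 disparity = disparity_from_depth(cyc$depth, rig),
                 rig = rig, light = light),
            class = "camo_render")
}

#' @export
print.camo_render <- function(x, ...) {
  cat(sprintf("<camo_render> %dx%d px, %s, %s light\n",
              x$rig$image_px[1], x$rig$image_px[2], x$rig$mode,
              x$light$kind))
  invisible(x)
}

#' Build a red/green anaglyph from a stereo render
#'
#' Left-image luminance is routed to the red channel and right-image
#' luminance to the green channel (blue zero), for viewing with
#' red-green glasses.
#'
#' @param output a `camo_render`.
#' @return H x W x 3 RGB array.
#' @export
make_anaglyph <- function(output) {
  stopifnot(inherits(output, "camo_render"))
  lum <- function(img) {
    0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  d <- dim(output$left)
  array(c(lum(output$left), lum(output$right),
          matrix(0, d[1], d[2])), dim = d)
}

#' Measure the angular extent of a mask's major axis
#'
#' Finds the mask's extreme pixels along its longer image dimension and
#' converts the pixel span to degrees through the exact tangent mapping
#' of the rig (outer pixel boundaries, i.e. extreme centres +- half a
#' pixel).
#'
#' @param mask logical matrix (H x W).
#' @param rig the [camera_rig()] used for the render.
#' @return angular extent in degrees.
#' @export
mask_angular_extent <- function(mask, rig = camera_rig()) {
  stopifnot(any(mask))
  win <- rig_window(rig)
  idx <- which(mask, arr.ind = TRUE)
  px_deg <- function(p, n, half) {
    x <- p / n * 2 * half - half
    atan(x / rig$distance) * 180 / pi
  }
  spans <- c(
    px_deg(max(idx[, 2]), rig$image_px[1], win[1]) -
      px_deg(min(idx[, 2]) - 1, rig$image_px[1], win[1]),
    px_deg(max(idx[, 1]), rig$image_px[2], win[2]) -
      px_deg(min(idx[, 1]) - 1, rig$image_px[2], win[2]))
  max(spans)
}
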