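# Metric 3-D scene composition: leaf and snake meshes, and a
# deterministic height-field stacking model standing in for rigid-body
# physics. World units are cm; the ground plane is z = 0 and the camera
# axis is +z, so "up" (out of the litter, towards the viewer) is +z.

#' Scene composition parameters
#'
#' Defaults follow the study geometry at a 57 cm viewing distance:
#' the background subtends 39.64 x 28.74 degrees, each leaf
#' 1.10 x 0.50 x 0.02 degrees, and leaves stack up to 1.5 cm.
#'
#' @param bounds XY extents of the background plane in cm
#'   (width, height).
#' @param cell height-field raster resolution in cm (default 0.1, i.e.
#'   1 mm).
#' @param max_stack maximum leaf stack height in cm (default 1.5).
#' @param leaf_major,leaf_minor,leaf_thickness leaf extents in cm.
#' @param leaf_curl out-of-plane curl depth in cm applied orthogonally
#'   to the leaf's long axis (default 0.08).
#' @param drop_z range of initial leaf drop heights in cm (metadata in
#'   the stacking model, retained for provenance).
#' @param snake_drop_z initial snake drop height in cm (metadata).
#' @param ground_color RGB of the brown background plane.
#' @return a list of class `camo_scene_params`.
#' @export
scene_params <- function(bounds = c(deg_to_cm(39.64), deg_to_cm(28.74)),
                         cell = 0.1, max_stack = 1.5,
                         leaf_major = deg_to_cm(1.10),
                         leaf_minor = deg_to_cm(0.50),
                         leaf_thickness = deg_to_cm(0.02),
                         leaf_curl = 0.08,
                         drop_z = c(5, 7), snake_drop_z = 12,
                         ground_color = c(0.30, 0.22, 0.12)) {
  stopifnot(length(bounds) == 2, all(bounds > 0), cell > 0, max_stack > 0)
  structure(list(bounds = bounds, cell = cell, max_stack = max_stack,
                 leaf_major = leaf_major, leaf_minor = leaf_minor,
                 leaf_thickness = leaf_thickness, leaf_curl = leaf_curl,
                 drop_z = drop_z, snake_drop_z = snake_drop_z,
                 ground_color = ground_color),
            class = "camo_scene_params")
}

# cubic Bezier in one parameter
bezier3 <- function(t, p0, p1, p2, p3) {
  (1 - t)^3 * p0 + 3 * t * (1 - t)^2 * p1 + 3 * t^2 * (1 - t) * p2 +
    t^3 * p3
}

#' Per-vertex normals from face geometry
#'
#' Area-weighted average of incident face normals.
#'
#' @param V vertex matrix (n x 3).
#' @param F face index matrix (m x 3, 1-based).
#' @return unit normal matrix (n x 3); isolated vertices get (0, 0, 1).
#' @export
vertex_normals <- function(V, F) {
  N <- matrix(0, nrow(V), 3)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # orient all face normals upwards (single-sheet surfaces lit from above)
  flip <- fn[, 3] < 0
  fn[flip, ] <- -fn[flip, ]
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], F[, k], sum)
      N[as.integer(names(acc)), c] <- N[as.integer(names(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  zero <- len < 1e-12
  N[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  len[zero] <- 1
  N / len
}

#' Build a leaf mesh
#'
#' The planar outline is a cubic Bezier half-profile mirrored about the
#' long axis; the sheet is then curled orthogonally to the long axis
#' (parabolic cross-section of depth `curl`). The mesh is a single top
#' surface; the nominal thickness participates in stacking.
#'
#' @param major,minor leaf extents in cm (long/short axis).
#' @param thickness nominal thickness in cm (stacking only).
#' @param curl curl depth in cm; 0 gives a planar leaf.
#' @param color RGB triplet in `[0, 1]`.
#' @param n_u,n_v grid resolution along/across the long axis (`n_v` odd).
#' @param control 4 x 2 matrix of Bezier control points in normalised
#'   (along, halfwidth) space; the first and last must lie on the axis.
#' @return a list of class `camo_mesh` with `V`, `F`, `N`, `color`,
#'   plus leaf metadata.
#' @export
build_leaf_mesh <- function(major = deg_to_cm(1.10),
                            minor = deg_to_cm(0.50),
                            thickness = deg_to_cm(0.02), curl = 0.08,
                            color = c(0.3, 0.4, 0.2), n_u = 12, n_v = 7,
                            control = rbind(c(0, 0), c(0.2, 1),
                                            c(0.8, 1), c(1, 0))) {
  stopifnot(major > 0, minor > 0, thickness > 0, curl >= 0)
  t <- seq(0, 1, length.out = n_u)
  xb <- bezier3(t, control[1, 1], control[2, 1], control[3, 1], control[4, 1])
  wb <- bezier3(t, control[1, 2], control[2, 2], control[3, 2], control[4, 2])
  if (max(wb) <= 0 || any(diff(xb) < 0)) {
    stop("degenerate Bezier control points for leaf outline")
  }
  wb <- wb / max(wb) * minor / 2
  v <- seq(-1, 1, length.out = n_v)
  X <- outer(xb - 0.5, rep(1, n_v)) * major
  Y <- outer(wb, v)
  Z <- matrix(rep(curl * v^2, each = n_u), n_u, n_v)
  V <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  F <- grid_faces(n_u, n_v)
  mesh <- list(V = V, F = F, N = vertex_normals(V, F), color = color,
               major = major, minor = minor, thickness = thickness,
               curl = curl)
  class(mesh) <- "camo_mesh"
  mesh
}

# triangulate an n_u x n_v vertex grid stored column-major by v
grid_faces <- function(n_u, n_v) {
  out <- matrix(0L, 2 * (n_u - 1) * (n_v - 1), 3)
  k <- 1L
  for (j in seq_len(n_v - 1)) {
    for (i in seq_len(n_u - 1)) {
      a <- (j - 1L) * n_u + i
      b <- a + 1L
      c <- a + n_u
      d <- c + 1L
      out[k, ] <- c(a, b, d); out[k + 1L, ] <- c(a, d, c)
      k <- k + 2L
    }
  }
  out
}

# radial scale of the snake cross-section along the body: slightly
# wider head, tapering (but not pointed) tail, constant central body
snake_profile <- function(u) {
  s <- rep(1, length(u))
  head <- u < 0.12
  s[head] <- 0.45 + 0.70 * sqrt(u[head] / 0.12)
  hump <- u >= 0.12 & u < 0.2
  s[hump] <- 1.15 - 0.15 * (u[hump] - 0.12) / 0.08
  tail <- u > 0.8
  s[tail] <- 1 - 0.82 * ((u[tail] - 0.8) / 0.2)^1.2
  s
}

#' Build a snake mesh
#'
#' An elliptical cross-section (constant over the central body, widened
#' head, tapering tail) swept along a straight axis, with the texture
#' mapped along the body: texture columns follow the body axis and rows
#' wrap around the cross-section.
#'
#' @param length,width,height body extents in cm; defaults subtend
#'   4.00 x 0.40 x 0.02 degrees at 57 cm.
#' @param texture optional `camo_texture` supplying vertex colours.
#' @param n_u,n_phi sweep resolution along the body / around the
#'   cross-section.
#' @return a `camo_mesh` with per-vertex colours (`C`).
#' @export
build_snake_mesh <- function(length = deg_to_cm(4.00),
                             width = deg_to_cm(0.40),
                             height = deg_to_cm(0.02), texture = NULL,
                             n_u = 80, n_phi = 12) {
  stopifnot(length > 0, width > 0, height > 0)
  u <- seq(0, 1, length.out = n_u)
  s <- snake_profile(u)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  a <- width / 2; b <- height / 2
  X <- outer((u - 0.5) * length, rep(1, n_phi))
  Y <- outer(a * s, cos(phi))
  Z <- outer(b * s, 1 + sin(phi))
  V <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  # closed tube: grid faces along u, wrap in phi
  Fo <- grid_faces(n_u, n_phi)
  wrap <- matrix(0L, 2 * (n_u - 1), 3)
  k <- 1L
  for (i in seq_len(n_u - 1)) {
    a1 <- (n_phi - 1L) * n_u + i
    b1 <- a1 + 1L
    c1 <- i
    d1 <- i + 1L
    wrap[k, ] <- c(a1, b1, d1); wrap[k + 1L, ] <- c(a1, d1, c1)
    k <- k + 2L
  }
  F <- rbind(Fo, wrap)
  # vertex colours from the texture: column ~ u, row ~ phi
  if (!is.null(texture)) {
    tw <- ncol(texture$binary_map); th <- nrow(texture$binary_map)
    cols <- pmin(tw, pmax(1, round(u * (tw - 1)) + 1))
    rows <- pmin(th, pmax(1, round((phi / (2 * pi)) * (th - 1)) + 1))
    C <- matrix(0, n_u * n_phi, 3)
    for (ci in 1:3) {
      C[, ci] <- as.vector(outer(cols, rows,
        function(cc, rr) texture$rgb[cbind(rr, cc, ci)]))
    }
  } else {
    C <- matrix(0.5, n_u * n_phi, 3)
  }
  # true outward normals for a closed tube (not upward-flipped)
  N <- tube_normals(V, F)
  mesh <- list(V = V, F = F, N = N, C = C, length = length, width = width,
               height = height)
  class(mesh) <- "camo_mesh"
  mesh
}

# outward normals for the snake tube: average face normals oriented
# away from the local axis point
tube_normals <- function(V, F) {
  N <- matrix(0, nrow(V), 3)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], F[, k], sum)
      N[as.integer(names(acc)), c] <- N[as.integer(names(acc)), c] + acc
    }
  }
  # orient away from the body axis (axis at y = 0, z = mean z per ring)
  out_dir <- cbind(0, V[, 2], V[, 3] - mean(V[, 3]))
  flip <- rowSums(N * out_dir) < 0
  N[flip, ] <- -N[flip, ]
  len <- sqrt(rowSums(N^2))
  zero <- len < 1e-12
  N[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  len[zero] <- 1
  N / len
}

# rotate local xy by theta and translate
pose_transform <- function(xy, theta, centre) {
  ct <- cos(theta); st <- sin(theta)
  cbind(xy[, 1] * ct - xy[, 2] * st + centre[1],
        xy[, 1] * st + xy[, 2] * ct + centre[2])
}

# Footprint sample points of a leaf in local coordinates (finer than
# the mesh so every height-field cell under the leaf is hit).
leaf_footprint <- function(params, n_u = 26, n_v = 15) {
  t <- seq(0, 1, length.out = n_u)
  xb <- bezier3(t, 0, 0.2, 0.8, 1)
  wb <- bezier3(t, 0, 1, 1, 0)
  wb <- wb / max(wb) * params$leaf_minor / 2
  v <- seq(-1, 1, length.out = n_v)
  list(x = as.vector(outer(xb - 0.5, rep(1, n_v))) * params$leaf_major,
       y = as.vector(outer(wb, v)),
       ztop = as.vector(matrix(rep(params$leaf_curl * v^2, each = n_u),
                               n_u, n_v)) + params$leaf_thickness)
}

# map world xy to 1-based height-field cells; drops points off-field
field_cells <- function(x, y, bounds, cell) {
  ix <- floor((x + bounds[1] / 2) / cell) + 1L
  iy <- floor((y + bounds[2] / 2) / cell) + 1L
  nx <- ceiling(bounds[1] / cell); ny <- ceiling(bounds[2] / cell)
  ok <- ix >= 1L & iy >= 1L & ix <= nx & iy <= ny
  list(ix = ix[ok], iy = iy[ok], ok = ok)
}

# Sequentially stack leaf poses onto a height field; returns the field
# and per-leaf resting heights. The running field holds top surfaces;
# each leaf rests flat at the running maximum under its footprint,
# capped so the stack never exceeds max_stack.
stack_leaf_poses <- function(poses, params) {
  nx <- ceiling(params$bounds[1] / params$cell)
  ny <- ceiling(params$bounds[2] / params$cell)
  field <- matrix(0, nx, ny)
  n <- nrow(poses)
  rest <- numeric(n)
  if (n > 0) {
    fp <- leaf_footprint(params)
    top_local <- max(fp$ztop)
    for (i in seq_len(n)) {
      xy <- pose_transform(cbind(fp$x, fp$y), poses$rot[i],
                           c(poses$x[i], poses$y[i]))
      cc <- field_cells(xy[, 1], xy[, 2], params$bounds, params$cell)
      if (!length(cc$ix)) next
      r <- cpp_footprint_max(field, cc$ix, cc$iy)
      r <- max(0, min(r, params$max_stack - top_local))
      rest[i] <- r
      cpp_footprint_raise(field, cc$ix, cc$iy, fp$ztop[cc$ok], r)
    }
  }
  list(field = field, rest = rest)
}

#' Drop leaves onto the background plane
#'
#' Leaves are placed sequentially: each samples an XY position uniform
#' within the bounds, a Z rotation uniform in `[0, 2pi)` and an initial
#' drop height (metadata), then rests flat at the running maximum of
#' the height field under its footprint, capped so the stack never
#' exceeds `max_stack`. Colours are sampled from the palette.
#'
#' @param n number of leaves (the study uses 4500; smaller values give
#'   fast test scenes).
#' @param params a [scene_params()] object.
#' @param palette a [camo_palette()] supplying leaf colours.
#' @param seed integer seed; layouts are bit-reproducible.
#' @return an object of class `camo_layout`: list with `params`,
#'   `leaves` (data.frame x, y, z0, rot, rest, r, g, b), `height_field`
#'   (matrix, x along rows), `snake` (NULL until [place_snake()]) and
#'   `seed`.
#' @export
drop_leaves <- function(n, params = scene_params(),
                        palette = generate_synthetic_palette(), seed = 1) {
  stopifnot(n >= 0, inherits(params, "camo_scene_params"))
  if (any(params$bounds <= 0)) stop("zero-area bounds")
  poses <- with_seed(seed, {
    data.frame(
      x = runif(n, -params$bounds[1] / 2, params$bounds[1] / 2),
      y = runif(n, -params$bounds[2] / 2, params$bounds[2] / 2),
      z0 = runif(n, params$drop_z[1], params$drop_z[2]),
      rot = runif(n, 0, 2 * pi),
      color_idx = if (n > 0) sample.int(nrow(palette$samples), n,
                                        replace = TRUE) else integer(0))
  })
  st <- stack_leaf_poses(poses, params)
  leaves <- cbind(poses[, c("x", "y", "z0", "rot")], rest = st$rest,
                  palette$samples[poses$color_idx, c("r", "g", "b"),
                                  drop = FALSE])
  rownames(leaves) <- NULL
  structure(list(params = params, leaves = leaves,
                 height_field = st$field, snake = NULL, seed = seed),
            class = "camo_layout")
}

#' @export
print.camo_layout <- function(x, ...) {
  cat(sprintf("<camo_layout> %d leaves, stack max %.2f cm, snake: %s\n",
              nrow(x$leaves), max(x$height_field),
              if (is.null(x$snake)) "none" else "placed"))
  invisible(x)
}

#' Place the snake target in a layout
#'
#' The snake samples an XY position and Z rotation (uniform), rests on
#' the maximum of the height field under its footprint, and is added to
#' the height field so it casts and receives shadows. When `quadrant`
#' is given, the body centroid is constrained to that quadrant (the
#' head/tail may cross the midlines); the body must fit within the
#' bounds.
#'
#' @param layout a `camo_layout` from [drop_leaves()].
#' @param snake a `camo_mesh` from [build_snake_mesh()].
#' @param seed integer seed.
#' @param quadrant optional `"TL"`, `"TR"`, `"BL"` or `"BR"`.
#' @param position,rotation optional fixed pose overriding the random
#'   draw (used for calibration scenes).
#' @return the layout with `snake` set (list: mesh, x, y, rot, rest).
#' @export
place_snake <- function(layout, snake = build_snake_mesh(), seed = 1,
                        quadrant = NULL, position = NULL, rotation = NULL) {
  stopifnot(inherits(layout, "camo_layout"), inherits(snake, "camo_mesh"))
  b <- layout$params$bounds
  if (snake$length > min(b)) stop("snake longer than scene bounds")
  pose <- with_seed(seed, {
    rot <- if (is.null(rotation)) runif(1, 0, 2 * pi) else rotation
    if (is.null(position)) {
      hx <- abs(cos(rot)) * snake$length / 2 + abs(sin(rot)) * snake$width / 2
      hy <- abs(sin(rot)) * snake$length / 2 + abs(cos(rot)) * snake$width / 2
      xr <- c(-b[1] / 2 + hx, b[1] / 2 - hx)
      yr <- c(-b[2] / 2 + hy, b[2] / 2 - hy)
      if (!is.null(quadrant)) {
        qx <- switch(quadrant, TL = , BL = c(-b[1] / 2, 0),
                     TR = , BR = c(0, b[1] / 2))
        qy <- switch(quadrant, TL = , TR = c(0, b[2] / 2),
                     BL = , BR = c(-b[2] / 2, 0))
        xr <- c(max(xr[1], qx[1]), min(xr[2], qx[2]))
        yr <- c(max(yr[1], qy[1]), min(yr[2], qy[2]))
      }
      if (xr[1] >= xr[2] || yr[1] >= yr[2]) {
        stop("snake does not fit the requested quadrant within bounds")
      }
      c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]), rot)
    } else {
      c(position[1], position[2], rot)
    }
  })
  xy <- pose_transform(snake$V[, 1:2, drop = FALSE], pose[3], pose[1:2])
  cc <- field_cells(xy[, 1], xy[, 2], b, layout$params$cell)
  rest <- if (length(cc$ix)) {
    cpp_footprint_max(layout$height_field, cc$ix, cc$iy)
  } else 0
  field <- layout$height_field + 0  # private copy before in-place raise
  if (length(cc$ix)) {
    cpp_footprint_raise(field, cc$ix, cc$iy, snake$V[cc$ok, 3], rest)
  }
  layout$height_field <- field
  layout$snake <- list(mesh = snake, x = pose[1], y = pose[2],
                       rot = pose[3], rest = rest)
  layout
}

#' Serialise a layout to JSON
#'
#' Writes element poses, colours, parameters and seeds; the height
#' field is reconstructed deterministically on read by replaying the
#' stacking, so any rendering is reproducible from the file alone.
#'
#' @param layout a `camo_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  snake <- layout$snake
  obj <- list(
    params = unclass(layout$params),
    seed = layout$seed,
    leaves = layout$leaves,
    snake = if (!is.null(snake)) {
      list(x = snake$x, y = snake$y, rot = snake$rot,
           length = snake$mesh$length, width = snake$mesh$width,
           height = snake$mesh$height)
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout back from JSON
#'
#' @param path file written by [write_layout_json()].
#' @param snake_texture optional `camo_texture` to re-skin the snake.
#' @return a `camo_layout` with the height field rebuilt.
#' @export
read_layout_json <- function(path, snake_texture = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(scene_params,
                    obj$params[setdiff(names(obj$params), character(0))])
  leaves <- as.data.frame(obj$leaves)
  st <- stack_leaf_poses(leaves, params)
  layout <- structure(list(params = params,
                           leaves = cbind(leaves[, c("x", "y", "z0", "rot")],
                                          rest = st$rest,
                                          leaves[, c("r", "g", "b")]),
                           height_field = st$field, snake = NULL,
                           seed = obj$seed),
                      class = "camo_layout")
  if (!is.null(obj$snake)) {
    mesh <- build_snake_mesh(obj$snake$length, obj$snake$width,
                             obj$snake$height, texture = snake_texture)
    layout <- place_snake(layout, mesh, seed = 0,
                          position = c(obj$snake$x, obj$snake$y),
                          rotation = obj$snake$rot)
  }
  layout
}
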