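# shared fixtures: everything is generated in code at test time

# a colour pair with known HSV values (dark/light base colours)
make_pair <- function(vd = 0.35, vl = 0.65, h = 0.25, s = 0.6) {
  mk <- function(v) {
    rgb <- hsv_to_rgb_mat(c(h, s, v))
    data.frame(r = rgb[1], g = rgb[2], b = rgb[3], h = h, s = s, v = v)
  }
  structure(list(dark = mk(vd), light = mk(vl)), class = "camo_colorpair")
}

# palette built directly from chosen HSV rows
palette_from_hsv <- function(h, s, v) {
  camo_palette(hsv_to_rgb_mat(cbind(h, s, v)), provenance = "synthetic")
}

# small texture raster for fast tests
small_tp <- function(...) {
  texture_params(width = 160, height = 60, sigma = 12, ...)
}

# a layout with elements placed by hand (no random drop)
manual_layout <- function(leaves = NULL, params = scene_params()) {
  lay <- drop_leaves(0, params, generate_synthetic_palette(2, 10), seed = 1)
  if (!is.null(leaves)) {
    lay$leaves <- leaves
    st <- camosearch:::stack_leaf_poses(leaves, params)
    # keep caller-specified rest heights but refresh the height field
    fp <- camosearch:::leaf_footprint(params)
    nx <- nrow(lay$height_field); ny <- ncol(lay$height_field)
    field <- matrix(0, nx, ny)
    for (i in seq_len(nrow(leaves))) {
      xy <- camosearch:::pose_transform(cbind(fp$x, fp$y), leaves$rot[i],
                                        c(leaves$x[i], leaves$y[i]))
      cc <- camosearch:::field_cells(xy[, 1], xy[, 2], params$bounds,
                                     params$cell)
      camosearch:::cpp_footprint_raise(field, cc$ix, cc$iy,
                                       fp$ztop[cc$ok], leaves$rest[i])
    }
    lay$height_field <- field
  }
  lay
}

one_leaf_row <- function(x = 0, y = 0, rot = 0, rest = 0) {
  data.frame(x = x, y = y, z0 = 5, rot = rot, rest = rest,
             r = 0.3, g = 0.4, b = 0.2)
}

# small rig for fast renders
small_rig <- function(mode = "monoscopic", scale = 1) {
  camera_rig(image_px = c(400, 290), mode = mode, res_scale = scale)
}

# explicit contrast-coding oracle for the fully within 2x2x2 ANOVA:
# per-subject contrast scores L_i = sum_j c_j Y_ij give
# SS_eff = n * mean(L)^2 / sum(c^2), SS_err = sum((L - mean(L))^2) / sum(c^2)
anova_contrast_oracle <- function(Y) {
  lv <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  effs <- list(c("a"), c("b"), c("c"), c("a", "b"), c("a", "c"),
               c("b", "c"), c("a", "b", "c"))
  out <- t(vapply(effs, function(ef) {
    cvec <- Reduce(`*`, lapply(ef, function(e) lv[[e]]))
    L <- as.vector(Y %*% cvec)
    c(SS = nrow(Y) * mean(L)^2 / sum(cvec^2),
      SS_error = sum((L - mean(L))^2) / sum(cvec^2))
  }, numeric(2)))
  as.data.frame(out)
}
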