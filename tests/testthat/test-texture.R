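# texture synthesis: thresholding, edges, enhancement field, composition

test_that("threshold stage maps constants and the boundary value to 1", {
  tp <- small_tp()
  const <- matrix(0.6, tp$height, tp$width)
  expect_true(all(make_binary_pattern(tp, noise = const) == 1L))
  # smoothing preserves a constant exactly (rows of the kernel sum to 1),
  # so a constant at the threshold tests the boundary assignment
  at_thr <- matrix(0.5, tp$height, tp$width)
  expect_true(all(make_binary_pattern(tp, noise = at_thr) == 1L))
  below <- matrix(0.49, tp$height, tp$width)
  expect_true(all(make_binary_pattern(tp, noise = below) == 0L))
})

test_that("binary pattern is deterministic and balanced across seeds", {
  tp <- texture_params(seed = 5)
  expect_identical(make_binary_pattern(tp), make_binary_pattern(tp))
  fr <- vapply(1:24, function(s) {
    mean(make_binary_pattern(texture_params(seed = s)))
  }, numeric(1))
  # smoothed uniform noise is symmetric about 0.5; individual seeds vary
  # (the sigma=33 pattern has few independent blobs) but the mean is tight
  expect_true(all(fr > 0.1 & fr < 0.9))
  expect_gt(mean(fr), 0.35)
  expect_lt(mean(fr), 0.65)
})

test_that("degenerate raster warns", {
  expect_warning(make_binary_pattern(texture_params(width = 20, height = 8,
                                                    sigma = 12)),
                 "degenerate")
})

test_that("locate_edges matches the brute-force 4-neighbour oracle", {
  # straight boundary: the two abutting columns
  m <- cbind(matrix(0L, 8, 4), matrix(1L, 8, 4))
  e <- locate_edges(m)
  expect_true(all(e[, 4:5]))
  expect_false(any(e[, c(1:3, 6:8)]))
  # no edges in constant maps
  expect_false(any(locate_edges(matrix(1L, 6, 6))))
  expect_false(any(locate_edges(matrix(0L, 6, 6))))
  # random blob map vs exhaustive neighbour scan
  set.seed(9)
  tp <- small_tp(seed = 4)
  bm <- make_binary_pattern(tp)
  e <- locate_edges(bm)
  oracle <- matrix(FALSE, nrow(bm), ncol(bm))
  for (i in seq_len(nrow(bm))) {
    for (j in seq_len(ncol(bm))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && jj >= 1 && ii <= nrow(bm) && jj <= ncol(bm) &&
            bm[ii, jj] != bm[i, j]) {
          oracle[i, j] <- TRUE
        }
      }
    }
  }
  expect_identical(e, oracle)
})

test_that("distance transform matches a brute-force oracle", {
  set.seed(3)
  feat <- matrix(runif(12 * 9) < 0.15, 12, 9)
  feat[5, 4] <- TRUE  # ensure non-empty
  d <- camosearch:::cpp_edt(feat)
  idx <- which(feat, arr.ind = TRUE)
  for (i in 1:12) {
    for (j in 1:9) {
      expect_equal(d[i, j],
                   sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("enhancement field has the stated ramp geometry and signs", {
  # left half dark (0), right half light (1); edge at columns 30/31
  m <- cbind(matrix(0L, 20, 30), matrix(1L, 20, 30))
  f <- enhancement_field(m, amplitude = 0.25, width = 10)
  expect_equal(f[1, 31], 0.25)    # d = 0 on the light side
  expect_equal(f[1, 30], -0.25)   # d = 0 on the dark side
  expect_equal(f[5, 25], -0.125)  # d = 5, dark side: linear midpoint
  expect_equal(f[5, 36], 0.125)
  expect_equal(f[1, 20], 0)       # d = 10: ramp reaches exactly 0
  expect_true(all(f[, 1:20] == 0))  # beyond the ramp: exactly 0
  expect_true(all(f[, 41:60] == 0))
  expect_true(all(f[, 1:30] <= 0) && all(f[, 31:60] >= 0))
})

test_that("enhancement field is antisymmetric under label reflection", {
  tp <- small_tp(seed = 8)
  bm <- make_binary_pattern(tp)
  f1 <- enhancement_field(bm)
  f2 <- enhancement_field(1L - bm)
  expect_equal(f2, -f1)
})

test_that("constant maps yield an empty edge set and zero field", {
  m <- matrix(1L, 10, 10)
  expect_equal(enhancement_field(m), matrix(0, 10, 10))
})

test_that("composition: colour count, locality, amplitude, bit-exactness", {
  tp <- small_tp(seed = 2)
  pair <- make_pair()
  bm <- make_binary_pattern(tp)
  plain <- compose_texture(tp, pair, enhanced = FALSE, binary_map = bm)
  enh <- compose_texture(tp, pair, enhanced = TRUE, binary_map = bm)
  # unenhanced: exactly two distinct colours
  cols <- unique(matrix(plain$rgb, ncol = 3))
  expect_identical(nrow(cols), 2L)
  expect_true(all(plain$enhancement == 0))
  # pixels beyond the ramp identical between versions
  d <- camosearch:::cpp_edt(locate_edges(bm))
  far <- d >= tp$enh_width
  for (ch in 1:3) {
    expect_identical(enh$rgb[, , ch][far], plain$rgb[, , ch][far])
  }
  # max per-pixel |dV| equals the amplitude (brute-force comparison)
  v0 <- rgb_to_hsv_mat(matrix(plain$rgb, ncol = 3))[, 3]
  v1 <- rgb_to_hsv_mat(matrix(enh$rgb, ncol = 3))[, 3]
  expect_equal(max(abs(v1 - v0)), tp$enh_amplitude, tolerance = 1e-12)
  expect_true(all(v1 >= 0 & v1 <= 1))
  # zero-amplitude enhancement reproduces the base texture bit-exactly
  tp0 <- small_tp(seed = 2, enh_amplitude = 0)
  z <- compose_texture(tp0, pair, enhanced = TRUE, binary_map = bm)
  expect_identical(z$rgb, plain$rgb)
})

test_that("mean-luminance shift is bounded by amplitude x edge fraction", {
  tp <- small_tp(seed = 6)
  pair <- make_pair()
  bm <- make_binary_pattern(tp)
  plain <- compose_texture(tp, pair, enhanced = FALSE, binary_map = bm)
  enh <- compose_texture(tp, pair, enhanced = TRUE, binary_map = bm)
  v0 <- rgb_to_hsv_mat(matrix(plain$rgb, ncol = 3))[, 3]
  v1 <- rgb_to_hsv_mat(matrix(enh$rgb, ncol = 3))[, 3]
  zone <- mean(abs(enh$enhancement) > 0)
  expect_lte(abs(mean(v1) - mean(v0)), tp$enh_amplitude * zone + 1e-12)
})

test_that("colour pairs violating the invariants are rejected", {
  tp <- small_tp()
  expect_error(compose_texture(tp, make_pair(vd = 0.2, vl = 0.6)), "0.25")
  expect_error(compose_texture(tp, make_pair(vd = 0.6, vl = 0.4)), "darker")
})
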