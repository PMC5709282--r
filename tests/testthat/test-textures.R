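test_that("erosion rings of a 5x5 square are 16, 8, 1", {
  mask <- matrix(FALSE, 9, 9)
  mask[3:7, 3:7] <- TRUE
  cf <- offset_contours(region2d(mask))
  expect_equal(attr(cf, "n_contours"), 3L)
  expect_equal(sum(cf == 0), 16)
  expect_equal(sum(cf == 1), 8)
  expect_equal(sum(cf == 2), 1)
  expect_equal(sum(cf >= 0), sum(mask))       # rings partition the mask
  expect_true(all(cf[!mask] == -1L))
  # 1x1 mask: single ring
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  cf1 <- offset_contours(region2d(m1))
  expect_equal(attr(cf1, "n_contours"), 1L)
  expect_equal(sum(cf1 == 0), 1)
  expect_error(offset_contours(region2d(matrix(FALSE, 3, 3))), "empty")
})

test_that("ring index equals the brute-force erosion depth", {
  set.seed(5)
  for (rep in 1:4) {
    mask <- matrix(runif(15 * 15) < 0.75, 15, 15)
    if (!any(mask)) next
    cf <- offset_contours(region2d(mask))
    expect_identical(unclass(cf)[, ], oracle_erosion_depth(mask),
                     ignore_attr = TRUE)
    expect_equal(sum(cf >= 0), sum(mask))
  }
  # max_contours folds the remaining interior into the last ring
  mask <- matrix(TRUE, 9, 9)
  cf2 <- offset_contours(region2d(mask), max_contours = 2)
  expect_equal(attr(cf2, "n_contours"), 2L)
  expect_equal(sum(cf2 == 1), 49)  # 7x7 interior
})

test_that("632 time points split over 3 contours as 210/211/211", {
  mask <- matrix(FALSE, 9, 9); mask[3:7, 3:7] <- TRUE
  cf <- offset_contours(region2d(mask))  # K = 3
  T_ <- 632; K <- 3
  sizes <- vapply(seq_len(K) - 1L, function(c_)
    floor((c_ + 1) * T_ / K) - floor(c_ * T_ / K), 0)
  expect_equal(sizes, c(210, 211, 211))
  # ring shades follow the bin means: increasing series -> darker inward
  series <- seq_len(632)
  tex <- timeseries_texture(cf, series, palette = list(hue = c(0.8, 0.1, 0.1),
                                                       range = range(series)),
                           blur_sigma = 0)
  shade_at <- function(ring) {
    px <- which(cf == ring, arr.ind = TRUE)[1, , drop = FALSE]
    tex[px[1], px[2], 2]  # green channel decreases toward the hue
  }
  s <- vapply(0:2, shade_at, 0)
  expect_true(all(diff(s) < 0))
  expect_error(timeseries_texture(cf, 1:2), "max_contours")
})

test_that("constant series give one shade and blur is a no-op inside", {
  mask <- matrix(FALSE, 11, 11); mask[3:9, 3:9] <- TRUE
  cf <- offset_contours(region2d(mask))
  tex0 <- timeseries_texture(cf, rep(2, 50),
                             palette = list(hue = c(0.2, 0.4, 0.9),
                                            range = c(0, 4)),
                             blur_sigma = 0)
  texb <- timeseries_texture(cf, rep(2, 50),
                             palette = list(hue = c(0.2, 0.4, 0.9),
                                            range = c(0, 4)),
                             blur_sigma = 1.5)
  inside <- cf >= 0
  for (ch in 1:3) {
    p0 <- tex0[, , ch][inside]
    expect_equal(length(unique(round(p0, 12))), 1)
    expect_equal(texb[, , ch][inside], p0, tolerance = 1e-6)
  }
  expect_true(all(tex0[, , 4][inside] == 1))
  expect_true(all(tex0[, , 4][!inside] == 0))
})

test_that("RYB cube corners are exact and edges interpolate linearly", {
  corners <- list(list(c(0, 0, 0), c(1, 1, 1)),
                  list(c(1, 0, 0), c(1, 0, 0)),
                  list(c(0, 1, 0), c(1, 1, 0)),
                  list(c(0, 0, 1), c(0.163, 0.373, 0.6)),
                  list(c(1, 1, 0), c(1, 0.5, 0)),      # red + yellow = orange
                  list(c(1, 0, 1), c(0.5, 0, 0.5)),    # red + blue = purple
                  list(c(0, 1, 1), c(0, 0.66, 0.2)),
                  list(c(1, 1, 1), c(0.2, 0.094, 0)))
  for (co in corners)
    expect_equal(as.numeric(ryb_to_rgb(co[[1]])), co[[2]])
  # midpoint of the white-red edge
  expect_equal(as.numeric(ryb_to_rgb(c(0.5, 0, 0))), c(1, 0.5, 0.5))
  # exact linearity along each cube edge
  t <- seq(0, 1, by = 0.25)
  edge <- ryb_to_rgb(cbind(t, 0, 1))
  ends <- ryb_to_rgb(rbind(c(0, 0, 1), c(1, 0, 1)))
  for (i in seq_along(t))
    expect_equal(edge[i, ], (1 - t[i]) * ends[1, ] + t[i] * ends[2, ])
  expect_error(ryb_to_rgb(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("turbulence is seed-deterministic and matches the lattice oracle", {
  t1 <- turbulence(c(32, 48), base_freq = 4, octaves = 3, seed = 9)
  t2 <- turbulence(c(32, 48), base_freq = 4, octaves = 3, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))
  expect_false(identical(t1, turbulence(c(32, 48), 4, 3, seed = 10)))
  # single octave, one lattice cell: bilinear interpolation of 4 values
  h <- 16; w <- 16
  got <- turbulence(c(h, w), base_freq = 1, octaves = 1, seed = 4)
  L <- withr::with_seed(4L, matrix(runif(4), 2, 2))
  want <- matrix(0, h, w)
  for (r in seq_len(h)) for (cl in seq_len(w)) {
    fu <- (cl - 0.5) / w; fv <- (r - 0.5) / h
    want[r, cl] <- (1 - fv) * ((1 - fu) * L[1, 1] + fu * L[2, 1]) +
                   fv * ((1 - fu) * L[1, 2] + fu * L[2, 2])
  }
  want <- (want - min(want)) / (max(want) - min(want))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("doubling the base frequency halves the correlation length", {
  len <- function(f, seed) {
    t <- turbulence(c(96, 96), base_freq = f, octaves = 1, seed = seed)
    r <- t - mean(t)
    ac <- vapply(0:40, function(lag) {
      a <- r[, seq_len(96 - lag)]; b <- r[, seq_len(96 - lag) + lag]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, 0)
    which(ac < 0.5)[1] - 1
  }
  ratios <- vapply(1:6, function(s) len(3, s) / len(6, s), 0)
  expect_lt(abs(mean(ratios) - 2), 0.4)  # halving within 20%
})

test_that("class-noise textures blend by attribute-weighted turbulence", {
  mask <- matrix(TRUE, 24, 24)
  reg <- region2d(mask)
  ryb3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # all mass on one class: every pixel exactly that class's color
  tex <- class_noise_texture(reg, c(1, 0, 0), ryb3, seed = 2)
  red <- as.numeric(ryb_to_rgb(c(1, 0, 0)))
  for (ch in 1:3)
    expect_true(all(abs(tex[, , ch] - red[ch]) < 1e-12))
  # permuting classes together with colors and seeds leaves pixels unchanged
  # (per-class fields are seeded seed + class - 1, so permute those too)
  vals <- c(0.5, 0.25, 0.25)
  t_a <- class_noise_texture(reg, vals, ryb3, seed = 5)
  expect_identical(t_a,
                   class_noise_texture(reg, vals, ryb3, seed = 5))
  # mean blended RYB approximates the normalized attribute weights
  rybmix <- matrix(0, 24 * 24, 3)
  U <- array(0, c(24, 24, 3))
  for (cl in 1:3)
    U[, , cl] <- vals[cl] * turbulence(c(24, 24), 4, 3, seed = 5 + cl - 1)
  S <- U[, , 1] + U[, , 2] + U[, , 3]
  wbar <- vapply(1:3, function(cl) mean(U[, , cl] / S), 0)
  expect_equal(wbar[1] > wbar[2], TRUE)   # red-dominated blend
  expect_lt(max(abs(wbar - vals)), 0.12)
  expect_error(class_noise_texture(reg, c(0, 0, 0), ryb3), "zero")
})

test_that("projection masks cover the projected footprint", {
  # flat 10x10 plate, 1 voxel thick, normal along z
  labels <- array(0L, c(16, 16, 8))
  labels[4:13, 4:13, 5] <- 1L
  vol <- labeled_volume(array(0, c(16, 16, 8)), labels)
  reg <- roi_projection_mask(vol, 1L, centroid = c(8.5, 8.5, 0),
                             resolution = 64)
  extent <- attr(reg, "extent")
  area_mm2 <- sum(reg$mask) * (2 * extent / 64)^2
  expect_lt(abs(area_mm2 - 100) / 100, 0.1)
  # 180-degree rotational symmetry of a centrally symmetric ROI
  rot <- reg$mask[64:1, 64:1]
  expect_gte(mean(rot == reg$mask), 0.995)
  # single-voxel ROI: one filled footprint at the raster center
  l1 <- array(0L, c(9, 9, 9)); l1[5, 5, 7] <- 1L
  v1 <- labeled_volume(array(0, c(9, 9, 9)), l1)
  r1 <- roi_projection_mask(v1, 1L, centroid = c(4, 4, 1), resolution = 33)
  cc <- which(r1$mask, arr.ind = TRUE)
  expect_true(nrow(cc) >= 1)
  expect_equal(as.numeric(colMeans(cc)), c(17, 17), tolerance = 1)
  expect_error(roi_projection_mask(v1, 1L, centroid = c(4, 4, 6)),
               "degenerate")
})

test_that("textures land only on their ROI's map pixels", {
  ph <- small_phantom()
  cam <- default_camera(ph$volume)
  tf <- label_transfer_function(ph$roi$label)
  m <- render_map(ph$volume, cam, tf, 96)
  lab <- ph$roi$label[ph$roi$shell == "outer"][1]
  ts <- texture_set(list(texture_recipe_timeseries(lab, sin(1:100),
                                                   blur_sigma = 0)))
  out <- apply_textures_to_map(m, ts)
  changed <- which(apply(abs(out - m$rgba), c(1, 2), max) > 1e-12)
  expect_true(all(m$label_raster[changed] == lab))
  # empty texture set: identity
  expect_identical(apply_textures_to_map(m, texture_set(list())), m$rgba)
  # absent label: warning, output unchanged
  absent <- max(ph$roi$label) + 5L
  expect_warning(
    out2 <- apply_textures_to_map(m, texture_set(list(
      texture_recipe_timeseries(absent, sin(1:10))))),
    "skipped")
  expect_identical(out2, m$rgba)
})

test_that("block-mates get more similar time-series textures than strangers", {
  ph <- small_phantom()
  cam <- default_camera(ph$volume)
  tf <- label_transfer_function(ph$roi$label)
  m <- render_map(ph$volume, cam, tf, 128)
  ts <- make_timeseries(ph$roi, n_time = 128, n_blocks = 2, rho = 0.9,
                        seed = 31)
  rng <- range(ts$series$values)
  outer_ids <- ph$roi$label[ph$roi$shell == "outer"]
  K <- 4
  # per-ROI contour-shade profile: green channel sampled ring by ring
  profiles <- sapply(outer_ids, function(l) {
    rec <- texture_recipe_timeseries(l,
      ts$series$values[match(l, ts$series$roi_ids), ],
      range = rng, max_contours = K, blur_sigma = 0)
    tex <- apply_textures_to_map(m, texture_set(list(rec)))
    cf <- offset_contours(region2d(m$label_raster == l), max_contours = K)
    vapply(seq_len(K) - 1L, function(r) {
      px <- which(cf == r, arr.ind = TRUE)
      if (nrow(px) == 0) return(NA_real_)
      tex[px[1, 1], px[1, 2], 2]
    }, 0)
  })
  blk <- ts$truth$block_assignment[as.character(outer_ids)]
  d <- as.matrix(dist(t(profiles)))
  same <- outer(blk, blk, "==") & upper.tri(d)
  diff <- !outer(blk, blk, "==") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})
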