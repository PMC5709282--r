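test_that("front-to-back compositing follows the closed forms", {
  expect_equal(composite_ray(matrix(c(1, 0, 0, 0.6), 1)),
               c(0.6, 0, 0, 0.6))
  expect_equal(composite_ray(rbind(c(1, 1, 1, 0.5), c(1, 0, 0, 0.5))),
               c(0.75, 0.5, 0.5, 0.75))
  expect_equal(composite_ray(NULL), c(0, 0, 0, 0))
  expect_equal(composite_ray(matrix(numeric(0), 0, 4)), c(0, 0, 0, 0))
  expect_error(composite_ray(matrix(c(1, 0, 0, 1.4), 1)), "opacity")
  # accumulated alpha is nondecreasing and capped at 1
  set.seed(1)
  s <- cbind(matrix(runif(60), 20), runif(20))
  acc <- 0
  for (i in 1:20) {
    res <- composite_ray(s[1:i, , drop = FALSE])
    expect_gte(res[4], acc)
    expect_lte(res[4], 1)
    acc <- res[4]
  }
})

test_that("default camera centers on the labeled centroid and encloses it", {
  labels <- array(0L, c(9, 9, 9)); labels[4, 5, 6] <- 1L
  vol <- labeled_volume(array(0, c(9, 9, 9)), labels)
  cam <- default_camera(vol)
  expect_equal(cam$center, c(3, 4, 5))
  labels2 <- array(0L, c(9, 9, 9))
  labels2[2, 5, 5] <- 1L; labels2[8, 5, 5] <- 1L  # symmetric about center
  vol2 <- labeled_volume(array(0, c(9, 9, 9)), labels2)
  expect_equal(default_camera(vol2)$center, c(4, 4, 4))
  ph <- small_phantom()
  cam3 <- default_camera(ph$volume)
  idx <- which(ph$volume$labels > 0)
  w <- voxel_to_world(ph$volume, arrayInd(idx, dim(ph$volume$labels)) - 1)
  expect_true(all(sqrt(rowSums(sweep(w, 2, cam3$center, "-")^2)) <
                  cam3$radius))
  expect_error(default_camera(labeled_volume(array(0, c(4, 4, 4)),
                                             array(0L, c(4, 4, 4)))),
               "no labeled voxels")
})

test_that("single rays match the literal per-sample oracle to 1e-12", {
  ph <- small_phantom()
  vol <- ph$volume
  cam <- default_camera(vol)
  # semi-transparent categorical transfer + intensity ramp background
  tf <- label_transfer_function(ph$roi$label, opacity = 0.35)
  step <- 0.5 * min(vol$spacing)
  set.seed(8)
  lats <- runif(12, -pi / 2 + 0.05, pi / 2 - 0.05)
  lons <- runif(12, -pi, pi - 0.01)
  for (i in seq_along(lats)) {
    got <- cast_ray(vol, cam, tf, lats[i], lons[i])
    want <- oracle_cast_ray(vol, cam, tf, lats[i], lons[i], step)
    expect_equal(got$rgba, want$rgba, tolerance = 1e-12)
    expect_identical(got$occlusion, want$occlusion)
  }
})

test_that("an all-transparent transfer function yields empty rays", {
  ph <- small_phantom()
  cam <- default_camera(ph$volume)
  tf <- transfer_function()  # zero opacity everywhere, no label overrides
  r <- cast_ray(ph$volume, cam, tf, 0.3, 0.4)
  expect_equal(r$rgba, c(0, 0, 0, 0))
  expect_length(r$occlusion, 0)
  m <- render_map(ph$volume, cam, label_transfer_function(1:8), 64,
                  visible_labels = integer(0))
  expect_true(all(m$rgba == 0))
  expect_true(all(m$label_raster == 0L))
})

test_that("opaque label raster equals the first-intersection oracle exactly", {
  ph <- small_phantom()
  vol <- ph$volume
  cam <- default_camera(vol)
  tf <- label_transfer_function(ph$roi$label)  # opaque
  step <- 0.5 * min(vol$spacing)
  m <- render_map(vol, cam, tf, 128, step = step)
  want <- oracle_label_raster(vol, cam, 128, step)
  expect_identical(m$label_raster, want)
  # every outer-shell label is visible on the map
  outer_ids <- ph$roi$label[ph$roi$shell == "outer"]
  expect_true(all(outer_ids %in% m$label_raster))
})

test_that("mirroring the volume mirrors the map about its vertical axis", {
  ph <- small_phantom()
  vol <- ph$volume
  g <- dim(vol$labels)[1]
  flipped <- labeled_volume(vol$intensity[, g:1, ], vol$labels[, g:1, ],
                            vol$spacing, vol$origin)
  ctr <- rep((g - 1) / 2, 3)
  cam <- spherical_camera(ctr, radius = 1.05 * (g - 1) * sqrt(3) / 2)
  tf <- label_transfer_function(ph$roi$label)
  m1 <- render_map(vol, cam, tf, 64)
  m2 <- render_map(flipped, cam, tf, 64)
  expect_identical(m2$label_raster, m1$label_raster[, 64:1])
})

test_that("outward rays from inside a hollow shell see the shell everywhere", {
  ph1 <- make_phantom(phantom_spec(grid = 24, n_cortical = 1,
                                   n_subcortical = 0, seed = 2))
  vol <- ph1$volume
  ctr <- rep((24 - 1) / 2, 3)
  cam <- spherical_camera(ctr, radius = 14, direction = "outward")
  tf <- label_transfer_function(1L)
  m <- render_map(vol, cam, tf, 64)
  inside <- !is.na(hammer_aitoff_inverse(
    pixel_to_map(row(m$label_raster), col(m$label_raster), 64, 32)[, 1],
    pixel_to_map(row(m$label_raster), col(m$label_raster), 64, 32)[, 2])[, 1])
  expect_true(all(m$label_raster[matrix(inside, 32, 64)] == 1L))
})

test_that("layered rendering separates the shells and restacks consistently", {
  ph <- small_phantom()
  vol <- ph$volume
  cam <- default_camera(vol)
  tf <- label_transfer_function(ph$roi$label)
  rays <- cast_camera_grid(vol, default_camera(vol, n_lat = 32, n_lon = 64),
                           tf)
  layers <- layer_sort(build_occlusion_graph(rays$occlusion))
  maps <- render_layered_maps(vol, cam, tf, 96, layers)
  expect_equal(vapply(maps, function(m) m$layer_index, 0L),
               seq_along(maps))
  outer_ids <- ph$roi$label[ph$roi$shell == "outer"]
  inner_ids <- ph$roi$label[ph$roi$shell == "inner"]
  expect_false(any(inner_ids %in% maps[[1]]$label_raster))
  expect_true(all(inner_ids %in% maps[[2]]$label_raster))
  # single-layer assignment reproduces the plain opaque rendering
  ly1 <- layer_assignment(setNames(rep(1L, nrow(ph$roi)), ph$roi$label))
  m_all <- render_layered_maps(vol, cam, tf, 96, ly1)[[1]]
  base <- render_map(vol, cam, tf, 96)
  expect_identical(m_all$label_raster, base$label_raster)
  expect_equal(m_all$rgba, base$rgba)
  # stacking back-to-front reproduces the unlayered label raster (>= 99%)
  stacked <- matrix(0L, nrow(base$label_raster), ncol(base$label_raster))
  for (k in rev(seq_along(maps))) {
    vis <- maps[[k]]$rgba[, , 4] > 0.5
    stacked[vis] <- maps[[k]]$label_raster[vis]
  }
  lab_px <- base$label_raster != 0L
  agree <- mean(stacked[lab_px] == base$label_raster[lab_px])
  expect_gte(agree, 0.99)
  # unassigned label errors
  ly_bad <- layer_assignment(setNames(rep(1L, nrow(ph$roi) - 1),
                                      ph$roi$label[-1]))
  expect_error(render_layered_maps(vol, cam, tf, 96, ly_bad),
               "no layer assignment")
})

test_that("layer scale factors magnify maps about the center", {
  ph <- small_phantom()
  cam <- default_camera(ph$volume)
  tf <- label_transfer_function(ph$roi$label)
  outer_n <- sum(ph$roi$shell == "outer")
  ly <- layer_assignment(
    setNames(ifelse(ph$roi$shell == "outer", 1L, 2L), ph$roi$label),
    scale = c("2" = 1.5))
  maps <- render_layered_maps(ph$volume, cam, tf, 96, ly)
  unscaled <- render_layered_maps(ph$volume, cam, tf, 96,
    layer_assignment(setNames(ifelse(ph$roi$shell == "outer", 1L, 2L),
                              ph$roi$label)))
  # magnified layer covers more pixels
  expect_gt(sum(maps[[2]]$label_raster > 0),
            sum(unscaled[[2]]$label_raster > 0))
  expect_equal(maps[[1]]$label_raster, unscaled[[1]]$label_raster)
})
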