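roi_row <- function(label, p) {
  data.frame(label = label, name = sprintf("roi_%d", label),
             cx = p[1], cy = p[2], cz = p[3], voxel_count = 1,
             volume_mm3 = 1)
}

test_that("Bezier control points extend radially from the centroid", {
  a <- roi_row(1L, c(10, 0, 0)); b <- roi_row(2L, c(0, 10, 0))
  e <- bezier_edge(a, b, centroid = c(0, 0, 0), elevation = 0.4)
  expect_equal(e$P0, c(10, 0, 0))
  expect_equal(e$P3, c(0, 10, 0))
  expect_equal(e$P1, c(14, 0, 0))    # pushed 0.4 * 10 outward
  expect_equal(e$P2, c(0, 14, 0))
  expect_gt(sqrt(sum(e$P1^2)), sqrt(sum(e$P0^2)))
  # elevation 0: straight chord
  e0 <- bezier_edge(a, b, c(0, 0, 0), elevation = 0)
  expect_equal(e0$P1, e0$P0)
  expect_equal(e0$P2, e0$P3)
  expect_error(bezier_edge(roi_row(1L, c(0, 0, 0)), b, c(0, 0, 0)),
               "degenerate")
})

test_that("symmetric centers give a point-reflection symmetric curve", {
  a <- roi_row(1L, c(5, 2, 0)); b <- roi_row(2L, c(-5, -2, 0))
  e <- bezier_edge(a, b, centroid = c(0, 0, 0), elevation = 0.3)
  s <- sample_bezier(e, 21)
  expect_equal(s, -s[21:1, ], tolerance = 1e-12)
})

test_that("Bezier sampling matches the cubic closed form", {
  e <- structure(list(P0 = c(0, 0, 0), P1 = c(0, 1, 0), P2 = c(1, 1, 0),
                      P3 = c(1, 0, 0), source = 1L, target = 2L),
                 class = "bezier_edge")
  s <- sample_bezier(e, 3)
  expect_equal(s[1, ], c(0, 0, 0))
  expect_equal(s[3, ], c(1, 0, 0))
  expect_equal(s[2, ], c(0.5, 0.75, 0))   # hand evaluation at t = 0.5
  # collinear control points stay on the line
  e2 <- structure(list(P0 = c(0, 0, 0), P1 = c(1, 1, 1), P2 = c(2, 2, 2),
                       P3 = c(3, 3, 3)), class = "bezier_edge")
  s2 <- sample_bezier(e2, 9)
  expect_equal(s2[, 2], s2[, 1])
  expect_equal(s2[, 3], s2[, 1])
  # parameter reversal reverses the polyline exactly
  e3 <- structure(list(P0 = e$P3, P1 = e$P2, P2 = e$P1, P3 = e$P0),
                  class = "bezier_edge")
  expect_equal(sample_bezier(e3, 7), sample_bezier(e, 7)[7:1, ])
  expect_error(sample_bezier(e, 1), ">= 2")
})

test_that("map projection of polylines splits at the antimeridian seam", {
  cam <- spherical_camera(c(0, 0, 0), 10)
  # points near lon 0: one piece
  pts <- cbind(c(5, 5, 5), c(-1, 0, 1), c(0, 0.5, 1))
  pl <- project_polyline_to_map(pts, cam, 128)
  expect_length(pl$pieces, 1)
  expect_equal(nrow(pl$pieces[[1]]), 3)
  # two points straddling lon = +/- pi: two pieces
  lonp <- pi - 0.01
  pts2 <- rbind(c(cos(lonp), sin(lonp), 0), c(cos(-lonp), sin(-lonp), 0)) * 5
  pl2 <- project_polyline_to_map(pts2, cam, 128)
  expect_length(pl2$pieces, 2)
  # a +z-axis point lands on the north-pole image (0, sqrt(2))
  pl3 <- project_polyline_to_map(rbind(c(0, 0, 7), c(1, 0, 0)), cam, 128)
  top <- pl3$pieces[[1]][1, ]
  want <- map_to_pixel(0, sqrt(2), 128, 64)
  expect_equal(as.numeric(top), as.numeric(want), tolerance = 1e-9)
  expect_error(project_polyline_to_map(rbind(c(0, 0, 0)), cam, 128),
               "camera center")
})

test_that("edge colors blend class weights in RYB and ignore scale", {
  ryb3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  c1 <- blend_edge_color(c(1, 0, 0), ryb3)
  expect_equal(c1, c(as.numeric(ryb_to_rgb(c(1, 0, 0))), 1))
  # equal red + yellow: the (0.5, 0.5, 0) point of the cube, orange-ward
  c2 <- blend_edge_color(c(2, 2, 0), ryb3)
  expect_equal(c2[1:3], as.numeric(ryb_to_rgb(c(0.5, 0.5, 0))))
  expect_gt(c2[1], c2[3])  # orange: red channel dominates blue
  expect_equal(blend_edge_color(c(5, 0, 0), ryb3), c1)
  expect_equal(blend_edge_color(10 * c(1, 2, 3), ryb3),
               blend_edge_color(c(1, 2, 3), ryb3))
  expect_error(blend_edge_color(c(0, 0, 0), ryb3), "zero")
})

test_that("composed figures are deterministic and anchored to ROI regions", {
  ph <- small_phantom()
  vol <- ph$volume
  cam <- default_camera(vol)
  tf <- label_transfer_function(ph$roi$label)
  m <- render_map(vol, cam, tf, 128)
  # no textures, no edges: base unchanged
  expect_identical(compose_figure(m), m$rgba)
  net <- build_structural_network(
    make_fibers(vol, ph$roi, 120, seed = 3)$fibers, vol, ph$roi)
  edges_df <- threshold_edges(net, 0.9, percentile = TRUE)
  pls <- edges_to_map_polylines(edges_df, ph$roi, cam, 128)
  f1 <- compose_figure(m, edges = pls)
  f2 <- compose_figure(m, edges = pls)
  expect_identical(f1, f2)
  expect_gt(sum(abs(f1 - m$rgba)), 0)
  # projected endpoints land within (or near) their ROI map regions
  outer_tab <- ph$roi[ph$roi$shell == "outer", ]
  for (i in seq_len(min(5, nrow(edges_df)))) {
    ra <- edges_df$roi_a[i]
    if (!ra %in% outer_tab$label) next
    rowa <- ph$roi[ph$roi$label == ra, ]
    pl <- project_polyline_to_map(
      rbind(c(rowa$cx, rowa$cy, rowa$cz)), cam, 128)
    px <- round(pl$pieces[[1]][1, ])
    h <- nrow(m$label_raster); w <- ncol(m$label_raster)
    window <- m$label_raster[max(1, px[1] - 2):min(h, px[1] + 2),
                             max(1, px[2] - 2):min(w, px[2] + 2)]
    expect_true(ra %in% window)
  }
})

test_that("layered panels tile side by side with matched sizes", {
  ph <- small_phantom()
  cam <- default_camera(ph$volume)
  tf <- label_transfer_function(ph$roi$label)
  ly <- layer_assignment(
    setNames(ifelse(ph$roi$shell == "outer", 1L, 2L), ph$roi$label))
  maps <- render_layered_maps(ph$volume, cam, tf, 64, ly)
  fig <- compose_figure(maps)
  expect_equal(dim(fig), c(32, 128, 4))
  figc <- compose_figure(maps, layout = list(arrange = "column"))
  expect_equal(dim(figc), c(64, 64, 4))
})
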