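#' Cubic Bezier edge between two ROI centers
#'
#' Control points: `P0`/`P3` are the ROI centers; `P1`/`P2` are extension
#' points pushed radially outward from the brain centroid by `elevation`
#' times each center's distance from the centroid, lifting the curve above
#' the structure.
#'
#' @param roi_a,roi_b single rows of a [roi_table()] (fields `cx`, `cy`,
#'   `cz`, `label`).
#' @param centroid world point (mm), the brain centroid.
#' @param elevation outward extension fraction (0 = straight chord).
#' @return A `bezier_edge`: list with `P0`..`P3` (length-3 points), `source`,
#'   `target`.
#' @export
bezier_edge <- function(roi_a, roi_b, centroid, elevation = 0.4) {
  centroid <- as.numeric(centroid)
  p0 <- c(roi_a$cx, roi_a$cy, roi_a$cz)
  p3 <- c(roi_b$cx, roi_b$cy, roi_b$cz)
  ra <- p0 - centroid; rb <- p3 - centroid
  na <- sqrt(sum(ra^2)); nb <- sqrt(sum(rb^2))
  if (na < 1e-9 || nb < 1e-9)
    stop("degenerate edge: ROI center coincides with centroid")
  structure(list(P0 = p0,
                 P1 = p0 + elevation * ra,
                 P2 = p3 + elevation * rb,
                 P3 = p3,
                 source = roi_a$label, target = roi_b$label),
            class = "bezier_edge")
}

#' Sample a cubic Bezier curve at uniform parameters
#'
#' `B(t) = (1-t)^3 P0 + 3(1-t)^2 t P1 + 3(1-t) t^2 P2 + t^3 P3`.
#'
#' @param edge a [bezier_edge()].
#' @param n number of samples (>= 2), uniform in `t` over `[0, 1]`.
#' @return n x 3 matrix of world points; rows 1 and n equal `P0` and `P3`.
#' @export
sample_bezier <- function(edge, n = 64L) {
  if (n < 2) stop("n must be >= 2")
  t <- seq(0, 1, length.out = n)
  outer((1 - t)^3, edge$P0) + outer(3 * (1 - t)^2 * t, edge$P1) +
    outer(3 * (1 - t) * t^2, edge$P2) + outer(t^3, edge$P3)
}

#' Project a 3D polyline onto the planar map
#'
#' Each point is turned into a direction from the camera center, mapped to
#' (lat, lon) and then through the forward Hammer-Aitoff projection to
#' fractional pixel coordinates. Consecutive points whose longitudes differ
#' by more than pi cross the antimeridian seam and start a new piece.
#'
#' @param points n x 3 matrix of world points (none at the camera center).
#' @param camera a [spherical_camera()].
#' @param map_width map width in pixels (height is `ceiling(width/2)`).
#' @param color RGBA vector attached to the polyline.
#' @param width_px stroke width in pixels.
#' @return A `map_polyline`: list with `pieces` (list of m x 2 matrices of
#'   fractional (row, col)), `color`, `width_px`.
#' @export
project_polyline_to_map <- function(points, camera, map_width,
                                    color = c(0, 0, 0, 1), width_px = 2) {
  points <- rbind_points(points)
  rel <- sweep(points, 2, camera$center, "-")
  if (any(rowSums(rel^2) < 1e-18)) stop("point at camera center")
  ll <- direction_to_latlon(rel)
  xy <- hammer_aitoff_forward(ll[, 1], ll[, 2])
  h <- as.integer(ceiling(map_width / 2))
  rc <- map_to_pixel(xy[, 1], xy[, 2], map_width, h)
  brk <- which(abs(diff(ll[, 2])) > pi)
  starts <- c(1, brk + 1)
  ends <- c(brk, nrow(rc))
  pieces <- Map(function(s, e) rc[s:e, , drop = FALSE], starts, ends)
  structure(list(pieces = pieces, color = color, width_px = width_px),
            class = "map_polyline")
}

#' Blend per-class edge weights into an RYB-mixed RGBA color
#'
#' Normalizes the class weights, blends the class RYB colors with those
#' weights, and converts to RGB. Scaling all weights by a constant leaves
#' the color unchanged.
#'
#' @param class_weights nonnegative weights, not all zero.
#' @param class_colors n_class x 3 RYB matrix.
#' @return RGBA vector (alpha 1).
#' @export
blend_edge_color <- function(class_weights, class_colors) {
  class_weights <- as.numeric(class_weights)
  if (any(class_weights < 0)) stop("weights must be nonnegative")
  s <- sum(class_weights)
  if (s == 0) stop("all class weights are zero")
  wn <- class_weights / s
  ryb <- colSums(wn * as.matrix(class_colors))
  c(ryb_to_rgb(ryb)[1, ], 1)
}

# Draw an anti-aliased stroked segment onto an RGBA array (in place value
# semantics: returns the modified array). Coverage falls off linearly over
# one pixel beyond the half-width.
draw_segment <- function(img, p1, p2, color, width_px) {
  h <- dim(img)[1]; w <- dim(img)[2]
  hw <- width_px / 2
  r0 <- max(1L, floor(min(p1[1], p2[1]) - hw - 1))
  r1 <- min(h, ceiling(max(p1[1], p2[1]) + hw + 1))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - hw - 1))
  c1 <- min(w, ceiling(max(p1[2], p2[2]) + hw + 1))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) {
    d <- sqrt((gr - p1[1])^2 + (gc - p1[2])^2)
  } else {
    t <- pmin(1, pmax(0, ((gr - p1[1]) * v[1] + (gc - p1[2]) * v[2]) / L2))
    d <- sqrt((gr - (p1[1] + t * v[1]))^2 + (gc - (p1[2] + t * v[2]))^2)
  }
  cov <- pmin(1, pmax(0, hw + 0.5 - d))
  a <- cov * color[4]
  if (all(a == 0)) return(img)
  for (ch in 1:3) {
    sub <- img[rr, cc, ch]
    img[rr, cc, ch] <- color[ch] * a + sub * (1 - a)
  }
  img[rr, cc, 4] <- a + img[rr, cc, 4] * (1 - a)
  img
}

# Draw a map_polyline (all pieces) onto an RGBA array.
draw_polyline <- function(img, pl) {
  for (piece in pl$pieces) {
    if (nrow(piece) < 2) next
    for (i in seq_len(nrow(piece) - 1))
      img <- draw_segment(img, piece[i, ], piece[i + 1, ], pl$color,
                          pl$width_px)
  }
  img
}

#' Compose a figure: base map(s), textures, network edges
#'
#' Draw order is base rendering, then the textured overlay (if supplied),
#' then edges. A layered sequence of maps is tiled side by side
#' (`layout$arrange = "row"`) or stacked (`"column"`); edges are drawn on
#' every panel whose `layer_index` appears in their `layers` attribute (all
#' panels when unset).
#'
#' @param base a `brain_map` or list of `brain_map`s (layered sequence).
#' @param textured optional RGBA array replacing the base pixels of a single
#'   map (as from [apply_textures_to_map()]); sizes must agree.
#' @param edges list of `map_polyline`s.
#' @param layout list; `arrange` = `"row"` or `"column"` for layered input.
#' @return H x W x 4 RGBA array.
#' @export
compose_figure <- function(base, textured = NULL, edges = list(),
                           layout = list(arrange = "row")) {
  panels <- if (inherits(base, "brain_map")) list(base) else base
  imgs <- vector("list", length(panels))
  for (i in seq_along(panels)) {
    img <- panels[[i]]$rgba
    if (!is.null(textured) && length(panels) == 1) {
      if (!all(dim(textured) == dim(img)))
        stop("textured image size does not match base map")
      img <- textured
    }
    for (e in edges) {
      on_layers <- attr(e, "layers")
      if (is.null(on_layers) || panels[[i]]$layer_index %in% on_layers)
        img <- draw_polyline(img, e)
    }
    imgs[[i]] <- img
  }
  if (length(imgs) == 1) return(imgs[[1]])
  hs <- vapply(imgs, function(x) dim(x)[1], 0L)
  ws <- vapply(imgs, function(x) dim(x)[2], 0L)
  if (length(unique(hs)) != 1 || length(unique(ws)) != 1)
    stop("panel sizes differ")
  if (identical(layout$arrange, "column")) {
    out <- array(0, c(sum(hs), ws[1], 4))
    at <- 0
    for (img in imgs) {
      out[at + seq_len(dim(img)[1]), , ] <- img
      at <- at + dim(img)[1]
    }
  } else {
    out <- array(0, c(hs[1], sum(ws), 4))
    at <- 0
    for (img in imgs) {
      out[, at + seq_len(dim(img)[2]), ] <- img
      at <- at + dim(img)[2]
    }
  }
  out
}

#' Build map polylines for a thresholded edge list
#'
#' Convenience wrapper: for each edge of an [threshold_edges()] table, build
#' the 3D Bezier curve, sample it, and project it onto the map with a color
#' scaled by edge weight (or a constant color).
#'
#' @param edge_df data.frame with `roi_a`, `roi_b`, `weight`.
#' @param roi a [roi_table()].
#' @param camera a [spherical_camera()].
#' @param map_width map width in pixels.
#' @param centroid brain centroid (defaults to camera center).
#' @param elevation Bezier extension fraction.
#' @param color base RGBA; alpha is scaled by weight / max weight.
#' @param n_samples Bezier samples per edge.
#' @return list of `map_polyline`s.
#' @export
edges_to_map_polylines <- function(edge_df, roi, camera, map_width,
                                   centroid = NULL, elevation = 0.4,
                                   color = c(0.1, 0.1, 0.1, 0.9),
                                   n_samples = 64L) {
  if (is.null(centroid)) centroid <- camera$center
  wmax <- if (nrow(edge_df)) max(edge_df$weight) else 1
  out <- vector("list", nrow(edge_df))
  for (i in seq_len(nrow(edge_df))) {
    ra <- roi[roi$label == edge_df$roi_a[i], ]
    rb <- roi[roi$label == edge_df$roi_b[i], ]
    be <- bezier_edge(ra, rb, centroid, elevation)
    pts <- sample_bezier(be, n_samples)
    col <- color
    if (wmax > 0) col[4] <- color[4] * (0.3 + 0.7 * edge_df$weight[i] / wmax)
    out[[i]] <- project_polyline_to_map(pts, camera, map_width, color = col)
  }
  out
}
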