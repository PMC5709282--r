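#' 2D region (binary mask) for texture generation
#'
#' @param mask logical (or 0/1) matrix; `TRUE` inside the region. Need not be
#'   connected, but must be nonempty for texture generation.
#' @param provenance free-text origin tag (e.g. `"map-layer"` or
#'   `"projection-plane"`).
#' @return A `region2d` object.
#' @export
region2d <- function(mask, provenance = "map-layer") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, provenance = provenance), class = "region2d")
}

#' Project an ROI's voxels onto its projection plane
#'
#' The projection plane of an ROI passes through the ROI center with normal
#' along the line joining the brain centroid and the ROI center. Voxel
#' centers are projected orthogonally onto the plane, expressed in a
#' deterministic in-plane orthonormal basis (the normal crossed with the
#' most orthogonal coordinate axis, then orthonormalized), and rasterized
#' into a square mask with a one-voxel-footprint dilation to close sampling
#' gaps.
#'
#' @param volume a [labeled_volume()].
#' @param label ROI id present in the volume.
#' @param centroid world point (mm); typically the centroid of all labeled
#'   voxels (the "brain" center).
#' @param resolution output mask edge length in pixels.
#' @return A [region2d()] with attributes `extent` (half-width of the plane
#'   window in mm) and `basis` (2 x 3 in-plane basis).
#' @export
roi_projection_mask <- function(volume, label, centroid, resolution = 64L) {
  idx <- which(volume$labels == label)
  if (length(idx) == 0) stop(sprintf("label %d not present", label))
  w <- voxel_to_world(volume, arrayInd(idx, dim(volume$labels)) - 1)
  center <- colMeans(w)
  nvec <- center - as.numeric(centroid)
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-9) stop("degenerate projection: ROI center equals centroid")
  nvec <- nvec / nn
  e <- diag(3)[, which.min(abs(nvec))]
  b1 <- c(nvec[2] * e[3] - nvec[3] * e[2],
          nvec[3] * e[1] - nvec[1] * e[3],
          nvec[1] * e[2] - nvec[2] * e[1])
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(nvec[2] * b1[3] - nvec[3] * b1[2],
          nvec[3] * b1[1] - nvec[1] * b1[3],
          nvec[1] * b1[2] - nvec[2] * b1[1])
  rel <- sweep(w, 2, center, "-")
  uv <- cbind(rel %*% b1, rel %*% b2)
  fp <- max(volume$spacing)
  extent <- max(abs(uv), fp) + fp
  px <- resolution / (2 * extent)       # pixels per mm
  # stamp each voxel's half-spacing footprint (closes inter-voxel gaps and
  # keeps the mask area faithful to the projected footprint area)
  h <- fp / 2
  mask <- matrix(FALSE, resolution, resolution)
  span <- function(u) {
    i0 <- pmax(1, ceiling((u - h + extent) * px + 0.5))
    i1 <- pmin(resolution, floor((u + h + extent) * px + 0.5))
    cbind(i0, i1)
  }
  rs <- span(uv[, 2]); cs <- span(uv[, 1])
  for (i in seq_len(nrow(uv))) {
    if (rs[i, 1] > rs[i, 2] || cs[i, 1] > cs[i, 2]) next
    mask[rs[i, 1]:rs[i, 2], cs[i, 1]:cs[i, 2]] <- TRUE
  }
  out <- region2d(mask, provenance = "projection-plane")
  attr(out, "extent") <- extent
  attr(out, "basis") <- rbind(b1, b2)
  out
}

#' Offset contours by iterative morphological erosion
#'
#' Ring 0 (the outermost contour) is the mask minus its erosion with the
#' 3x3 full-square structuring element; the process iterates on the eroded
#' mask until it is empty or `max_contours` rings exist, in which case all
#' remaining interior pixels join the last ring.
#'
#' @param region a nonempty [region2d()].
#' @param max_contours optional cap on the number of rings.
#' @return A `contour_field`: integer matrix, -1 outside the mask, ring
#'   index `0..K-1` inside, with attribute `n_contours` = K.
#' @export
offset_contours <- function(region, max_contours = NULL) {
  mask <- region$mask
  if (!any(mask)) stop("empty mask")
  kern <- EBImage::makeBrush(3, shape = "box")
  field <- matrix(-1L, nrow(mask), ncol(mask))
  # pad by one pixel so pixels on the raster border erode against background
  erode1 <- function(m) {
    pd <- matrix(0, nrow(m) + 2, ncol(m) + 2)
    pd[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    er <- EBImage::imageData(EBImage::erode(pd, kern)) > 0
    er[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  }
  cur <- mask
  k <- 0L
  while (any(cur)) {
    if (!is.null(max_contours) && k == max_contours - 1L) {
      field[cur] <- k
      k <- k + 1L
      break
    }
    er <- erode1(cur * 1)
    ring <- cur & !er
    field[ring] <- k
    cur <- er
    k <- k + 1L
  }
  structure(field, class = "contour_field", n_contours = k)
}

# Gaussian blur with zero padding so the kernel always fits and nothing
# wraps around the raster edges.
gblur_padded <- function(m, sigma) {
  p <- 2 * ceiling(3 * sigma) + 2
  pd <- matrix(0, nrow(m) + 2 * p, ncol(m) + 2 * p)
  pd[p + seq_len(nrow(m)), p + seq_len(ncol(m))] <- m
  out <- EBImage::imageData(EBImage::gblur(pd, sigma))
  out[p + seq_len(nrow(m)), p + seq_len(ncol(m))]
}

#' Texture encoding a time series as shaded offset contours
#'
#' The time axis is divided evenly across the K contours: ring `c` (0 =
#' outermost = earliest) covers sample indices `[floor(cT/K),
#' floor((c+1)T/K))` and is colored by the shade of the base hue for the
#' bin's mean activity, normalized between `palette$range` (global min/max
#' across the whole time-series set keeps ROIs comparable). A Gaussian blur
#' (normalized convolution confined to the mask, so boundary pixels do not
#' darken) smooths the rings; the result is re-masked.
#'
#' @param contours a [offset_contours()] result.
#' @param series numeric time series for this ROI, length >= number of
#'   contours.
#' @param palette list with `hue` (RGB in `[0,1]`, the full-activity color)
#'   and `range` (length-2 global activity min/max). Shade runs linearly
#'   from white (minimum) to `hue` (maximum).
#' @param blur_sigma Gaussian sigma in pixels (0 disables blurring).
#' @return H x W x 4 RGBA array; alpha 1 inside the mask, 0 outside.
#' @export
timeseries_texture <- function(contours, series,
                               palette = list(hue = c(0.8, 0.1, 0.1),
                                              range = NULL),
                               blur_sigma = 1.5) {
  K <- attr(contours, "n_contours")
  T_ <- length(series)
  if (T_ < K)
    stop(sprintf(paste0("series has %d points but %d contours; ",
                        "cap max_contours at %d in offset_contours()"),
                 T_, K, T_))
  rng <- palette$range
  if (is.null(rng)) rng <- range(series)
  binmean <- vapply(seq_len(K) - 1L, function(c_) {
    lo <- floor(c_ * T_ / K) + 1L
    hi <- floor((c_ + 1L) * T_ / K)
    mean(series[lo:hi])
  }, 0)
  a <- if (diff(rng) > 0) pmin(1, pmax(0, (binmean - rng[1]) / diff(rng)))
       else rep(0.5, K)
  hue <- palette$hue
  shades <- cbind(1 - a * (1 - hue[1]), 1 - a * (1 - hue[2]),
                  1 - a * (1 - hue[3]))
  mask <- contours >= 0
  h <- nrow(contours); wd <- ncol(contours)
  out <- array(0, c(h, wd, 4))
  ringidx <- contours[mask] + 1L
  for (ch in 1:3) {
    plane <- matrix(0, h, wd)
    plane[mask] <- shades[ringidx, ch]
    if (blur_sigma > 0) {
      num <- gblur_padded(plane * mask, blur_sigma)
      den <- gblur_padded(mask * 1, blur_sigma)
      plane[mask] <- (num / pmax(den, 1e-12))[mask]
    }
    cplane <- matrix(0, h, wd)
    cplane[mask] <- pmin(1, pmax(0, plane[mask]))
    out[, , ch] <- cplane
  }
  out[, , 4] <- mask * 1
  out
}

#' Default RYB color-cube corners
#'
#' RGB values at the eight corners of the RYB unit cube, indexed by the RYB
#' bits (r, y, b), with painterly mixing semantics: red + yellow = orange,
#' blue + red = purple, all three = near-black.
#'
#' @return 2 x 2 x 2 x 3 numeric array of corner RGB values.
#' @export
default_ryb_cube <- function() {
  corners <- array(0, c(2, 2, 2, 3))
  corners[1, 1, 1, ] <- c(1, 1, 1)            # white  (0,0,0)
  corners[2, 1, 1, ] <- c(1, 0, 0)            # red    (1,0,0)
  corners[1, 2, 1, ] <- c(1, 1, 0)            # yellow (0,1,0)
  corners[1, 1, 2, ] <- c(0.163, 0.373, 0.6)  # blue   (0,0,1)
  corners[2, 2, 1, ] <- c(1, 0.5, 0)          # orange (1,1,0)
  corners[2, 1, 2, ] <- c(0.5, 0, 0.5)        # purple (1,0,1)
  corners[1, 2, 2, ] <- c(0, 0.66, 0.2)       # green  (0,1,1)
  corners[2, 2, 2, ] <- c(0.2, 0.094, 0)      # black  (1,1,1)
  corners
}

#' Convert RYB colors to RGB by trilinear interpolation in a color cube
#'
#' The red-yellow-blue model mixes the way painters expect (red + yellow =
#' orange, blue + red = purple); each RYB triple is converted to RGB by
#' trilinear interpolation between eight configured cube corners.
#'
#' @param ryb n x 3 matrix (or length-3 vector) of RYB components in
#'   `[0, 1]`.
#' @param cube 2 x 2 x 2 x 3 array of corner RGB values (default
#'   [default_ryb_cube()]).
#' @return n x 3 matrix of RGB values clamped to `[0, 1]`.
#' @export
ryb_to_rgb <- function(ryb, cube = default_ryb_cube()) {
  ryb <- rbind_points(ryb)
  if (any(ryb < 0 | ryb > 1)) stop("RYB components must be in [0, 1]")
  r <- ryb[, 1]; y <- ryb[, 2]; b <- ryb[, 3]
  out <- matrix(0, nrow(ryb), 3)
  for (ch in 1:3) {
    acc <- 0
    for (i in 0:1) for (j in 0:1) for (k in 0:1) {
      wgt <- (if (i) r else 1 - r) * (if (j) y else 1 - y) *
             (if (k) b else 1 - b)
      acc <- acc + wgt * cube[i + 1, j + 1, k + 1, ch]
    }
    out[, ch] <- acc
  }
  out[] <- pmin(1, pmax(0, out))
  out
}

#' Multi-octave value-noise turbulence raster
#'
#' Classic turbulence: octave `o` (1-based) samples seeded uniform lattice
#' noise at frequency `2^(o-1) * base_freq` cells across the image, bilinear
#' interpolated, summed with amplitude `1 / 2^(o-1)`; the sum is min-max
#' normalized to `[0, 1]`. Deterministic per seed.
#'
#' @param shape length-2 (rows, cols) of the output raster.
#' @param base_freq lattice cells across the image at the first octave.
#' @param octaves number of octaves (>= 1).
#' @param seed integer seed.
#' @return rows x cols numeric matrix in `[0, 1]`.
#' @export
turbulence <- function(shape, base_freq = 4, octaves = 3, seed = 1L) {
  if (octaves < 1) stop("octaves must be >= 1")
  h <- shape[1]; w <- shape[2]
  acc <- matrix(0, h, w)
  u <- (seq_len(w) - 0.5) / w
  v <- (seq_len(h) - 0.5) / h
  withr::with_seed(seed, {
    for (o in seq_len(octaves)) {
      f <- base_freq * 2^(o - 1)
      L <- matrix(stats::runif((f + 1)^2), f + 1, f + 1)
      gu <- u * f; gv <- v * f
      i0 <- pmin(floor(gu), f - 1); fu <- gu - i0
      j0 <- pmin(floor(gv), f - 1); fv <- gv - j0
      # value at (row r, col c) interpolates L[i0..i0+1, j0..j0+1]
      Vm <- matrix(fv, h, w); Um <- matrix(fu, h, w, byrow = TRUE)
      l00 <- L[cbind(rep(i0 + 1, each = h), rep(j0 + 1, times = w))]
      l10 <- L[cbind(rep(i0 + 2, each = h), rep(j0 + 1, times = w))]
      l01 <- L[cbind(rep(i0 + 1, each = h), rep(j0 + 2, times = w))]
      l11 <- L[cbind(rep(i0 + 2, each = h), rep(j0 + 2, times = w))]
      val <- (1 - Vm) * ((1 - Um) * l00 + Um * l10) +
             Vm * ((1 - Um) * l01 + Um * l11)
      acc <- acc + abs(val) / 2^(o - 1)
    }
  })
  rng <- range(acc)
  if (diff(rng) == 0) return(matrix(0.5, h, w))
  (acc - rng[1]) / diff(rng)
}

#' Multi-class RYB turbulence-noise texture
#'
#' Each class gets an independent turbulence field (seed offset by the class
#' index); per pixel, class weights are the class attribute values modulated
#' by their turbulence fields and normalized, the weighted RYB colors are
#' blended, and the blend is converted to RGB. A class with all the
#' attribute mass therefore paints every pixel in exactly its color, while
#' comparable classes interleave patches at the turbulence scale.
#'
#' @param region a nonempty [region2d()].
#' @param class_values nonnegative per-class attribute values (not all
#'   zero).
#' @param class_colors n_class x 3 matrix of RYB colors.
#' @param seed integer seed.
#' @param base_freq,octaves turbulence parameters.
#' @return H x W x 4 RGBA array; alpha 1 inside the mask.
#' @export
class_noise_texture <- function(region, class_values, class_colors,
                                seed = 1L, base_freq = 4, octaves = 3) {
  mask <- region$mask
  if (!any(mask)) stop("empty mask")
  class_values <- as.numeric(class_values)
  if (length(class_values) < 2) stop("need >= 2 classes")
  if (any(class_values < 0)) stop("class values must be nonnegative")
  if (sum(class_values) == 0) stop("all class values are zero")
  class_colors <- as.matrix(class_colors)
  h <- nrow(mask); w <- ncol(mask)
  nc <- length(class_values)
  U <- array(0, c(h, w, nc))
  for (cl in seq_len(nc))
    U[, , cl] <- class_values[cl] * turbulence(c(h, w), base_freq, octaves,
                                               seed = seed + cl - 1L)
  S <- apply(U, c(1, 2), sum)
  flat <- S == 0
  ryb <- matrix(0, h * w, 3)
  vals_norm <- class_values / sum(class_values)
  for (cl in seq_len(nc)) {
    wgt <- U[, , cl] / ifelse(flat, 1, S)
    wgt[flat] <- vals_norm[cl]  # degenerate pixels: attribute-only blend
    ryb <- ryb + as.vector(wgt) %o% class_colors[cl, ]
  }
  rgb <- ryb_to_rgb(pmin(1, pmax(0, ryb)))
  out <- array(0, c(h, w, 4))
  for (ch in 1:3) {
    plane <- matrix(rgb[, ch], h, w)
    plane[!mask] <- 0
    out[, , ch] <- plane
  }
  out[, , 4] <- mask * 1
  out
}

#' Assemble a set of per-ROI texture recipes
#'
#' A texture set holds recipes, not pixels: when applied to a brain map the
#' texture is generated on each ROI's own map-space region.
#'
#' @param ... recipes from [texture_recipe_timeseries()] /
#'   [texture_recipe_classnoise()].
#' @return A `texture_set` (list keyed by label).
#' @export
texture_set <- function(...) {
  recs <- list(...)
  if (length(recs) == 1 && is.list(recs[[1]]) && is.null(recs[[1]]$label))
    recs <- recs[[1]]
  names(recs) <- vapply(recs, function(r) as.character(r$label), "")
  structure(recs, class = "texture_set")
}

#' @rdname texture_set
#' @param label ROI id the recipe applies to.
#' @param series numeric time series for the ROI.
#' @param hue base RGB hue for the shade ramp.
#' @param range global activity min/max (for cross-ROI comparability).
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param max_contours optional cap on contour count.
#' @export
texture_recipe_timeseries <- function(label, series, hue = c(0.8, 0.1, 0.1),
                                      range = NULL, blur_sigma = 1.5,
                                      max_contours = NULL) {
  list(style = "timeseries", label = as.integer(label), series = series,
       hue = hue, range = range, blur_sigma = blur_sigma,
       max_contours = max_contours)
}

#' @rdname texture_set
#' @param values per-class attribute values for the ROI.
#' @param colors n_class x 3 RYB class colors.
#' @param seed,base_freq,octaves noise parameters.
#' @export
texture_recipe_classnoise <- function(label, values,
                                      colors = diag(3), seed = 1L,
                                      base_freq = 4, octaves = 3) {
  list(style = "class_noise", label = as.integer(label), values = values,
       colors = colors, seed = seed, base_freq = base_freq,
       octaves = octaves)
}

#' Apply ROI textures to a rendered brain map
#'
#' For each recipe whose label appears in the map's label raster, the
#' texture is generated on that ROI's map region (contours and noise are
#' computed in map space) and composited over the base rendering; ROIs
#' without a recipe keep the base rendering. Recipes for absent labels are
#' skipped with a warning.
#'
#' @param map a `brain_map`.
#' @param textures a [texture_set()].
#' @return H x W x 4 RGBA array.
#' @export
apply_textures_to_map <- function(map, textures) {
  out <- map$rgba
  for (rec in textures) {
    mask <- map$label_raster == rec$label
    if (!any(mask)) {
      warning(sprintf("no pixels with label %d on this map; texture skipped",
                      rec$label))
      next
    }
    reg <- region2d(mask, provenance = "map-layer")
    tex <- if (rec$style == "timeseries") {
      cf <- offset_contours(reg, max_contours = rec$max_contours)
      K <- attr(cf, "n_contours")
      if (length(rec$series) < K)
        cf <- offset_contours(reg, max_contours = length(rec$series))
      timeseries_texture(cf, rec$series,
                         palette = list(hue = rec$hue, range = rec$range),
                         blur_sigma = rec$blur_sigma)
    } else {
      class_noise_texture(reg, rec$values, rec$colors, seed = rec$seed,
                          base_freq = rec$base_freq, octaves = rec$octaves)
    }
    a <- tex[, , 4]
    for (ch in 1:3)
      out[, , ch] <- tex[, , ch] * a + out[, , ch] * (1 - a)
    out[, , 4] <- a + out[, , 4] * (1 - a)
  }
  out
}

#' Write an RGBA texture or image as 8-bit PNG
#'
#' @param rgba H x W x 4 array in `[0, 1]`.
#' @param path output PNG path.
#' @export
write_texture_png <- function(rgba, path) {
  png::writePNG(rgba, path)
  invisible(path)
}
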