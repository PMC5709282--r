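#' Front-to-back compositing of ray samples
#'
#' Accumulates color and opacity near-to-far: `C <- C + (1-A)*alpha_i*c_i`,
#' `A <- A + (1-A)*alpha_i`, with early exit once `A >= 0.999`. Accumulated
#' opacity is nondecreasing and never exceeds 1.
#'
#' @param samples numeric matrix with columns r, g, b, alpha (one row per
#'   sample, ordered near to far), or a zero-row matrix / NULL for an empty
#'   ray.
#' @return numeric length 4: accumulated (r, g, b, alpha).
#' @export
composite_ray <- function(samples) {
  if (is.null(samples) || NROW(samples) == 0) return(c(0, 0, 0, 0))
  samples <- as.matrix(samples)
  if (ncol(samples) != 4) stop("samples must have columns r,g,b,alpha")
  a <- samples[, 4]
  if (any(a < 0 | a > 1)) stop("opacity outside [0,1]")
  C <- c(0, 0, 0); A <- 0
  for (i in seq_len(nrow(samples))) {
    if (A >= 0.999) break
    w <- (1 - A) * a[i]
    C <- C + w * samples[i, 1:3]
    A <- A + w
  }
  c(C, A)
}

# Per-voxel unit normals from the negated central-difference intensity
# gradient (one-sided at faces). Returned as three arrays plus the gradient
# norm; zero-gradient voxels keep a zero normal (the shader treats them as
# fully lit).
precompute_normals <- function(volume) {
  I <- volume$intensity
  d <- dim(I); s <- volume$spacing
  diffax <- function(ax) {
    n <- d[ax]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    denom <- (hi - lo) * s[ax]
    if (ax == 1) g <- (I[hi, , , drop = FALSE] - I[lo, , , drop = FALSE]) /
        array(denom, d)
    else if (ax == 2) g <- (I[, hi, , drop = FALSE] - I[, lo, , drop = FALSE]) /
        array(rep(denom, each = d[1]), d)
    else g <- (I[, , hi, drop = FALSE] - I[, , lo, drop = FALSE]) /
        array(rep(denom, each = d[1] * d[2]), d)
    g
  }
  gx <- -diffax(1); gy <- -diffax(2); gz <- -diffax(3)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  pos <- nrm > 1e-12
  gx[pos] <- gx[pos] / nrm[pos]; gx[!pos] <- 0
  gy[pos] <- gy[pos] / nrm[pos]; gy[!pos] <- 0
  gz[pos] <- gz[pos] / nrm[pos]; gz[!pos] <- 0
  list(nx = gx, ny = gy, nz = gz)
}

# Vectorized trilinear interpolation of `arr` at continuous 0-based voxel
# coordinates (cx, cy, cz); caller guarantees coordinates inside the grid.
trilinear_sample <- function(arr, cx, cy, cz) {
  d <- dim(arr)
  x0 <- pmin(pmax(floor(cx), 0), d[1] - 2); fx <- cx - x0
  y0 <- pmin(pmax(floor(cy), 0), d[2] - 2); fy <- cy - y0
  z0 <- pmin(pmax(floor(cz), 0), d[3] - 2); fz <- cz - z0
  i0 <- x0 + 1; j0 <- y0 + 1; k0 <- z0 + 1
  g <- function(di, dj, dk) arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(0, 0, 0) + fx * g(1, 0, 0)) +
              fy       * ((1 - fx) * g(0, 1, 0) + fx * g(1, 1, 0))) +
  fz       * ((1 - fy) * ((1 - fx) * g(0, 0, 1) + fx * g(1, 0, 1)) +
              fy       * ((1 - fx) * g(0, 1, 1) + fx * g(1, 1, 1)))
}

# Shared ray-casting engine, vectorized over rays with a loop over steps.
# origins/dirs: n x 3 world coordinates; t runs 0..t_max in steps of `step`.
# Returns rgba (n x 4), first_label (n), and optionally the per-ray
# first-visit occlusion sequences. Compositing stops contributing once
# accumulated alpha reaches 0.999; occlusion recording continues to the end
# of the ray so occluded interior ROIs are still observed.
cast_ray_engine <- function(volume, tf, origins, dirs, t_max, step,
                            visible_labels = NULL, record_occlusion = TRUE,
                            normals = NULL,
                            shading = list(ambient = 0.2, diffuse = 0.6,
                                           specular = 0.2, shininess = 16),
                            occlusion_alpha = 0.01) {
  n <- nrow(origins)
  d <- dim(volume$labels)
  if (is.null(normals)) normals <- precompute_normals(volume)
  n_steps <- floor(t_max / step) + 1L
  C <- matrix(0, n, 3); A <- numeric(n)
  occ_lab <- if (record_occlusion) matrix(0L, n_steps, n)
  first_lab <- integer(n)
  ox <- origins[, 1]; oy <- origins[, 2]; oz <- origins[, 3]
  dx <- dirs[, 1]; dy <- dirs[, 2]; dz <- dirs[, 3]
  o0 <- volume$origin; sp <- volume$spacing
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * step
    cx <- (ox + t * dx - o0[1]) / sp[1]
    cy <- (oy + t * dy - o0[2]) / sp[2]
    cz <- (oz + t * dz - o0[3]) / sp[3]
    valid <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 &
             cz >= 0 & cz <= d[3] - 1
    if (!any(valid)) next
    vi <- which(valid)
    lab <- integer(n)
    lab[vi] <- volume$labels[cbind(round(cx[vi]) + 1, round(cy[vi]) + 1,
                                   round(cz[vi]) + 1)]
    intens <- numeric(n)
    intens[vi] <- trilinear_sample(volume$intensity, cx[vi], cy[vi], cz[vi])
    ev <- tf_eval(tf, intens[vi], lab[vi], visible_labels)
    alpha <- numeric(n); alpha[vi] <- ev$alpha
    # Blinn-Phong headlight: light and half-vector along -ray direction
    nx <- trilinear_sample(normals$nx, cx[vi], cy[vi], cz[vi])
    ny <- trilinear_sample(normals$ny, cx[vi], cy[vi], cz[vi])
    nz <- trilinear_sample(normals$nz, cx[vi], cy[vi], cz[vi])
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    ndl <- numeric(length(vi))
    posn <- nn > 1e-8
    ndl[posn] <- pmax(0, -(nx[posn] * dx[vi][posn] + ny[posn] * dy[vi][posn] +
                           nz[posn] * dz[vi][posn]) / nn[posn])
    ndl[!posn] <- 1  # flat region: fully lit
    diffuse <- shading$ambient + shading$diffuse * ndl
    specular <- shading$specular * ndl^shading$shininess
    shaded <- ev$color * diffuse + specular
    live <- A < 0.999
    w <- numeric(n)
    w[vi] <- alpha[vi] * (1 - A[vi]) * live[vi]
    C[vi, ] <- C[vi, ] + shaded * w[vi]
    A <- A + w
    if (record_occlusion) {
      ol <- integer(n)
      hit <- vi[alpha[vi] > occlusion_alpha & lab[vi] > 0]
      ol[hit] <- lab[hit]
      occ_lab[k, ] <- ol
      newfirst <- first_lab == 0L & ol != 0L
      first_lab[newfirst] <- ol[newfirst]
    }
  }
  res <- list(rgba = cbind(pmin(C, 1), pmin(A, 1)), first_label = first_lab)
  if (record_occlusion) {
    seqs <- vector("list", n)
    touched <- which(colSums(occ_lab != 0L) > 0L)
    seqs[touched] <- lapply(touched, function(j) {
      s <- occ_lab[, j]
      s <- s[s != 0L]
      s[!duplicated(s)]
    })
    empty <- setdiff(seq_len(n), touched)
    seqs[empty] <- list(integer(0))
    res$occlusion <- seqs
  }
  res
}

# Ray geometry for a camera at given lat/lon angles: origins, directions and
# the sampling range. Inward rays run surface -> center (length = radius);
# outward rays run center -> surface and beyond to the volume bounding box.
camera_rays <- function(volume, camera, lat, lon) {
  u <- latlon_to_direction(lat, lon)
  if (camera$direction == "inward") {
    origins <- sweep(u * camera$radius, 2, camera$center, "+")
    dirs <- -u
    t_max <- camera$radius
  } else {
    origins <- matrix(rep(camera$center, each = length(lat)), ncol = 3)
    dirs <- u
    d <- dim(volume$labels)
    corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                     c(0, d[3] - 1)))
    cw <- voxel_to_world(volume, corners)
    dmax <- sqrt(max(rowSums(sweep(cw, 2, camera$center, "-")^2)))
    t_max <- max(camera$radius, dmax)
  }
  list(origins = origins, dirs = dirs, t_max = t_max)
}

#' Cast a single spherical ray
#'
#' Casts the ray belonging to camera grid point (lat, lon): inward from the
#' sphere surface toward the center, or outward from the center toward the
#' surface point. Samples are taken at a fixed step (default half the
#' smallest voxel spacing): trilinear intensity, nearest-voxel label,
#' Blinn-Phong headlight shading, front-to-back compositing. The occlusion
#' sequence lists distinct nonzero labels in first-visit order whose sampled
#' opacity exceeds 0.01.
#'
#' @param volume a [labeled_volume()].
#' @param camera a [spherical_camera()].
#' @param tf a [transfer_function()].
#' @param lat,lon scalar angles (radians).
#' @param visible_labels optional integer vector; labels outside it are
#'   transparent.
#' @param step sampling step in mm.
#' @return list with `rgba` (length 4) and `occlusion` (integer vector).
#' @export
cast_ray <- function(volume, camera, tf, lat, lon, visible_labels = NULL,
                     step = 0.5 * min(volume$spacing)) {
  rg <- camera_rays(volume, camera, lat, lon)
  r <- cast_ray_engine(volume, tf, rg$origins, rg$dirs, rg$t_max, step,
                       visible_labels = visible_labels)
  list(rgba = as.numeric(r$rgba[1, ]), occlusion = r$occlusion[[1]])
}

#' Cast rays on the camera's latitude-longitude grid
#'
#' Casts one ray per (lat, lon) grid point of the camera (latitudes strictly
#' inside the poles, longitudes in `[-pi, pi)`), returning the per-ray RGBA
#' and occlusion sequences. This is the sampling used to build occlusion
#' graphs independently of any map raster.
#'
#' @inheritParams cast_ray
#' @return list with `rgba` (n x 4), `first_label` (n), `occlusion` (list of
#'   integer vectors), `lat`, `lon` (the grid angles, row-major lat-by-lon).
#' @export
cast_camera_grid <- function(volume, camera, tf, visible_labels = NULL,
                             step = 0.5 * min(volume$spacing)) {
  lat <- (seq_len(camera$n_lat) - 0.5) / camera$n_lat * pi - pi / 2
  lon <- (seq_len(camera$n_lon) - 0.5) / camera$n_lon * 2 * pi - pi
  g <- expand.grid(lat = lat, lon = lon)
  rg <- camera_rays(volume, camera, g$lat, g$lon)
  r <- cast_ray_engine(volume, tf, rg$origins, rg$dirs, rg$t_max, step,
                       visible_labels = visible_labels)
  list(rgba = r$rgba, first_label = r$first_label, occlusion = r$occlusion,
       lat = g$lat, lon = g$lon)
}

#' Render the planar brain map by inverse-mapped spherical ray casting
#'
#' Every pixel inside the Hammer-Aitoff ellipse is mapped back to (lat, lon)
#' and a spherical ray is cast for it (inverse per-pixel mapping leaves no
#' resampling holes). The label raster holds each pixel's front-most ROI
#' (first entry of its occlusion sequence), 0 outside the ellipse or where no
#' ROI is met.
#'
#' @inheritParams cast_ray
#' @param width map width in pixels (>= 16); height is `ceiling(width/2)`.
#' @param chunk number of rays cast per vectorized block (memory knob).
#' @return A `brain_map` object: `rgba` (H x W x 4 array in `[0,1]`),
#'   `label_raster` (H x W integer matrix), `camera`, `layer_index`, and
#'   `records` (occlusion sequences for pixels inside the ellipse).
#' @export
render_map <- function(volume, camera, tf, width = 512,
                       visible_labels = NULL,
                       step = 0.5 * min(volume$spacing), chunk = 32768L) {
  if (width < 16) stop("width must be >= 16")
  height <- as.integer(ceiling(width / 2))
  width <- as.integer(width)
  px <- expand.grid(row = seq_len(height), col = seq_len(width))
  mc <- pixel_to_map(px$row, px$col, width, height)
  ll <- hammer_aitoff_inverse(mc[, 1], mc[, 2])
  inside <- which(!is.na(ll[, 1]))
  rgba <- array(0, c(height, width, 4))
  label_raster <- matrix(0L, height, width)
  records <- vector("list", length(inside))
  normals <- precompute_normals(volume)
  for (start in seq(1, length(inside), by = chunk)) {
    idx <- inside[start:min(start + chunk - 1, length(inside))]
    rg <- camera_rays(volume, camera, ll[idx, 1], ll[idx, 2])
    r <- cast_ray_engine(volume, tf, rg$origins, rg$dirs, rg$t_max, step,
                         visible_labels = visible_labels, normals = normals)
    lin <- cbind(px$row[idx], px$col[idx])
    for (ch in 1:4) rgba[cbind(lin, ch)] <- r$rgba[, ch]
    label_raster[lin] <- r$first_label
    records[start:(start + length(idx) - 1)] <- r$occlusion
  }
  structure(list(rgba = rgba, label_raster = label_raster, camera = camera,
                 layer_index = 1L, records = records),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  ids <- sort(unique(as.integer(x$label_raster)))
  ids <- ids[ids > 0]
  cat(sprintf("brain_map: %d x %d px, layer %d, %d ROIs visible\n",
              nrow(x$label_raster), ncol(x$label_raster),
              x$layer_index, length(ids)))
  invisible(x)
}

#' @export
plot.brain_map <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(x$rgba), 0, 0, 1, 1)
  invisible(x)
}

# Uniform magnification of a brain map about the map center: bilinear
# resampling for color channels, nearest neighbor for the label raster.
scale_map <- function(map, s) {
  if (s == 1) return(map)
  h <- nrow(map$label_raster); w <- ncol(map$label_raster)
  px <- expand.grid(row = seq_len(h), col = seq_len(w))
  mc <- pixel_to_map(px$row, px$col, w, h)
  src <- map_to_pixel(mc[, 1] / s, mc[, 2] / s, w, h)
  rr <- src[, 1]; cc <- src[, 2]
  ok <- rr >= 0.5 & rr <= h + 0.5 & cc >= 0.5 & cc <= w + 0.5
  out_rgba <- array(0, c(h, w, 4))
  out_lab <- matrix(0L, h, w)
  # nearest for labels
  rn <- pmin(pmax(round(rr), 1), h); cn <- pmin(pmax(round(cc), 1), w)
  out_lab[cbind(px$row, px$col)[ok, ]] <-
    map$label_raster[cbind(rn, cn)[ok, , drop = FALSE]]
  # bilinear for rgba
  r0 <- pmin(pmax(floor(rr - 0.5), 0), h - 1); fr <- (rr - 0.5) - r0
  c0 <- pmin(pmax(floor(cc - 0.5), 0), w - 1); fc <- (cc - 0.5) - c0
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  for (ch in 1:4) {
    pl <- map$rgba[, , ch]
    v <- (1 - fr) * ((1 - fc) * pl[cbind(r0 + 1, c0 + 1)] +
                     fc * pl[cbind(r0 + 1, c1 + 1)]) +
         fr * ((1 - fc) * pl[cbind(r1 + 1, c0 + 1)] +
               fc * pl[cbind(r1 + 1, c1 + 1)])
    v[!ok] <- 0
    out_rgba[cbind(px$row, px$col, ch)] <- v
  }
  map$rgba <- out_rgba
  map$label_raster <- out_lab
  map
}

#' Render one brain map per occlusion layer
#'
#' Layer `k` renders only its labels, forced opaque; other labels are fully
#' transparent, so deeper structures become visible in later layers. An
#' optional per-layer scale factor magnifies each map about its center
#' (bilinear for color, nearest neighbor for labels) to counteract the
#' enlargement of interior ROIs by inward spherical projection.
#'
#' @inheritParams render_map
#' @param layers a [layer_assignment()] covering every nonzero label present
#'   in the volume.
#' @return list of `brain_map` objects, one per layer, `layer_index` set.
#' @export
render_layered_maps <- function(volume, camera, tf, width, layers,
                                step = 0.5 * min(volume$spacing)) {
  present <- sort(unique(as.integer(volume$labels)))
  present <- present[present > 0]
  miss <- setdiff(present, as.integer(names(layers$layer)))
  if (length(miss))
    stop(sprintf("labels with no layer assignment: %s",
                 paste(miss, collapse = ", ")))
  ks <- sort(unique(layers$layer))
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    vis <- as.integer(names(layers$layer)[layers$layer == k])
    tfk <- tf_force_opaque(tf, vis)
    m <- render_map(volume, camera, tfk, width, visible_labels = vis,
                    step = step)
    sc <- if (!is.null(layers$scale)) layers$scale[as.character(k)] else 1
    if (is.null(sc) || is.na(sc)) sc <- 1
    m <- scale_map(m, sc)
    m$layer_index <- as.integer(k)
    out[[i]] <- m
  }
  out
}
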