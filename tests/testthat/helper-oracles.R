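# Independent brute-force oracles, written as literal loops separate from the
# package's vectorized rendering path.

# Trilinear interpolation by explicit 8-corner loop (0-based coords).
oracle_trilinear <- function(arr, p) {
  d <- dim(arr)
  x0 <- min(max(floor(p[1]), 0), d[1] - 2)
  y0 <- min(max(floor(p[2]), 0), d[2] - 2)
  z0 <- min(max(floor(p[3]), 0), d[3] - 2)
  f <- p - c(x0, y0, z0)
  acc <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    w <- (if (i) f[1] else 1 - f[1]) * (if (j) f[2] else 1 - f[2]) *
         (if (k) f[3] else 1 - f[3])
    acc <- acc + w * arr[x0 + i + 1, y0 + j + 1, z0 + k + 1]
  }
  acc
}

# Per-voxel unit normal at integer voxel v (0-based) from central differences
# of intensity (one-sided at faces), negated and normalized.
oracle_voxel_normal <- function(vol, v) {
  d <- dim(vol$intensity)
  g <- numeric(3)
  for (ax in 1:3) {
    hi <- min(v[ax] + 1, d[ax] - 1); lo <- max(v[ax] - 1, 0)
    ih <- v; ih[ax] <- hi; il <- v; il[ax] <- lo
    g[ax] <- (vol$intensity[ih[1] + 1, ih[2] + 1, ih[3] + 1] -
              vol$intensity[il[1] + 1, il[2] + 1, il[3] + 1]) /
             ((hi - lo) * vol$spacing[ax])
  }
  g <- -g
  n <- sqrt(sum(g^2))
  if (n > 1e-12) g / n else c(0, 0, 0)
}

# Literal per-sample ray oracle: walks the inward ray for camera grid point
# (lat, lon), recomputing sampling, piecewise-linear transfer evaluation,
# Blinn-Phong headlight shading and front-to-back compositing step by step.
oracle_cast_ray <- function(vol, cam, tf, lat, lon, step) {
  u <- c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  if (cam$direction == "inward") {
    origin <- cam$center + cam$radius * u
    dirv <- -u
    t_max <- cam$radius
  } else stop("oracle handles inward rays")
  d <- dim(vol$labels)
  C <- c(0, 0, 0); A <- 0
  occ <- integer(0)
  n_steps <- floor(t_max / step) + 1
  for (k in seq_len(n_steps)) {
    p <- origin + (k - 1) * step * dirv
    cvox <- (p - vol$origin) / vol$spacing
    if (any(cvox < 0) || any(cvox > d - 1)) next
    v <- round(cvox)
    lab <- vol$labels[v[1] + 1, v[2] + 1, v[3] + 1]
    intens <- oracle_trilinear(vol$intensity, cvox)
    # transfer evaluation: label override else intensity ramp
    has <- !is.null(tf$label_colors) && lab > 0 &&
      as.character(lab) %in% rownames(tf$label_colors)
    if (has) {
      alpha <- unname(tf$label_opacities[as.character(lab)])
      col <- tf$label_colors[as.character(lab), ]
    } else {
      alpha <- stats::approx(tf$breaks, tf$opacities, intens, rule = 2)$y
      col <- c(stats::approx(tf$breaks, tf$colors[, 1], intens, rule = 2)$y,
               stats::approx(tf$breaks, tf$colors[, 2], intens, rule = 2)$y,
               stats::approx(tf$breaks, tf$colors[, 3], intens, rule = 2)$y)
    }
    # shading: interpolate per-voxel normals of the 8 surrounding voxels
    x0 <- min(max(floor(cvox[1]), 0), d[1] - 2)
    y0 <- min(max(floor(cvox[2]), 0), d[2] - 2)
    z0 <- min(max(floor(cvox[3]), 0), d[3] - 2)
    f <- cvox - c(x0, y0, z0)
    nv <- c(0, 0, 0)
    for (i in 0:1) for (j in 0:1) for (kk in 0:1) {
      w <- (if (i) f[1] else 1 - f[1]) * (if (j) f[2] else 1 - f[2]) *
           (if (kk) f[3] else 1 - f[3])
      nv <- nv + w * oracle_voxel_normal(vol, c(x0 + i, y0 + j, z0 + kk))
    }
    nn <- sqrt(sum(nv^2))
    ndl <- if (nn > 1e-8) max(0, -sum(nv * dirv) / nn) else 1
    shaded <- col * (0.2 + 0.6 * ndl) + 0.2 * ndl^16
    if (lab > 0 && alpha > 0.01 && !(lab %in% occ)) occ <- c(occ, lab)
    if (A < 0.999) {
      w <- (1 - A) * alpha
      C <- C + w * shaded
      A <- A + w
    }
  }
  list(rgba = unname(c(pmin(C, 1), min(A, 1))), occlusion = occ)
}

# First-intersection ray-march: the first nonzero label met along the inward
# ray for a map pixel, using nearest-voxel lookup at the same fixed step.
oracle_first_hit <- function(vol, cam, lat, lon, step) {
  u <- c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  origin <- cam$center + cam$radius * u
  d <- dim(vol$labels)
  n_steps <- floor(cam$radius / step) + 1
  t <- (seq_len(n_steps) - 1) * step
  px <- origin[1] - t * u[1]; py <- origin[2] - t * u[2]
  pz <- origin[3] - t * u[3]
  vx <- round((px - vol$origin[1]) / vol$spacing[1])
  vy <- round((py - vol$origin[2]) / vol$spacing[2])
  vz <- round((pz - vol$origin[3]) / vol$spacing[3])
  ok <- vx >= 0 & vx <= d[1] - 1 & vy >= 0 & vy <= d[2] - 1 &
        vz >= 0 & vz <= d[3] - 1
  labs <- integer(n_steps)
  labs[ok] <- vol$labels[cbind(vx[ok], vy[ok], vz[ok]) + 1]
  hit <- which(labs > 0)
  if (length(hit)) labs[hit[1]] else 0L
}

# Label raster oracle for a whole map (opaque labels).
oracle_label_raster <- function(vol, cam, width, step) {
  height <- as.integer(ceiling(width / 2))
  out <- matrix(0L, height, width)
  for (r in seq_len(height)) for (cl in seq_len(width)) {
    xy <- pixel_to_map(r, cl, width, height)
    ll <- hammer_aitoff_inverse(xy[1], xy[2])
    if (is.na(ll[1])) next
    out[r, cl] <- oracle_first_hit(vol, cam, ll[1], ll[2], step)
  }
  out
}

# Brute-force two-pass Pearson covariance/correlation oracle.
oracle_correlation <- function(values) {
  n <- nrow(values); T_ <- ncol(values)
  mu <- numeric(n); s <- numeric(n)
  for (i in seq_len(n)) mu[i] <- sum(values[i, ]) / T_
  for (i in seq_len(n)) s[i] <- sqrt(sum((values[i, ] - mu[i])^2))
  R <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    R[i, j] <- sum((values[i, ] - mu[i]) * (values[j, ] - mu[j])) /
               (s[i] * s[j])
  }
  R
}

# Repeated-erosion depth oracle: erosion depth of each mask pixel under the
# 3x3 full-square element, by literal neighborhood loops.
oracle_erosion_depth <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  depth <- matrix(-1L, h, w)
  cur <- mask
  lev <- 0L
  while (any(cur)) {
    nxt <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      if (!cur[r, cl]) next
      keep <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w || !cur[rr, cc])
          keep <- FALSE
      }
      nxt[r, cl] <- keep
    }
    ring <- cur & !nxt
    depth[ring] <- lev
    cur <- nxt
    lev <- lev + 1L
  }
  depth
}

# Random DAG generator: edges only from lower to higher positions of a
# random permutation, random positive integer weights.
random_dag <- function(n, p = 0.35) {
  perm <- sample.int(n)
  W <- matrix(0, n, n, dimnames = list(seq_len(n), seq_len(n)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p)
      W[perm[i], perm[j]] <- sample.int(20, 1)
  }
  structure(list(nodes = seq_len(n), weights = W), class = "occlusion_graph")
}
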