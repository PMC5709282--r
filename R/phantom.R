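#' Specification for the two-shell phantom
#'
#' The phantom is a cubic grid holding two concentric spherical structures:
#' an outer cortical shell band partitioned into `n_cortical` angular-Voronoi
#' ROIs and an inner subcortical core ball partitioned into `n_subcortical`
#' ROIs. The outer shell covers the full solid angle, so every inner ROI is
#' occluded by outer ROIs along every radial ray — guaranteeing at least two
#' depth layers for layer-sorting.
#'
#' @param grid cubic edge length in voxels (>= 16).
#' @param n_cortical number of outer-shell ROIs (>= 1).
#' @param n_subcortical number of inner-core ROIs (>= 0).
#' @param shell_radii length-2 fractions of the half-grid: outer shell outer
#'   radius, inner core radius; `0 < inner < outer <= 1`.
#' @param shell_width outer shell band thickness as a fraction of the
#'   half-grid.
#' @param seed integer RNG seed; all phantom outputs are pure functions of
#'   the spec including the seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid = 64L, n_cortical = 16L, n_subcortical = 6L,
                         shell_radii = c(outer = 0.85, inner = 0.45),
                         shell_width = 0.2, inner_width = 0.2, seed = 1L) {
  if (grid < 16) stop("grid must be >= 16")
  if (n_cortical < 1) stop("n_cortical must be >= 1")
  if (n_subcortical < 0) stop("n_subcortical must be >= 0")
  outer <- shell_radii[[1]]; inner <- shell_radii[[2]]
  if (!(inner > 0 && inner < outer && outer <= 1))
    stop("need 0 < inner radius < outer radius <= 1")
  if (shell_width <= 0 || outer - shell_width <= inner)
    stop("shell_width must leave a gap above the inner core")
  if (inner_width <= 0 || inner_width >= inner)
    stop("inner_width must be in (0, inner radius)")
  structure(list(grid = as.integer(grid), n_cortical = as.integer(n_cortical),
                 n_subcortical = as.integer(n_subcortical),
                 outer = outer, inner = inner, shell_width = shell_width,
                 inner_width = inner_width, seed = as.integer(seed)),
            class = "phantom_spec")
}

# n well-spread unit vectors: seeded best-candidate (Mitchell) sampling --
# each new seed is the candidate maximizing its minimum angle to the
# existing seeds. Deterministic under the caller's seed; keeps parcels far
# enough apart that the separation margins cannot empty one.
spread_sphere_seeds <- function(n, n_candidates = 64L) {
  one <- function() {
    z <- stats::runif(1, -1, 1); t <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(max(0, 1 - z^2))
    c(r * cos(t), r * sin(t), z)
  }
  seeds <- matrix(one(), 1)
  while (nrow(seeds) < n) {
    cand <- t(replicate(n_candidates, one()))
    dots <- cand %*% t(seeds)
    best <- which.min(apply(dots, 1, max))  # max min-angle = min max-cosine
    seeds <- rbind(seeds, cand[best, ])
  }
  seeds
}

# Angular distance to the nearest seed and half-distance to the Voronoi
# bisector, for unit direction rows `u`: a1 = angle to nearest seed,
# delta = (a2 - a1)/2 (Inf with a single seed).
angular_margin <- function(u, seeds) {
  ang <- u %*% t(seeds)
  ang <- acos(pmin(1, pmax(-1, ang)))
  dim(ang) <- c(nrow(u), nrow(seeds))
  if (ncol(ang) == 1)
    return(list(nearest = rep(1L, nrow(u)), delta = rep(Inf, nrow(u))))
  ord1 <- max.col(-ang, ties.method = "first")
  a1 <- ang[cbind(seq_len(nrow(ang)), ord1)]
  ang[cbind(seq_len(nrow(ang)), ord1)] <- Inf
  a2 <- ang[cbind(seq_len(nrow(ang)), max.col(-ang, ties.method = "first"))]
  list(nearest = ord1, delta = (a2 - a1) / 2)
}

#' Generate the labeled two-shell phantom volume
#'
#' Seeds `n_cortical` well-spread directions for the outer shell band and
#' `n_subcortical` for the inner band, then assigns shell-band voxels to
#' their nearest same-shell seed by angular distance (spherical Voronoi
#' bands) -- but only where the direction clears a separation margin from
#' the Voronoi bisector. The margin equals the nearest-voxel flip radius of
#' the renderer (half a voxel diagonal plus camera-centering slack, divided
#' by the band's inner radius), so no spherical ray can sample two
#' same-shell parcels: parcels are separated by thin background gaps, like
#' sulci between cortical regions. Inner-band voxels are additionally kept
#' only beneath outer-parcel cores, so every inner voxel's radial ray is
#' guaranteed to cross an outer ROI first -- at least two occlusion layers
#' by construction, with an exactly known layering.
#'
#' Intensity is a smooth radial gradient plus a small per-label offset plus
#' seeded Gaussian noise (sd = 0.02 of the intensity range). Labels
#' 1..n_cortical are cortical ("outer"); the rest subcortical ("inner").
#' Deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [labeled_volume()], spacing 1 mm, origin 0)
#'   and `roi` (its [roi_table()], with `shell` column "outer"/"inner").
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    g <- spec$grid
    half <- (g - 1) / 2
    ctr <- rep(half, 3)
    ax <- seq_len(g) - 1
    X <- array(rep(ax, times = g * g), c(g, g, g)) - ctr[1]
    Y <- array(rep(rep(ax, each = g), times = g), c(g, g, g)) - ctr[2]
    Z <- array(rep(ax, each = g * g), c(g, g, g)) - ctr[3]
    R <- sqrt(X^2 + Y^2 + Z^2)
    rfrac <- R / half
    outer_band <- rfrac <= spec$outer & rfrac >= spec$outer - spec$shell_width
    inner_band <- rfrac <= spec$inner & rfrac >= spec$inner - spec$inner_width
    seeds_out <- spread_sphere_seeds(spec$n_cortical)
    seeds_in <- if (spec$n_subcortical > 0)
      spread_sphere_seeds(spec$n_subcortical)
    # nearest-voxel flip radius at each band's inner radius (voxel units):
    # half a voxel diagonal + slack for the data-driven camera center
    flip <- function(r_min) (sqrt(3) / 2 + 0.7) / r_min
    m_out <- 1.15 * flip((spec$outer - spec$shell_width) * half)
    m_in <- 1.15 * flip((spec$inner - spec$inner_width) * half)
    labels <- array(0L, c(g, g, g))
    idx_o <- which(outer_band)
    u_o <- cbind(X[idx_o], Y[idx_o], Z[idx_o]) / R[idx_o]
    am_o <- angular_margin(u_o, seeds_out)
    keep <- am_o$delta > m_out
    labels[idx_o[keep]] <- am_o$nearest[keep]
    if (spec$n_subcortical > 0) {
      idx_i <- which(inner_band)
      u_i <- cbind(X[idx_i], Y[idx_i], Z[idx_i]) / R[idx_i]
      am_i <- angular_margin(u_i, seeds_in)
      under <- angular_margin(u_i, seeds_out)  # enclosure by outer cores
      keep <- am_i$delta > m_in & under$delta > 2 * m_out
      labels[idx_i[keep]] <- spec$n_cortical + am_i$nearest[keep]
    }
    n_roi <- spec$n_cortical + spec$n_subcortical
    counts <- tabulate(labels[labels > 0L], nbins = n_roi)
    if (any(counts == 0))
      stop(sprintf("ROI counts too large for grid: label %d is empty",
                   which(counts == 0)[1]))
    intensity <- 1 - pmin(rfrac, 1)                        # radial gradient
    off <- c(0, seq_len(n_roi) / n_roi * 0.3)
    intensity <- intensity + off[labels + 1L]              # label offset
    intensity <- intensity +
      stats::rnorm(length(intensity), sd = 0.02 * diff(range(intensity)))
    vol <- labeled_volume(intensity, labels)
    roi <- roi_table(vol)
    roi$shell <- ifelse(roi$label <= spec$n_cortical, "outer", "inner")
    list(volume = vol, roi = roi)
  })
}

#' Generate synthetic fibers with known endpoint-pair ground truth
#'
#' Each fiber picks an ROI pair with seeded non-uniform probabilities (so
#' pair counts differ), one voxel of each ROI as its endpoints (endpoints are
#' exact voxel centers, hence guaranteed inside the ROI under nearest-voxel
#' lookup), and connects them by a 3-point quadratic arc bowed toward the
#' volume center, densified to about one-voxel steps.
#'
#' @param volume a [labeled_volume()] with >= 2 ROIs.
#' @param roi its [roi_table()].
#' @param n_fibers number of fibers (>= 0).
#' @param seed integer seed.
#' @param bow fraction by which the arc midpoint is pulled toward the volume
#'   center.
#' @return list with `fibers` (a `fiber_set`: list of n x 3 world-coordinate
#'   polylines) and `truth` (list with symmetric integer `pair_counts`
#'   matrix, dimnames = label ids).
#' @export
make_fibers <- function(volume, roi, n_fibers, seed = 1L, bow = 0.35) {
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  ids <- roi$label
  if (length(ids) < 2) stop("need >= 2 ROIs to generate fibers")
  withr::with_seed(seed, {
    pairs <- utils::combn(seq_along(ids), 2)
    pw <- stats::runif(ncol(pairs))^2
    pw <- pw / sum(pw)
    pick <- if (n_fibers > 0)
      sample.int(ncol(pairs), n_fibers, replace = TRUE, prob = pw)
    else integer(0)
    vox_by_label <- lapply(ids, function(l) {
      idx <- which(volume$labels == l)
      arrayInd(idx, dim(volume$labels)) - 1
    })
    d <- dim(volume$labels)
    ctr_world <- voxel_to_world(volume, matrix((d - 1) / 2, 1))
    fibers <- vector("list", n_fibers)
    pc <- matrix(0L, length(ids), length(ids),
                 dimnames = list(ids, ids))
    for (f in seq_len(n_fibers)) {
      a <- pairs[1, pick[f]]; b <- pairs[2, pick[f]]
      va <- vox_by_label[[a]]; vb <- vox_by_label[[b]]
      p0 <- voxel_to_world(volume, va[sample.int(nrow(va), 1), , drop = FALSE])
      p1 <- voxel_to_world(volume, vb[sample.int(nrow(vb), 1), , drop = FALSE])
      mid <- (p0 + p1) / 2
      pm <- mid + bow * (ctr_world - mid)
      len <- sqrt(sum((p1 - p0)^2))
      nseg <- max(2L, ceiling(len / min(volume$spacing)))
      t <- seq(0, 1, length.out = nseg + 1)
      # quadratic Bezier through p0, pm, p1; endpoints exact
      B <- outer((1 - t)^2, p0[1, ]) + outer(2 * (1 - t) * t, pm[1, ]) +
           outer(t^2, p1[1, ])
      B[1, ] <- p0; B[nseg + 1, ] <- p1
      fibers[[f]] <- B
      pc[a, b] <- pc[a, b] + 1L; pc[b, a] <- pc[b, a] + 1L
    }
    list(fibers = structure(fibers, class = "fiber_set"),
         truth = list(pair_counts = pc))
  })
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("fiber_set: %d fibers, %d points total\n", length(x),
              sum(vapply(x, nrow, 0L))))
  invisible(x)
}

#' Generate block-correlated ROI time series
#'
#' ROIs are partitioned round-robin into `n_blocks` communities; each ROI's
#' series is `sqrt(rho)` times a shared community signal plus `sqrt(1-rho)`
#' times a private signal (both i.i.d. standard Gaussian over time), then
#' z-scored per ROI. Expected within-community correlation is `rho`,
#' between-community 0.
#'
#' @param roi a [roi_table()].
#' @param n_time number of time points (>= 2); 632 matches a typical
#'   processed resting-state acquisition length.
#' @param n_blocks number of communities.
#' @param rho target within-community correlation in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `series` (a `timeseries_set`: list with `values`
#'   ROI x time matrix, `roi_ids`) and `truth` (list with `block_assignment`
#'   named by label, `block_rho`).
#' @export
make_timeseries <- function(roi, n_time = 632L, n_blocks = 2L, rho = 0.8,
                            seed = 1L) {
  if (n_time < 2) stop("n_time must be >= 2")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  ids <- sort(roi$label)
  withr::with_seed(seed, {
    block <- ((seq_along(ids) - 1) %% n_blocks) + 1L
    names(block) <- ids
    shared <- matrix(stats::rnorm(n_blocks * n_time), n_blocks, n_time)
    private <- matrix(stats::rnorm(length(ids) * n_time), length(ids), n_time)
    v <- sqrt(rho) * shared[block, , drop = FALSE] + sqrt(1 - rho) * private
    v <- t(apply(v, 1, function(x) (x - mean(x)) / stats::sd(x)))
    rownames(v) <- ids
    list(series = timeseries_set(v, ids),
         truth = list(block_assignment = block, block_rho = rho))
  })
}

#' Construct a time-series set
#'
#' @param values ROI x time numeric matrix (no missing values).
#' @param roi_ids integer ids aligned with rows.
#' @return A `timeseries_set`.
#' @export
timeseries_set <- function(values, roi_ids) {
  values <- as.matrix(values)
  if (nrow(values) != length(roi_ids))
    stop("row count must equal number of roi_ids")
  if (ncol(values) < 2) stop("need at least 2 time points")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(values = values, roi_ids = as.integer(roi_ids),
                 n_time = ncol(values)),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("timeseries_set: %d ROIs x %d time points\n",
              nrow(x$values), x$n_time))
  invisible(x)
}

#' Generate per-class ROI attributes with a known dominant class
#'
#' Emulates per-class network measures (e.g. node degree averaged within a
#' diagnostic class). Every ROI receives nonnegative values for each class
#' with one designated dominant class at least 1.5 times every other value,
#' giving discriminative textures a known ground truth.
#'
#' @param roi a [roi_table()].
#' @param n_class number of classes (>= 2).
#' @param seed integer seed.
#' @return data.frame: `label`, `dominant`, and one `class_<k>` column per
#'   class (values >= 0).
#' @export
make_class_attributes <- function(roi, n_class = 3L, seed = 1L) {
  if (n_class < 2) stop("n_class must be >= 2")
  ids <- sort(roi$label)
  withr::with_seed(seed, {
    vals <- matrix(stats::runif(length(ids) * n_class, 0.2, 0.6),
                   length(ids), n_class)
    dom <- sample.int(n_class, length(ids), replace = TRUE)
    for (i in seq_along(ids)) {
      others <- max(vals[i, -dom[i]])
      vals[i, dom[i]] <- 1.5 * others * stats::runif(1, 1.05, 1.3)
    }
    out <- data.frame(label = ids, dominant = dom)
    for (k in seq_len(n_class)) out[[sprintf("class_%d", k)]] <- vals[, k]
    out
  })
}
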