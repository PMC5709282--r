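#' Spherical camera enclosing (or inside) the volume
#'
#' The camera is a latitude-longitude sphere. For inward rendering, rays start
#' on the sphere surface and travel to the center; for outward rendering
#' (interior viewpoint) rays start at the center and travel toward each
#' (lat, lon) surface point, showing interior surfaces.
#'
#' @param center world point (mm), length 3.
#' @param radius sphere radius in mm, > 0.
#' @param n_lat,n_lon resolution of the lat/lon grid used when casting rays on
#'   the spherical grid directly (map rendering derives its own rays per
#'   pixel).
#' @param direction `"inward"` or `"outward"`.
#' @return A `spherical_camera` object.
#' @export
spherical_camera <- function(center, radius, n_lat = 512, n_lon = 1024,
                             direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be 3 finite values")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (n_lat < 2 || n_lon < 2) stop("grid resolution must be >= 2")
  structure(list(center = center, radius = radius,
                 n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 direction = direction),
            class = "spherical_camera")
}

#' @export
print.spherical_camera <- function(x, ...) {
  cat(sprintf("spherical_camera: center (%s) mm, radius %.3f mm, %dx%d grid, %s rays\n",
              paste(format(x$center, digits = 4), collapse = ", "),
              x$radius, x$n_lat, x$n_lon, x$direction))
  invisible(x)
}

#' Default camera for a labeled volume
#'
#' Center = world centroid of all labeled (nonzero) voxels, which preserves
#' left/right symmetry for symmetric anatomy; radius = 1.05 times the largest
#' center-to-labeled-voxel distance, so every labeled voxel lies strictly
#' inside the sphere.
#'
#' @param volume a [labeled_volume()] with at least one nonzero label.
#' @param n_lat,n_lon,direction passed to [spherical_camera()].
#' @return A [spherical_camera()].
#' @export
default_camera <- function(volume, n_lat = 512, n_lon = 1024,
                           direction = "inward") {
  idx <- which(volume$labels > 0L)
  if (length(idx) == 0L) stop("volume has no labeled voxels")
  ijk <- arrayInd(idx, dim(volume$labels)) - 1
  w <- voxel_to_world(volume, ijk)
  center <- colMeans(w)
  dmax <- sqrt(max(rowSums(sweep(w, 2, center, "-")^2)))
  if (dmax == 0) dmax <- max(volume$spacing)  # single labeled voxel
  spherical_camera(center, 1.05 * dmax, n_lat = n_lat, n_lon = n_lon,
                   direction = direction)
}
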