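#' Hammer-Aitoff equal-area projection (forward)
#'
#' Maps latitude/longitude on the sphere to a point inside the 2:1 ellipse
#' `x^2/8 + y^2/2 <= 1`. With `g = sqrt(1 + cos(lat) * cos(lon/2))`:
#' `x = 2*sqrt(2)*cos(lat)*sin(lon/2)/g`, `y = sqrt(2)*sin(lat)/g`.
#' The projection preserves areas but not angles, so equal solid angles on
#' the camera sphere occupy equal map area.
#'
#' @param lat latitude in radians, in `[-pi/2, pi/2]`.
#' @param lon longitude in radians, in `[-pi, pi)`.
#' @return n x 2 matrix of map coordinates (columns `x`, `y`).
#' @export
hammer_aitoff_forward <- function(lat, lon) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("lat/lon must be finite")
  if (any(lat < -pi / 2 - 1e-12 | lat > pi / 2 + 1e-12))
    stop("lat out of range [-pi/2, pi/2]")
  if (any(lon < -pi - 1e-12 | lon >= pi + 1e-12))
    stop("lon out of range [-pi, pi)")
  g <- sqrt(1 + cos(lat) * cos(lon / 2))
  cbind(x = 2 * sqrt(2) * cos(lat) * sin(lon / 2) / g,
        y = sqrt(2) * sin(lat) / g)
}

#' Hammer-Aitoff projection (inverse)
#'
#' Standard closed-form inverse: `z = sqrt(1 - (x/4)^2 - (y/2)^2)`,
#' `lon = 2*atan2(z*x, 2*(2*z^2 - 1))`, `lat = asin(z*y)`. Points outside the
#' ellipse return `NA` for both angles (the renderer paints background there).
#'
#' @param x,y map coordinates, `x` in `[-2*sqrt(2), 2*sqrt(2)]`, `y` in
#'   `[-sqrt(2), sqrt(2)]`.
#' @return n x 2 matrix with columns `lat`, `lon` (`NA` outside the ellipse).
#' @export
hammer_aitoff_inverse <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  inside <- x^2 / 8 + y^2 / 2 < 1
  lat <- rep(NA_real_, length(x)); lon <- rep(NA_real_, length(x))
  if (any(inside)) {
    xi <- x[inside]; yi <- y[inside]
    z <- sqrt(1 - (xi / 4)^2 - (yi / 2)^2)
    lon[inside] <- 2 * atan2(z * xi, 2 * (2 * z^2 - 1))
    lat[inside] <- asin(pmin(1, pmax(-1, z * yi)))
  }
  cbind(lat = lat, lon = lon)
}

#' Map-coordinate to pixel-raster conversion
#'
#' Map coordinates span `x` in `[-2*sqrt(2), 2*sqrt(2)]` and `y` in
#' `[-sqrt(2), sqrt(2)]`; they scale uniformly to a `height x width` raster
#' with row 1 at the top (`y` decreasing with row, `x` increasing with
#' column). Pixel centers sit at half-integer offsets.
#'
#' @param row,col 1-based pixel indices (centers).
#' @param width,height raster size in pixels (`height = ceiling(width/2)`).
#' @return n x 2 matrix of map coordinates.
#' @export
pixel_to_map <- function(row, col, width, height) {
  sx <- 4 * sqrt(2) / width
  sy <- 2 * sqrt(2) / height
  cbind(x = -2 * sqrt(2) + (col - 0.5) * sx,
        y = sqrt(2) - (row - 0.5) * sy)
}

#' @rdname pixel_to_map
#' @param x,y map coordinates.
#' @return For `map_to_pixel`: n x 2 matrix of fractional (row, col)
#'   positions (1-based pixel centers at integers).
#' @export
map_to_pixel <- function(x, y, width, height) {
  sx <- 4 * sqrt(2) / width
  sy <- 2 * sqrt(2) / height
  cbind(row = (sqrt(2) - y) / sy + 0.5,
        col = (x + 2 * sqrt(2)) / sx + 0.5)
}

#' Spherical direction for latitude/longitude
#'
#' Unit vectors with the north pole (+z) at `lat = pi/2` and `lon = 0` on the
#' +x axis: `(cos(lat)cos(lon), cos(lat)sin(lon), sin(lat))`.
#'
#' @inheritParams hammer_aitoff_forward
#' @return n x 3 matrix of unit vectors.
#' @export
latlon_to_direction <- function(lat, lon) {
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

#' @rdname latlon_to_direction
#' @param dirs n x 3 matrix of nonzero direction vectors.
#' @return For `direction_to_latlon`: n x 2 matrix with columns `lat`, `lon`.
#' @export
direction_to_latlon <- function(dirs) {
  dirs <- rbind_points(dirs)
  n <- sqrt(rowSums(dirs^2))
  if (any(n == 0)) stop("zero-length direction")
  cbind(lat = asin(pmin(1, pmax(-1, dirs[, 3] / n))),
        lon = atan2(dirs[, 2], dirs[, 1]))
}
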