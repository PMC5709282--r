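#' Labeled volume: co-registered intensity and ROI label grids
#'
#' Bundles a scalar intensity grid with an integer region-of-interest (ROI)
#' label grid on the same voxel lattice. The label grid is authoritative for
#' geometry; intensity is used for shading only. Voxel indexing is 0-based and
#' a voxel's world position is its center: `world = origin + index * spacing`,
#' applied per axis.
#'
#' @param intensity 3D numeric array of finite values (arbitrary units).
#' @param labels 3D array of nonnegative integers, same shape as `intensity`;
#'   0 is background, `k >= 1` an ROI id.
#' @param spacing numeric length-3, voxel size per axis in mm (strictly
#'   positive).
#' @param origin numeric length-3, world coordinate (mm) of the center of
#'   voxel (0,0,0).
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(intensity, labels, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  if (length(dim(intensity)) != 3L || length(dim(labels)) != 3L)
    stop("intensity and labels must be 3D arrays")
  if (!identical(dim(intensity), dim(labels)))
    stop(sprintf("shape mismatch: intensity %s vs labels %s",
                 paste(dim(intensity), collapse = "x"),
                 paste(dim(labels), collapse = "x")))
  if (!all(is.finite(intensity))) stop("intensity must be finite everywhere")
  lab <- as.numeric(labels)
  if (any(abs(lab - round(lab)) > 1e-6))
    stop("labels must be integer-valued (tolerance 1e-6)")
  if (any(lab < 0)) stop("labels must be nonnegative")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  labi <- array(as.integer(round(lab)), dim(labels))
  structure(
    list(intensity = intensity, labels = labi,
         spacing = spacing, origin = origin),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensity)
  ids <- sort(unique(as.integer(x$labels)))
  ids <- ids[ids > 0L]
  cat(sprintf("labeled_volume: %d x %d x %d voxels, spacing (%s) mm, %d ROIs\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = ", "),
              length(ids)))
  invisible(x)
}

#' @rdname labeled_volume
#' @param x object to test.
#' @export
is_labeled_volume <- function(x) inherits(x, "labeled_volume")

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel indices are 0-based; index (0,0,0) sits at `origin`. The conversion is
#' per-axis affine: `world = origin + index * spacing`.
#'
#' @param volume a [labeled_volume()].
#' @param points numeric matrix, one point per row (n x 3).
#' @return n x 3 matrix of converted coordinates.
#' @export
world_to_voxel <- function(volume, points) {
  points <- rbind_points(points)
  sweep(sweep(points, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(volume, points) {
  points <- rbind_points(points)
  sweep(sweep(points, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  storage.mode(points) <- "double"
  points
}

#' Look up the ROI label at world points (nearest voxel center)
#'
#' Points outside the grid map to background (0). No dilation or tolerance is
#' applied: a point belongs to the single voxel whose center is nearest.
#'
#' @inheritParams world_to_voxel
#' @return integer vector of labels, one per row of `points`.
#' @export
label_at <- function(volume, points) {
  v <- round(world_to_voxel(volume, points))
  d <- dim(volume$labels)
  ok <- v[, 1] >= 0 & v[, 1] < d[1] &
        v[, 2] >= 0 & v[, 2] < d[2] &
        v[, 3] >= 0 & v[, 3] < d[3]
  out <- integer(nrow(v))
  if (any(ok)) {
    idx <- v[ok, , drop = FALSE] + 1
    out[ok] <- volume$labels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  }
  out
}

#' Per-ROI summary table: names, centroids, voxel counts, volumes
#'
#' The center of an ROI is the world-coordinate centroid of its voxel centers;
#' its volume is `voxel_count` times the voxel volume (product of spacings).
#' ROI volumes feed the fiber-density denominator of the structural network.
#'
#' @param volume a [labeled_volume()].
#' @param names optional character vector of ROI names, aligned with the
#'   sorted label ids; defaults to `"roi_<id>"`.
#' @return data.frame with columns `label`, `name`, `cx`, `cy`, `cz` (mm),
#'   `voxel_count`, `volume_mm3`.
#' @export
roi_table <- function(volume, names = NULL) {
  lab <- as.integer(volume$labels)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) stop("volume has no nonzero labels")
  d <- dim(volume$labels)
  idx <- which(volume$labels > 0L)
  ijk <- arrayInd(idx, d) - 1  # 0-based voxel indices
  l <- volume$labels[idx]
  vox_vol <- prod(volume$spacing)
  cnt <- tabulate(match(l, ids), nbins = length(ids))
  cx <- vapply(split(ijk[, 1], l), mean, 0)[as.character(ids)]
  cy <- vapply(split(ijk[, 2], l), mean, 0)[as.character(ids)]
  cz <- vapply(split(ijk[, 3], l), mean, 0)[as.character(ids)]
  w <- sweep(sweep(cbind(cx, cy, cz), 2, volume$spacing, "*"),
             2, volume$origin, "+")
  if (is.null(names)) names <- sprintf("roi_%d", ids)
  data.frame(label = ids, name = names,
             cx = w[, 1], cy = w[, 2], cz = w[, 3],
             voxel_count = cnt, volume_mm3 = cnt * vox_vol,
             row.names = NULL)
}

axis_aligned_affine <- function(img) {
  m <- RNifti::xform(img)
  lin <- m[1:3, 1:3]
  offdiag <- lin - diag(diag(lin))
  if (max(abs(offdiag)) > 1e-6)
    stop("NIfTI affine has rotation/shear; only axis-aligned (scaling + translation) affines are supported")
  if (any(diag(lin) <= 0))
    stop("NIfTI affine must have positive scaling on each axis")
  list(spacing = diag(lin), origin = m[1:3, 4])
}

#' Read a labeled volume from a pair of NIfTI files
#'
#' Geometry (spacing/origin) is taken from the label volume's header affine,
#' which must be axis-aligned (scaling plus translation only). Label values
#' must be integers to within 1e-6.
#'
#' @param intensity_path,labels_path paths to NIfTI (.nii/.nii.gz) files on
#'   the same grid.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(intensity_path, labels_path) {
  ii <- RNifti::readNifti(intensity_path)
  li <- RNifti::readNifti(labels_path)
  di <- dim(ii); dl <- dim(li)
  if (!identical(di, dl))
    stop(sprintf("shape mismatch: intensity %s vs labels %s",
                 paste(di, collapse = "x"), paste(dl, collapse = "x")))
  geom <- axis_aligned_affine(li)
  labeled_volume(array(as.numeric(ii), di), array(as.numeric(li), dl),
                 spacing = geom$spacing, origin = geom$origin)
}

#' Write a labeled volume to a pair of NIfTI files
#'
#' @param volume a [labeled_volume()].
#' @param intensity_path,labels_path output NIfTI paths.
#' @return invisibly, the two paths.
#' @export
write_labeled_volume <- function(volume, intensity_path, labels_path) {
  aff <- structure(rbind(cbind(diag(volume$spacing), volume$origin),
                         c(0, 0, 0, 1)), code = 2L)
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, volume$spacing)
    img <- RNifti::`qform<-`(img, aff)
    RNifti::writeNifti(img, path)
  }
  wr(volume$intensity, intensity_path)
  wr(array(as.double(volume$labels), dim(volume$labels)), labels_path)
  invisible(c(intensity_path, labels_path))
}
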