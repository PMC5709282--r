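#' Write a brain map as PNG plus a sparse label table
#'
#' Writes `<stem>.png` (8-bit RGBA) and `<stem>.labels.tsv`, a sparse
#' pixel-to-label table with columns `row`, `col`, `label` (1-based pixels,
#' nonzero labels only). Reading the label table back reproduces the label
#' raster exactly; the PNG is lossy only by 8-bit quantization (at most
#' 1/255 per channel).
#'
#' @param map a `brain_map`.
#' @param path_stem output path without extension.
#' @return invisibly, the two paths written.
#' @export
write_map <- function(map, path_stem) {
  png_path <- paste0(path_stem, ".png")
  tsv_path <- paste0(path_stem, ".labels.tsv")
  png::writePNG(map$rgba, png_path)
  idx <- which(map$label_raster != 0L, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   label = map$label_raster[idx])
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(png_path, tsv_path))
}

#' Read a sparse label table back into a raster
#'
#' @param path a `.labels.tsv` written by [write_map()].
#' @param height,width raster dimensions.
#' @return integer height x width matrix.
#' @export
read_label_raster <- function(path, height, width) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- matrix(0L, height, width)
  if (nrow(df)) out[cbind(df$row, df$col)] <- as.integer(df$label)
  out
}

#' Write / read an ROI table as TSV
#'
#' @param roi a [roi_table()] data.frame.
#' @param path TSV path.
#' @export
write_roi_table <- function(roi, path) {
  utils::write.table(roi, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read fibers as a plain-text polyline table
#'
#' Columns `fiber_id`, `x`, `y`, `z`, one row per point, points in order
#' along each fiber.
#'
#' @param fibers a `fiber_set`.
#' @param path TSV path.
#' @export
write_fibers_tsv <- function(fibers, path) {
  df <- do.call(rbind, lapply(seq_along(fibers), function(i) {
    f <- rbind_points(fibers[[i]])
    data.frame(fiber_id = i, x = f[, 1], y = f[, 2], z = f[, 3])
  }))
  if (is.null(df)) df <- data.frame(fiber_id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fibers_tsv
#' @export
read_fibers_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fibers <- lapply(split(df[, c("x", "y", "z")], df$fiber_id), as.matrix)
  fibers <- unname(fibers[order(as.integer(names(fibers)))])
  bad <- vapply(fibers, nrow, 0L) < 2
  if (any(bad)) stop("every fiber needs >= 2 points")
  structure(fibers, class = "fiber_set")
}

#' Read / write TrackVis TRK streamline files
#'
#' Minimal TRK v2 support: the 1000-byte header (dimensions, voxel size,
#' voxel order, vox-to-ras) and raw float32 streamlines, without per-point
#' scalars or per-track properties. Coordinates are stored and returned in
#' the file's native (voxel-mm) frame.
#'
#' @param path TRK file path.
#' @return A `fiber_set` with attributes `grid_dim`, `voxel_size`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic[1:5], charToRaw("TRACK"))) stop("not a TRK file")
  dim3 <- readBin(con, "integer", 3, size = 2)
  voxel_size <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)              # origin (unused)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)                           # scalar names
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)                           # property names
  readBin(con, "raw", 1000 - 6 - 6 - 12 - 12 - 2 - 200 - 2 - 200 - 12)
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 4)               # version
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000) stop("unexpected TRK header size")
  fibers <- list()
  repeat {
    m <- readBin(con, "integer", 1, size = 4)
    if (length(m) == 0) break
    pts <- readBin(con, "numeric", m * (3 + n_scalars), size = 4)
    pts <- matrix(pts, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3,
                                                           drop = FALSE]
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    fibers[[length(fibers) + 1]] <- pts
  }
  out <- structure(fibers, class = "fiber_set")
  attr(out, "grid_dim") <- dim3
  attr(out, "voxel_size") <- voxel_size
  out
}

#' @rdname read_trk
#' @param fibers a `fiber_set`.
#' @param dim3 integer length-3 grid dimensions for the header.
#' @param voxel_size numeric length-3 voxel size for the header.
#' @export
write_trk <- function(fibers, path, dim3 = c(0L, 0L, 0L),
                      voxel_size = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)
  writeBin(as.integer(dim3), con, size = 2)
  writeBin(as.numeric(voxel_size), con, size = 4)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4)    # origin
  writeBin(0L, con, size = 2)                        # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                        # n_properties
  writeBin(raw(200), con)
  writeBin(raw(1000 - 6 - 6 - 12 - 12 - 2 - 200 - 2 - 200 - 12), con)
  writeBin(length(fibers), con, size = 4)
  writeBin(2L, con, size = 4)                        # version
  writeBin(1000L, con, size = 4)                     # hdr_size
  for (f in fibers) {
    f <- rbind_points(f)
    writeBin(nrow(f), con, size = 4)
    writeBin(as.numeric(t(f)), con, size = 4)
  }
  invisible(path)
}

#' Write / read a time-series set as TSV
#'
#' Header row `roi_id` then `t0..t{n-1}`; one row per ROI.
#'
#' @param series a [timeseries_set()].
#' @param path TSV path.
#' @export
write_timeseries <- function(series, path) {
  df <- data.frame(roi_id = series$roi_ids, series$values,
                   check.names = FALSE)
  colnames(df) <- c("roi_id", sprintf("t%d", seq_len(series$n_time) - 1))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  timeseries_set(as.matrix(df[, -1, drop = FALSE]), as.integer(df$roi_id))
}

#' Write an edge list as TSV (`roi_a`, `roi_b`, `weight`)
#'
#' @param edge_df a [threshold_edges()] result.
#' @param path TSV path.
#' @export
write_edge_list <- function(edge_df, path) {
  utils::write.table(edge_df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
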