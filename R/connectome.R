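#' Construct a connectivity matrix object
#'
#' @param weights square symmetric numeric matrix (ROI x ROI).
#' @param roi_ids integer ids aligned with rows/columns.
#' @param kind `"structural"` (nonnegative weights, zero diagonal) or
#'   `"functional"` (entries in `[-1, 1]`, unit diagonal).
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, roi_ids,
                                kind = c("structural", "functional")) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (nrow(weights) != length(roi_ids))
    stop("roi_ids must align with weights")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  if (kind == "structural") {
    if (any(weights < 0)) stop("structural weights must be nonnegative")
    if (any(diag(weights) != 0)) stop("structural diagonal must be 0")
  } else {
    if (any(weights < -1 - 1e-9 | weights > 1 + 1e-9))
      stop("functional weights must be in [-1, 1]")
    if (max(abs(diag(weights) - 1)) > 1e-9)
      stop("functional diagonal must be 1")
  }
  dimnames(weights) <- list(roi_ids, roi_ids)
  structure(list(weights = weights, roi_ids = as.integer(roi_ids),
                 kind = kind),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("connectivity_matrix (%s): %d ROIs, %d nonzero edges\n",
              x$kind, length(x$roi_ids), nz))
  invisible(x)
}

#' Structural network from fiber endpoints (fiber density)
#'
#' A fiber connects ROI pair (i, j), i != j, if and only if one terminal
#' point falls in i and the other in j (nearest-voxel label lookup, no
#' dilation). The edge weight is the fiber count divided by the mean of the
#' two ROI volumes (mm^3): `w_ij = count_ij / mean(vol_i, vol_j)`. Fibers
#' with an endpoint in background (or outside the grid) or with both
#' endpoints in the same ROI contribute nothing; interior fiber points are
#' ignored.
#'
#' @param fibers a `fiber_set` (list of n x 3 world-coordinate polylines).
#' @param volume a [labeled_volume()].
#' @param roi its [roi_table()] (supplies `volume_mm3`).
#' @return A [connectivity_matrix()] of kind `"structural"`. The integer
#'   endpoint-pair counts are attached as attribute `"counts"`.
#' @export
build_structural_network <- function(fibers, volume, roi) {
  ids <- sort(roi$label)
  if (length(ids) < 2) stop("need >= 2 ROIs")
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (length(fibers) > 0) {
    ends <- do.call(rbind, lapply(fibers, function(f) {
      f <- rbind_points(f)
      f[c(1, nrow(f)), , drop = FALSE]
    }))
    lab <- label_at(volume, ends)
    la <- lab[seq(1, length(lab), by = 2)]
    lb <- lab[seq(2, length(lab), by = 2)]
    keep <- la > 0 & lb > 0 & la != lb
    if (any(keep)) {
      ia <- match(la[keep], ids); ib <- match(lb[keep], ids)
      for (f in seq_along(ia)) {
        counts[ia[f], ib[f]] <- counts[ia[f], ib[f]] + 1L
        counts[ib[f], ia[f]] <- counts[ib[f], ia[f]] + 1L
      }
    }
  }
  vol3 <- roi$volume_mm3[match(ids, roi$label)]
  meanvol <- outer(vol3, vol3, function(a, b) (a + b) / 2)
  W <- counts / meanvol
  diag(W) <- 0
  out <- connectivity_matrix(W, ids, "structural")
  attr(out, "counts") <- counts
  out
}

#' Functional connectivity: Pearson correlation of ROI time series
#'
#' @param series a [timeseries_set()] with at least 3 time points; every row
#'   must have nonzero variance.
#' @return A [connectivity_matrix()] of kind `"functional"` (unit diagonal).
#' @export
functional_connectivity <- function(series) {
  v <- series$values
  if (ncol(v) < 3) stop("need n_time >= 3")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant time series for ROI %s",
                 series$roi_ids[which(sds == 0)[1]]))
  R <- stats::cor(t(v))
  diag(R) <- 1
  connectivity_matrix(R, series$roi_ids, "functional")
}

#' Node strength (weighted degree)
#'
#' `strength_i = sum_j w_ij` over `j != i`. For functional matrices the
#' absolute correlation is summed by default, keeping strengths nonnegative;
#' set `absolute = FALSE` to sum signed correlations.
#'
#' @param net a [connectivity_matrix()].
#' @param absolute use `|w|` for functional matrices.
#' @return data.frame with columns `label`, `strength`.
#' @export
node_strength <- function(net, absolute = TRUE) {
  W <- net$weights
  if (net$kind == "functional" && absolute) W <- abs(W)
  diag(W) <- 0
  data.frame(label = net$roi_ids, strength = rowSums(W), row.names = NULL)
}

#' Threshold a network into an edge list
#'
#' Keeps upper-triangle entries with weight >= `tau`, sorted by descending
#' weight, then by (roi_a, roi_b).
#'
#' @param net a [connectivity_matrix()].
#' @param tau finite threshold (or `-Inf` to keep all edges).
#' @param percentile if `TRUE`, interpret `tau` in `[0, 1]` as a quantile of
#'   the upper-triangle weights and threshold at that quantile.
#' @return data.frame with columns `roi_a`, `roi_b`, `weight`
#'   (`roi_a < roi_b`).
#' @export
threshold_edges <- function(net, tau, percentile = FALSE) {
  W <- net$weights
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  if (percentile) tau <- stats::quantile(w, tau, names = FALSE)
  keep <- w >= tau
  df <- data.frame(roi_a = net$roi_ids[ut[keep, 1]],
                   roi_b = net$roi_ids[ut[keep, 2]],
                   weight = w[keep])
  df <- df[order(-df$weight, df$roi_a, df$roi_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a connectivity matrix as TSV
#'
#' Square table with a `roi_id` header column and ROI ids as column names.
#'
#' @param net a [connectivity_matrix()].
#' @param path TSV path.
#' @param kind matrix kind for the reader.
#' @export
write_connectivity_matrix <- function(net, path) {
  df <- data.frame(roi_id = net$roi_ids, net$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @export
read_connectivity_matrix <- function(path, kind = "structural") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  ids <- as.integer(df$roi_id)
  W <- as.matrix(df[, -1, drop = FALSE])
  W <- (W + t(W)) / 2  # undo asymmetric rounding from text round-trip
  connectivity_matrix(W, ids, kind)
}
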