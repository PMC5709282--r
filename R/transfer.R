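#' Transfer function: intensity and label to color and opacity
#'
#' A piecewise-linear map from voxel intensity to opacity and base color,
#' plus categorical per-label overrides. Samples whose nearest-voxel label
#' has an override render with that label's color/opacity; all other samples
#' (including background) use the intensity ramps.
#'
#' @param breaks sorted numeric intensity breakpoints.
#' @param opacities opacity at each breakpoint, in `[0,1]`.
#' @param colors matrix `length(breaks) x 3` of RGB in `[0,1]` at each
#'   breakpoint.
#' @param label_colors optional named list or matrix: per-label RGB override;
#'   names are label ids.
#' @param label_opacities optional named numeric: per-label opacity override
#'   (defaults to 1 for labels with a color override).
#' @return A `transfer_function` object.
#' @export
transfer_function <- function(breaks = c(0, 1),
                              opacities = c(0, 0),
                              colors = matrix(0.5, length(breaks), 3),
                              label_colors = NULL,
                              label_opacities = NULL) {
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks)) stop("breaks must be sorted")
  opacities <- as.numeric(opacities)
  if (length(opacities) != length(breaks))
    stop("opacities must align with breaks")
  if (any(opacities < 0 | opacities > 1)) stop("opacities must be in [0,1]")
  colors <- as.matrix(colors)
  if (nrow(colors) != length(breaks) || ncol(colors) != 3)
    stop("colors must be length(breaks) x 3")
  lc <- NULL; lo <- NULL
  if (!is.null(label_colors)) {
    if (is.list(label_colors))
      label_colors <- do.call(rbind, label_colors)
    lc <- as.matrix(label_colors)
    if (is.null(rownames(lc))) stop("label_colors must be named by label id")
    lo <- rep(1, nrow(lc))
    names(lo) <- rownames(lc)
    if (!is.null(label_opacities)) {
      if (any(label_opacities < 0 | label_opacities > 1))
        stop("label opacities must be in [0,1]")
      lo[names(label_opacities)] <- label_opacities
    }
  }
  structure(list(breaks = breaks, opacities = opacities, colors = colors,
                 label_colors = lc, label_opacities = lo),
            class = "transfer_function")
}

#' Categorical transfer function for opaque/semi-transparent ROI rendering
#'
#' Assigns each label a distinct color (evenly spaced hues) and a common
#' opacity; intensity-based opacity is zero, so only labeled voxels render.
#'
#' @param labels integer vector of ROI ids.
#' @param opacity opacity applied to every label (default 1 = opaque).
#' @param colors optional n x 3 RGB matrix, one row per label.
#' @return A [transfer_function()].
#' @export
label_transfer_function <- function(labels, opacity = 1, colors = NULL) {
  labels <- sort(unique(as.integer(labels)))
  labels <- labels[labels > 0]
  if (length(labels) == 0) stop("no nonzero labels")
  if (is.null(colors)) {
    hues <- (seq_along(labels) - 1) / length(labels)
    colors <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.75, 0.95)) / 255)
  }
  rownames(colors) <- labels
  op <- rep(opacity, length(labels)); names(op) <- labels
  transfer_function(label_colors = colors, label_opacities = op)
}

# Evaluate opacity and color for vectors of intensity + label. Returns
# list(alpha, color n x 3). Labels not in `visible` are fully transparent.
tf_eval <- function(tf, intensity, label, visible = NULL) {
  n <- length(intensity)
  alpha <- stats::approx(tf$breaks, tf$opacities, xout = intensity,
                         rule = 2)$y
  col <- cbind(
    stats::approx(tf$breaks, tf$colors[, 1], xout = intensity, rule = 2)$y,
    stats::approx(tf$breaks, tf$colors[, 2], xout = intensity, rule = 2)$y,
    stats::approx(tf$breaks, tf$colors[, 3], xout = intensity, rule = 2)$y)
  if (!is.null(tf$label_colors) && any(label > 0)) {
    m <- match(as.character(label), rownames(tf$label_colors))
    hit <- !is.na(m) & label > 0
    if (any(hit)) {
      alpha[hit] <- tf$label_opacities[m[hit]]
      col[hit, ] <- tf$label_colors[m[hit], , drop = FALSE]
    }
  }
  if (!is.null(visible)) {
    off <- label > 0 & !(label %in% visible)
    alpha[off] <- 0
  }
  list(alpha = alpha, color = col)
}

# Force the given labels opaque (opacity 1), keeping their colors; labels
# without colors get evenly spaced hues. Used by layered rendering.
tf_force_opaque <- function(tf, labels) {
  labels <- sort(unique(as.integer(labels)))
  labels <- labels[labels > 0]
  colors <- matrix(NA_real_, length(labels), 3)
  rownames(colors) <- labels
  if (!is.null(tf$label_colors)) {
    m <- match(as.character(labels), rownames(tf$label_colors))
    colors[!is.na(m), ] <- tf$label_colors[m[!is.na(m)], , drop = FALSE]
  }
  miss <- which(is.na(colors[, 1]))
  if (length(miss)) {
    hues <- (miss - 1) / length(labels)
    colors[miss, ] <- t(grDevices::col2rgb(grDevices::hsv(hues, 0.75, 0.95)) / 255)
  }
  op <- rep(1, length(labels)); names(op) <- labels
  transfer_function(breaks = tf$breaks, opacities = rep(0, length(tf$breaks)),
                    colors = tf$colors, label_colors = colors,
                    label_opacities = op)
}
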