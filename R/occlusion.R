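#' Build the occlusion graph from per-ray first-visit sequences
#'
#' Each ray contributes weight 1 to the directed edge `a -> b` for every
#' ordered pair (a seen before b) in its first-visit label sequence; with
#' `consecutive_only = TRUE` only adjacent pairs in the sequence count.
#' Reciprocal edges are allowed (cyclic occlusion from non-convex shapes);
#' self-edges are impossible because sequences hold distinct labels.
#'
#' @param records list of integer vectors (first-visit label sequences), as
#'   returned by [render_map()] (`$records`) or [cast_camera_grid()]
#'   (`$occlusion`).
#' @param consecutive_only count only consecutive pairs instead of all
#'   ordered pairs.
#' @return An `occlusion_graph`: list with `nodes` (sorted label ids) and
#'   `weights` (square matrix, `weights[a, b]` = number of rays seeing a
#'   before b).
#' @export
build_occlusion_graph <- function(records, consecutive_only = FALSE) {
  records <- records[lengths(records) > 0]
  nodes <- sort(unique(unlist(records, use.names = FALSE)))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in records) {
    m <- length(s)
    if (m < 2) next
    i <- match(s, nodes)
    if (consecutive_only) {
      for (p in seq_len(m - 1)) W[i[p], i[p + 1]] <- W[i[p], i[p + 1]] + 1
    } else {
      for (p in seq_len(m - 1))
        W[i[p], i[(p + 1):m]] <- W[i[p], i[(p + 1):m]] + 1
    }
  }
  structure(list(nodes = as.integer(nodes), weights = W),
            class = "occlusion_graph")
}

#' @export
print.occlusion_graph <- function(x, ...) {
  cat(sprintf("occlusion_graph: %d nodes, %d directed edges, total weight %g\n",
              length(x$nodes), sum(x$weights > 0), sum(x$weights)))
  invisible(x)
}

#' Construct a layer assignment directly
#'
#' @param layer named integer vector: label id -> 1-based layer index
#'   (contiguous from 1).
#' @param scale optional numeric vector of per-layer magnification factors,
#'   named by layer index; defaults to 1 for every layer.
#' @return A `layer_assignment` object.
#' @export
layer_assignment <- function(layer, scale = NULL) {
  ids <- sort(as.integer(names(layer)))
  layer <- as.integer(layer[order(as.integer(names(layer)))])
  names(layer) <- ids
  ks <- sort(unique(layer))
  if (!identical(ks, seq_along(ks)))
    stop("layer indices must be contiguous from 1")
  if (is.null(scale)) {
    scale <- rep(1, length(ks)); names(scale) <- ks
  } else {
    sc <- rep(1, length(ks)); names(sc) <- ks
    sc[names(scale)] <- scale
    scale <- sc
  }
  structure(list(layer = layer, scale = scale), class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  for (k in sort(unique(x$layer)))
    cat(sprintf("layer %d (scale %.2f): %s\n", k, x$scale[as.character(k)],
                paste(names(x$layer)[x$layer == k], collapse = ", ")))
  invisible(x)
}

#' Sort occlusion-graph nodes into depth layers
#'
#' Iterative topological peeling: layer k collects every unassigned node with
#' zero incoming weight from other unassigned nodes. When a cycle leaves no
#' such node, the node with minimum combined incoming edge weight (ties:
#' smallest label id) has its incoming edges deleted — discarding the least
#' occlusion evidence — and the zero-incoming set is re-evaluated. On an
#' acyclic graph the result is a valid topological layering: every edge runs
#' from a strictly lower layer to a higher one.
#'
#' @param graph an [build_occlusion_graph()] result.
#' @return A [layer_assignment()] (all scales 1).
#' @export
layer_sort <- function(graph) {
  nodes <- graph$nodes
  if (length(nodes) == 0)
    return(layer_assignment(stats::setNames(integer(0), character(0))))
  W <- graph$weights
  remaining <- rep(TRUE, length(nodes))
  assign <- integer(length(nodes))
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    repeat {
      idx <- which(remaining)
      incoming <- colSums(W[idx, idx, drop = FALSE])
      zero <- idx[incoming == 0]
      if (length(zero) > 0) break
      # cycle: drop incoming edges of the min-incoming node (tie: smallest id)
      pick <- idx[order(incoming, nodes[idx])[1]]
      W[, pick] <- 0
    }
    assign[zero] <- k
    remaining[zero] <- FALSE
  }
  layer_assignment(stats::setNames(assign, nodes))
}

#' Write / read an occlusion graph as a TSV edge table
#'
#' Columns `src`, `dst`, `weight`, one row per directed edge with positive
#' weight.
#'
#' @param graph an `occlusion_graph`.
#' @param path output TSV path.
#' @return invisibly, `path` (writer); an `occlusion_graph` (reader).
#' @export
write_occlusion_graph <- function(graph, path) {
  idx <- which(graph$weights > 0, arr.ind = TRUE)
  df <- data.frame(src = graph$nodes[idx[, 1]], dst = graph$nodes[idx[, 2]],
                   weight = graph$weights[idx])
  df <- df[order(df$src, df$dst), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occlusion_graph
#' @export
read_occlusion_graph <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  nodes <- sort(unique(c(df$src, df$dst)))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  W[cbind(match(df$src, nodes), match(df$dst, nodes))] <- df$weight
  structure(list(nodes = as.integer(nodes), weights = W),
            class = "occlusion_graph")
}

#' Write a layer assignment as TSV (`label`, `layer`, `scale`)
#'
#' @param layers a [layer_assignment()].
#' @param path output TSV path.
#' @export
write_layer_assignment <- function(layers, path) {
  df <- data.frame(label = as.integer(names(layers$layer)),
                   layer = as.integer(layers$layer),
                   scale = layers$scale[as.character(layers$layer)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
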