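#' Construct a vascular graph
#'
#' A vascular graph represents the cerebral microvasculature as straight
#' cylindrical pipes between branch points.  Each node carries a 3D position
#' (micrometres) and a radius; each edge is a vessel segment between two
#' nodes with a length and a radius.  Unless supplied, the edge length is
#' the Euclidean distance between its endpoints (a `length` column may carry
#' the true tortuous length instead) and the edge radius is the arithmetic
#' mean of the endpoint node radii.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`
#'   (positions and radii in micrometres).
#' @param edges data.frame with columns `id`, `node_a`, `node_b` and
#'   optionally `length` and `radius`.
#' @param depth_axis which coordinate (1 = x, 2 = y, 3 = z) increases with
#'   cortical depth.  Default 2.
#' @return An object of class `vascular_graph`: a list with elements
#'   `nodes`, `edges` (with resolved `length`, `radius` and integer endpoint
#'   indices `ia`, `ib`), `depth_axis`, `N`, `M`.
#' @export
vascular_graph <- function(nodes, edges, depth_axis = 2L) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  need_n <- c("id", "x", "y", "z", "radius")
  need_e <- c("id", "node_a", "node_b")
  miss_n <- setdiff(need_n, names(nodes))
  miss_e <- setdiff(need_e, names(edges))
  if (length(miss_n)) stop("node table missing columns: ", paste(miss_n, collapse = ", "))
  if (length(miss_e)) stop("edge table missing columns: ", paste(miss_e, collapse = ", "))
  if (!depth_axis %in% 1:3) stop("depth_axis must be 1, 2 or 3")

  if (anyDuplicated(nodes$id)) {
    stop("duplicated node ids: ", paste(utils::head(nodes$id[duplicated(nodes$id)], 5L), collapse = ", "))
  }
  if (nrow(edges) && anyDuplicated(edges$id)) {
    stop("duplicated edge ids: ", paste(utils::head(edges$id[duplicated(edges$id)], 5L), collapse = ", "))
  }
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  if (nrow(nodes) && !all(is.finite(pos))) {
    stop("non-finite node positions at rows: ",
         paste(utils::head(which(!stats::complete.cases(pos) | rowSums(!is.finite(pos)) > 0), 5L), collapse = ", "))
  }
  bad_r <- which(!is.finite(nodes$radius) | nodes$radius <= 0)
  if (length(bad_r)) {
    stop("non-positive node radii at rows: ", paste(utils::head(bad_r, 5L), collapse = ", "))
  }

  if (nrow(edges)) {
    ia <- match(edges$node_a, nodes$id)
    ib <- match(edges$node_b, nodes$id)
    dang <- which(is.na(ia) | is.na(ib))
    if (length(dang)) {
      stop("edges reference unknown node ids at rows: ",
           paste(utils::head(dang, 5L), collapse = ", "))
    }
    loops <- which(ia == ib)
    if (length(loops)) {
      stop("self-loop edges at rows: ", paste(utils::head(loops, 5L), collapse = ", "))
    }
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key)) {
      stop("multi-edges between the same node pair at rows: ",
           paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
    }
    if (is.null(edges$length)) {
      edges$length <- sqrt(rowSums((pos[ia, , drop = FALSE] - pos[ib, , drop = FALSE])^2))
    }
    if (is.null(edges$radius)) {
      edges$radius <- (nodes$radius[ia] + nodes$radius[ib]) / 2
    }
    bad_l <- which(!is.finite(edges$length) | edges$length <= 0)
    if (length(bad_l)) stop("non-positive edge lengths at rows: ", paste(utils::head(bad_l, 5L), collapse = ", "))
    bad_er <- which(!is.finite(edges$radius) | edges$radius <= 0)
    if (length(bad_er)) stop("non-positive edge radii at rows: ", paste(utils::head(bad_er, 5L), collapse = ", "))
    edges$ia <- ia
    edges$ib <- ib
  } else {
    edges <- data.frame(id = integer(), node_a = integer(), node_b = integer(),
                        length = numeric(), radius = numeric(),
                        ia = integer(), ib = integer())
  }

  structure(
    list(nodes = nodes, edges = edges, depth_axis = as.integer(depth_axis),
         N = nrow(nodes), M = nrow(edges)),
    class = "vascular_graph"
  )
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat(sprintf("<vascular_graph> %d nodes, %d edges\n", x$N, x$M))
  if (x$N) {
    d <- node_depth(x)
    cat(sprintf("  depth axis %d, depth range [%.1f, %.1f] um\n",
                x$depth_axis, min(d), max(d)))
    if (x$M) {
      cat(sprintf("  edge radius range [%.2f, %.2f] um, total length %.0f um\n",
                  min(x$edges$radius), max(x$edges$radius), sum(x$edges$length)))
    }
  }
  invisible(x)
}

#' Node depth coordinate
#'
#' Cortical depth of each node along the graph's depth axis.
#' @param graph a `vascular_graph`.
#' @return numeric vector of depths (um), one per node.
#' @export
node_depth <- function(graph) {
  graph$nodes[[c("x", "y", "z")[graph$depth_axis]]]
}

#' Edge midpoint depth
#' @param graph a `vascular_graph`.
#' @return numeric vector of midpoint depths (um), one per edge.
#' @export
edge_depth <- function(graph) {
  d <- node_depth(graph)
  (d[graph$edges$ia] + d[graph$edges$ib]) / 2
}

#' Node degrees
#' @param graph a `vascular_graph`.
#' @return integer vector, one entry per node row.
#' @export
node_degree <- function(graph) {
  tabulate(c(graph$edges$ia, graph$edges$ib), nbins = graph$N)
}

as_igraph <- function(graph) {
  igraph::make_graph(rbind(graph$edges$ia, graph$edges$ib),
                     n = graph$N, directed = FALSE)
}

#' Load a vascular graph from node and edge tables
#'
#' Reads CSV/TSV tables (delimiter auto-detected).  The node table must have
#' columns `id,x,y,z,radius`; the edge table `id,node_a,node_b` plus
#' optional `length` (true tortuous length, um) and `radius`.
#'
#' @param node_file,edge_file paths to the tables.
#' @param depth_axis passed to [vascular_graph()].
#' @return a `vascular_graph`.
#' @export
load_graph <- function(node_file, edge_file, depth_axis = 2L) {
  nodes <- as.data.frame(data.table::fread(node_file))
  edges <- as.data.frame(data.table::fread(edge_file))
  vascular_graph(nodes, edges, depth_axis = depth_axis)
}

#' Write a vascular graph to node and edge tables
#'
#' Numeric values are written with round-trip precision, so
#' load -> write -> load reproduces ids, positions and radii exactly.
#'
#' @param graph a `vascular_graph`.
#' @param node_file,edge_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_graph <- function(graph, node_file, edge_file) {
  fwrite_precise(graph$nodes[, c("id", "x", "y", "z", "radius")], node_file)
  fwrite_precise(graph$edges[, c("id", "node_a", "node_b", "length", "radius")], edge_file)
  invisible(c(node_file, edge_file))
}

#' Reduce a vascular graph to its largest connected component
#'
#' Ties between equally sized components are broken in favour of the
#' component containing the smallest node id.
#'
#' @param graph a nonempty `vascular_graph`.
#' @return the induced `vascular_graph` on the largest component.
#' @export
largest_component <- function(graph) {
  if (graph$N == 0L) stop("empty graph")
  comp <- igraph::components(as_igraph(graph))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: component holding the smallest node id
    min_id <- vapply(best, function(cc) min(graph$nodes$id[comp$membership == cc]), numeric(1))
    best <- best[which.min(min_id)]
  }
  keep <- comp$membership == best
  subset_graph(graph, which(keep))
}

# induced subgraph on node row indices, re-validated through the constructor
subset_graph <- function(graph, node_idx) {
  keep_nodes <- graph$nodes[node_idx, , drop = FALSE]
  in_set <- logical(graph$N)
  in_set[node_idx] <- TRUE
  keep_e <- in_set[graph$edges$ia] & in_set[graph$edges$ib]
  keep_edges <- graph$edges[keep_e, c("id", "node_a", "node_b", "length", "radius"), drop = FALSE]
  vascular_graph(keep_nodes, keep_edges, depth_axis = graph$depth_axis)
}

#' Classify edges into capillaries, large vessels and other
#'
#' Classification is by diameter d = 2r: capillaries have
#' `d` within `cap_range`, large vessels `d >= large_min`, everything else
#' is `other`.  The conventional ranges are capillaries at 4--6 um and large
#' vessels at >= 14 um; flow-share accounting commonly counts every vessel
#' below 6 um as capillary (`cap_range = c(0, 6)`).
#'
#' @param graph a `vascular_graph`.
#' @param cap_range length-2 numeric, capillary diameter interval (um).
#' @param large_min minimum large-vessel diameter (um).
#' @return factor per edge with levels `capillary`, `large`, `other`, with
#'   attributes `cap_range` and `large_min`.
#' @export
classify_vessels <- function(graph, cap_range = c(4, 6), large_min = 14) {
  if (length(cap_range) != 2L || cap_range[1] >= cap_range[2]) {
    stop("cap_range must be an increasing diameter interval")
  }
  if (cap_range[2] >= large_min) stop("capillary upper bound must be below large_min")
  d <- 2 * graph$edges$radius
  lab <- rep("other", graph$M)
  lab[d >= cap_range[1] & d <= cap_range[2]] <- "capillary"
  lab[d >= large_min] <- "large"
  structure(factor(lab, levels = c("capillary", "large", "other")),
            cap_range = cap_range, large_min = large_min)
}

#' Assign cortical layers by depth
#'
#' Layers are the half-open depth intervals `[b_i, b_{i+1})` between the
#' supplied boundaries, labelled `L1 ... Ln` from the cortical surface down;
#' a depth on a boundary belongs to the deeper interval.  Nodes above the
#' first or below the last boundary get the sentinel labels `above-L1` /
#' `below-Ln` with a warning.  Edges are labelled by midpoint depth.
#'
#' @param graph a `vascular_graph`.
#' @param boundaries strictly increasing depth cut-points (um); `n + 1`
#'   values define `n` layers.
#' @return a `layer_annotation`: list with `node_layer`, `edge_layer`
#'   (factors) and `boundaries`.
#' @export
assign_layers <- function(graph, boundaries) {
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing with at least 2 values")
  }
  n_layer <- length(boundaries) - 1L
  labels <- c(paste0("above-L1"), paste0("L", seq_len(n_layer)), paste0("below-L", n_layer))
  cut_depth <- function(depth) {
    idx <- findInterval(depth, boundaries)  # [b_i, b_{i+1}) half-open
    idx[depth >= boundaries[n_layer + 1L]] <- n_layer + 1L
    factor(labels[idx + 1L], levels = labels)
  }
  nl <- cut_depth(node_depth(graph))
  el <- cut_depth(edge_depth(graph))
  n_out <- sum(nl %in% labels[c(1L, n_layer + 2L)])
  if (n_out > 0L) {
    warning(sprintf("%d node(s) outside the layered depth range", n_out))
  }
  structure(list(node_layer = nl, edge_layer = el, boundaries = boundaries),
            class = "layer_annotation")
}

#' Crop a vascular graph to an axis-aligned box
#'
#' Keeps only edges with both endpoints inside the box (and the nodes those
#' edges use).  Used to discard the boundary region where imposed entry and
#' exit conditions distort the solution before computing metrics.
#'
#' @param graph a `vascular_graph`.
#' @param box list or matrix giving `xlim`, `ylim`, `zlim` (each length 2, um).
#' @return the cropped `vascular_graph` (possibly empty, with a warning).
#' @export
crop_region <- function(graph, box) {
  if (is.matrix(box)) box <- list(xlim = box[1, ], ylim = box[2, ], zlim = box[3, ])
  for (nm in c("xlim", "ylim", "zlim")) {
    if (length(box[[nm]]) != 2L || box[[nm]][1] > box[[nm]][2]) stop("invalid box: ", nm)
  }
  nd <- graph$nodes
  inside <- nd$x >= box$xlim[1] & nd$x <= box$xlim[2] &
            nd$y >= box$ylim[1] & nd$y <= box$ylim[2] &
            nd$z >= box$zlim[1] & nd$z <= box$zlim[2]
  keep_e <- inside[graph$edges$ia] & inside[graph$edges$ib]
  used <- sort(unique(c(graph$edges$ia[keep_e], graph$edges$ib[keep_e])))
  if (length(used) == 0L) {
    warning("crop box excludes every edge; returning empty graph")
    return(vascular_graph(nd[0, ], graph$edges[0, c("id", "node_a", "node_b", "length", "radius")],
                          depth_axis = graph$depth_axis))
  }
  # keep also isolated inside-nodes? no: only nodes used by surviving edges
  subset_graph_edges(graph, which(keep_e))
}

subset_graph_edges <- function(graph, edge_idx) {
  e <- graph$edges[edge_idx, , drop = FALSE]
  used <- sort(unique(c(e$ia, e$ib)))
  vascular_graph(graph$nodes[used, , drop = FALSE],
                 e[, c("id", "node_a", "node_b", "length", "radius")],
                 depth_axis = graph$depth_axis)
}
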