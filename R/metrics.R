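#' Resting-state ratios
#'
#' The resting-state ratio of a per-edge quantity is its value at time
#' point `i` divided by its value at time 0 (the undilated baseline), so
#' the ratio is 1 at `i = 0` by construction.  For flow the ratio is taken
#' on `|Q|` because edge orientation is arbitrary.  Edges whose baseline is
#' numerically zero (below `baseline_tol` times the overall maximum) are
#' excluded with a warning.
#'
#' @param traj numeric matrix, time points x edges.
#' @param use_abs take absolute values first (use for flow).
#' @param baseline_tol relative baseline threshold for exclusion.
#' @param edge_ids optional edge ids labelling the columns.
#' @return a `ratio_series`: list with the ratio matrix `rs` (time x
#'   retained edges), `edge_ids` of the retained columns, and `n_excluded`.
#' @export
resting_state_ratio <- function(traj, use_abs = FALSE, baseline_tol = 1e-12,
                                edge_ids = seq_len(ncol(traj))) {
  if (use_abs) traj <- abs(traj)
  base <- traj[1L, ]
  scale <- max(abs(traj))
  keep <- is.finite(base) & abs(base) > baseline_tol * scale
  if (!any(keep)) {
    warning("all edges have (near) zero baseline; empty ratio series")
    return(structure(list(rs = traj[, 0, drop = FALSE], edge_ids = edge_ids[0],
                          n_excluded = ncol(traj)),
                     class = "ratio_series"))
  }
  if (any(!keep)) {
    warning(sprintf("%d edge(s) excluded for zero baseline", sum(!keep)))
  }
  rs <- sweep(traj[, keep, drop = FALSE], 2L, base[keep], "/")
  structure(list(rs = rs, edge_ids = edge_ids[keep], n_excluded = sum(!keep)),
            class = "ratio_series")
}

#' Flow and radius resting-state ratios of a simulation
#'
#' Convenience wrappers applying [resting_state_ratio()] to the flow
#' magnitude and radius trajectories of a `simulation_result`.
#'
#' @param result a `simulation_result`.
#' @param baseline_tol passed through.
#' @return a `ratio_series`.
#' @export
flow_ratio <- function(result, baseline_tol = 1e-12) {
  resting_state_ratio(result$Q, use_abs = TRUE, baseline_tol = baseline_tol,
                      edge_ids = result$graph$edges$id)
}

#' @rdname flow_ratio
#' @export
radius_ratio <- function(result, baseline_tol = 1e-12) {
  resting_state_ratio(result$radii, baseline_tol = baseline_tol,
                      edge_ids = result$graph$edges$id)
}

#' Average ratio over an edge subset
#'
#' Arithmetic mean of the resting-state ratio over the subset at each time
#' point (`AR(i)`), then the arithmetic mean of that series over time
#' (`AR`).
#'
#' @param ratios a `ratio_series`.
#' @param subset edge ids to average over; `NULL` means all retained edges.
#' @return list with `ar_t` (per time point) and `ar` (scalar).
#' @export
average_ratio <- function(ratios, subset = NULL) {
  cols <- if (is.null(subset)) seq_along(ratios$edge_ids) else match(subset, ratios$edge_ids)
  cols <- cols[!is.na(cols)]
  if (!length(cols)) stop("empty subset after baseline filtering")
  ar_t <- rowMeans(ratios$rs[, cols, drop = FALSE])
  list(ar_t = ar_t, ar = mean(ar_t))
}

# line graph of the vasculature: vertices are edges, connected when they
# share a node; vertex order matches the edge row order
line_graph <- function(graph) {
  igraph::make_line_graph(as_igraph(graph))
}

#' Distance orders from a target edge
#'
#' The distance order of an edge with respect to a target edge is the
#' minimum number of connected edges traversed to reach it (edges sharing a
#' node have order 1): shortest-path distance in the line graph.
#'
#' @param graph a `vascular_graph`.
#' @param k target edge id.
#' @param m_max maximum order (>= 1).
#' @return list of length `m_max`; element `m` holds the edge ids at order
#'   exactly `m` (disjoint sets).
#' @export
distance_orders <- function(graph, k, m_max = 20L) {
  if (m_max < 1L) stop("m_max must be >= 1")
  row <- match(k, graph$edges$id)
  if (is.na(row)) stop("unknown edge id: ", k)
  d <- as.integer(igraph::distances(line_graph(graph), v = row)[1L, ])
  lapply(seq_len(m_max), function(m) graph$edges$id[which(d == m)])
}

#' Order ratio of the flow
#'
#' Quantifies how dilation on endfoot-bearing edges perturbs flow `m` hops
#' away.  Two variants share the same nesting:
#'
#' * `on = "ratio"`: the innermost average of
#'   `RS_Q(i, k~) / RS_Q(i, k)` runs over the edges `k~` at order `m` from
#'   `k`; the middle average over all endfoot-bearing edges `k` (edges
#'   whose order-`m` shell is empty are skipped); the outer average over
#'   time points.  The three averages are nested in exactly this order,
#'   never pooled.  On a run without dilation this curve is identically 1.
#' * `on = "variation"`: the per-edge flow variation `v(k) = mean_i
#'   |RS_Q(i, k) - 1|` replaces the raw ratio; the curve is the nested mean
#'   of `v(k~)/v(k)` over the order-`m` shell and then over endfoot edges.
#'   This is the locality profile that decays with distance from the
#'   dilated segment and that the exponential fit (and the conventional
#'   0.1 threshold at orders up to 20) describes; it is undefined on a
#'   dilation-free run.
#'
#' @param ratios a `ratio_series` of flow ratios (see [flow_ratio()]).
#' @param graph the `vascular_graph`.
#' @param coupling an `endfoot_coupling`.
#' @param m_max maximum order (default 20).
#' @param on `"ratio"` (default) or `"variation"`, see Details.
#' @return an `order_ratio_curve` data.frame with columns `m` and `or`.
#' @export
order_ratio <- function(ratios, graph, coupling, m_max = 20L,
                        on = c("ratio", "variation")) {
  on <- match.arg(on)
  ef_edges <- intersect(sort(unique(coupling$edge_id)), ratios$edge_ids)
  if (!length(ef_edges)) stop("no endfoot-bearing edge with a valid baseline")
  lg <- line_graph(graph)
  src_rows <- match(ef_edges, graph$edges$id)
  dmat <- igraph::distances(lg, v = src_rows)      # endfoot edges x all edges
  col_of <- match(graph$edges$id, ratios$edge_ids) # edge row -> rs column (NA if excluded)
  rs <- ratios$rs
  n_t <- nrow(rs)
  k_col <- match(ef_edges, ratios$edge_ids)

  if (on == "variation") {
    v <- colMeans(abs(rs - 1))
    if (all(v[k_col] == 0)) stop("flow variation is zero on every endfoot edge")
  }

  or <- vapply(seq_len(m_max), function(m) {
    if (on == "ratio") {
      per_k <- matrix(NA_real_, n_t, length(ef_edges))
      for (j in seq_along(ef_edges)) {
        shell <- which(dmat[j, ] == m)
        cols <- col_of[shell]
        cols <- cols[!is.na(cols)]
        if (!length(cols)) next
        per_k[, j] <- rowMeans(rs[, cols, drop = FALSE]) / rs[, k_col[j]]
      }
      if (all(is.na(per_k))) return(NA_real_)
      mean(rowMeans(per_k, na.rm = TRUE))
    } else {
      per_k <- rep(NA_real_, length(ef_edges))
      for (j in seq_along(ef_edges)) {
        shell <- which(dmat[j, ] == m)
        cols <- col_of[shell]
        cols <- cols[!is.na(cols)]
        if (!length(cols) || v[k_col[j]] == 0) next
        per_k[j] <- mean(v[cols]) / v[k_col[j]]
      }
      if (all(is.na(per_k))) return(NA_real_)
      mean(per_k, na.rm = TRUE)
    }
  }, numeric(1))

  structure(data.frame(m = seq_len(m_max), or = or),
            class = c("order_ratio_curve", "data.frame"))
}

#' Fit an exponential decay to an order-ratio curve
#'
#' Nonlinear least squares of `f(m) = a * exp(-b * m) + c` with `a, b >= 0`,
#' started at `(OR(1) - OR(m_max), 0.1, OR(m_max))`.  A numerically
#' constant curve returns the degenerate fit `(0, 0, mean)`.
#'
#' @param curve an `order_ratio_curve`, or a data.frame with columns `m`,
#'   `or`.
#' @return list with `a`, `b`, `c`, the residual norm `rss`, and the
#'   fitted values.
#' @export
fit_order_decay <- function(curve) {
  df <- stats::na.omit(data.frame(m = curve$m, or = curve$or))
  if (nrow(df) < 4L) stop("need at least 4 orders to fit")
  if (stats::sd(df$or) < 1e-12) {
    return(list(a = 0, b = 0, c = mean(df$or), rss = 0, fitted = df$or))
  }
  start <- list(a = max(df$or[1L] - df$or[nrow(df)], 1e-6), b = 0.1, c = df$or[nrow(df)])
  fit <- minpack.lm::nlsLM(or ~ a * exp(-b * m) + c, data = df, start = start,
                           lower = c(0, 0, -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
       rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit))
}

#' Neighbor-endfeet classification
#'
#' For every edge, counts the endfeet attached to edges within distance
#' order `m_max` (the edge itself counted at order 0), classifies edges by
#' that count, and reports the mean time-averaged resting-state flow ratio
#' per class.  With a layer annotation, also reports the percentage
#' distribution of classes within each requested layer group.
#'
#' @param graph a `vascular_graph`.
#' @param coupling an `endfoot_coupling`.
#' @param ratios a flow `ratio_series` (optional; class means skipped when
#'   absent).
#' @param m_max neighborhood order (default 20).
#' @param layers optional `layer_annotation`.
#' @param layer_groups named list of layer-label vectors, e.g.
#'   `list("L2/L3" = c("L2", "L3"), "L5" = "L5")`.
#' @return a `neighbor_class_summary`: list with `per_edge` (edge id,
#'   neighbor-endfeet count), `histogram`, `class_means` (mean
#'   time-averaged flow ratio per class) and `layer_percentages`.
#' @export
neighbor_endfeet_analysis <- function(graph, coupling, ratios = NULL,
                                      m_max = 20L, layers = NULL,
                                      layer_groups = list("L2/L3" = c("L2", "L3"),
                                                          "L5" = "L5")) {
  cnt <- numeric(graph$M)
  tab <- table(match(coupling$edge_id, graph$edges$id))
  cnt[as.integer(names(tab))] <- as.numeric(tab)
  lg <- line_graph(graph)
  nb <- igraph::ego(lg, order = m_max, nodes = igraph::V(lg))
  n_nbr <- vapply(nb, function(v) sum(cnt[as.integer(v)]), numeric(1))
  per_edge <- data.frame(edge_id = graph$edges$id, n_endfeet = n_nbr)

  hist <- as.data.frame(table(n_endfeet = n_nbr), stringsAsFactors = FALSE)
  hist$n_endfeet <- as.numeric(hist$n_endfeet)
  names(hist)[2] <- "n_edges"

  class_means <- NULL
  if (!is.null(ratios)) {
    tavg <- colMeans(ratios$rs)
    idx <- match(ratios$edge_ids, graph$edges$id)
    cm <- tapply(tavg, n_nbr[idx], mean)
    class_means <- data.frame(n_endfeet = as.numeric(names(cm)),
                              mean_flow_ratio = as.numeric(cm))
  }

  layer_pct <- NULL
  if (!is.null(layers)) {
    layer_pct <- lapply(layer_groups, function(labs) {
      sel <- layers$edge_layer %in% labs
      if (!any(sel)) return(NULL)
      tb <- table(n_nbr[sel])
      data.frame(n_endfeet = as.numeric(names(tb)),
                 percent = 100 * as.numeric(tb) / sum(tb))
    })
  }

  structure(list(per_edge = per_edge, histogram = hist,
                 class_means = class_means, layer_percentages = layer_pct),
            class = "neighbor_class_summary")
}

#' Layer- and vessel-class summaries of a simulation
#'
#' Produces (a) the mean `|Q|` time series per layer and vessel class,
#' (b) the per-layer percentage share of the time-averaged resting-state
#' flow ratio attributable to each class (shares sum to 100% within each
#' layer), (c) per-layer quantile summaries of the time-mean `|Q|` per
#' edge, and (d) depth profiles of edge length and endfeet counts in
#' fixed-width depth bins.
#'
#' @param result a `simulation_result`.
#' @param layers a `layer_annotation` for `result$graph`.
#' @param classes a [classify_vessels()] factor; defaults to the `(0, 6]` /
#'   `>= 14` um flow-share convention.
#' @param depth_bin depth histogram bin width, um (default 25).
#' @return list with data.frames `timeseries`, `shares`,
#'   `layer_quantiles`, `depth_profile`.
#' @export
summarize_by_group <- function(result, layers, classes = NULL, depth_bin = 25) {
  graph <- result$graph
  if (is.null(classes)) classes <- classify_vessels(graph, cap_range = c(0, 6))
  if (length(layers$edge_layer) != graph$M) stop("layer annotation does not cover all edges")
  absQ <- abs(result$Q)
  lay <- as.character(layers$edge_layer)
  cls <- as.character(classes)

  key <- interaction(lay, cls, drop = TRUE)
  ts_list <- lapply(levels(key), function(kk) {
    cols <- which(key == kk)
    parts <- strsplit(kk, "\\.")[[1]]
    data.frame(time = result$time, layer = parts[1], class = parts[2],
               mean_flow = rowMeans(absQ[, cols, drop = FALSE]))
  })
  timeseries <- do.call(rbind, ts_list)

  # per-layer class shares of the time-averaged resting-state flow ratio
  fr <- flow_ratio(result)
  tavg <- colMeans(fr$rs)
  idx <- match(fr$edge_ids, graph$edges$id)
  df <- data.frame(layer = lay[idx], class = cls[idx], tavg = tavg)
  ag <- stats::aggregate(tavg ~ layer + class, df, mean)
  shares <- do.call(rbind, lapply(split(ag, ag$layer), function(s) {
    s$share <- 100 * s$tavg / sum(s$tavg)
    s
  }))
  rownames(shares) <- NULL

  # per-layer quantiles of the per-edge time-mean |Q|
  edge_mean <- colMeans(absQ)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  lq <- do.call(rbind, lapply(split(seq_len(graph$M), paste(lay, cls)), function(ii) {
    q <- stats::quantile(edge_mean[ii], qs)
    data.frame(layer = lay[ii[1]], class = cls[ii[1]], n_edges = length(ii),
               q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5])
  }))
  rownames(lq) <- NULL

  # depth profile: edge length per class and endfeet per depth bin
  ed <- edge_depth(graph)
  bins <- floor(ed / depth_bin) * depth_bin
  len_ag <- stats::aggregate(graph$edges$length,
                             list(depth = bins, class = cls), sum)
  names(len_ag)[3] <- "edge_length"
  ef_row <- match(result$coupling$edge_id, graph$edges$id)
  ef_bin <- floor(ed[ef_row] / depth_bin) * depth_bin
  ef_tab <- as.data.frame(table(depth = ef_bin), stringsAsFactors = FALSE)
  ef_tab$depth <- as.numeric(ef_tab$depth)
  names(ef_tab)[2] <- "n_endfeet"
  depth_profile <- merge(len_ag, ef_tab, by = "depth", all = TRUE)

  list(timeseries = timeseries, shares = shares, layer_quantiles = lq,
       depth_profile = depth_profile)
}

#' Planar heatmap grid of mean flow
#'
#' Averages `|Q|` of the selected edges at one time point over a planar
#' grid (depth x one lateral axis), the standard way of visualising
#' layer-resolved flow.
#'
#' @param result a `simulation_result`.
#' @param time_point time (s) at which to evaluate (nearest recorded step).
#' @param edges optional logical/integer subset of edge rows.
#' @param cell grid cell size `c(lateral, depth)` in um (default 17 x 21).
#' @param lateral_axis which non-depth coordinate spans the x axis.
#' @return data.frame with `lateral`, `depth`, `mean_flow`, `n_edges`.
#' @export
flow_heatmap <- function(result, time_point = 3, edges = NULL,
                         cell = c(17, 21), lateral_axis = NULL) {
  graph <- result$graph
  i <- which.min(abs(result$time - time_point))
  if (is.null(edges)) edges <- seq_len(graph$M)
  ax <- graph$depth_axis
  if (is.null(lateral_axis)) lateral_axis <- setdiff(1:3, ax)[1]
  pos <- graph$nodes[, c("x", "y", "z")]
  mid <- (pos[graph$edges$ia, ] + pos[graph$edges$ib, ]) / 2
  lat <- floor(mid[edges, lateral_axis] / cell[1]) * cell[1]
  dep <- floor(mid[edges, ax] / cell[2]) * cell[2]
  q <- abs(result$Q[i, edges])
  ag <- stats::aggregate(q, list(lateral = lat, depth = dep),
                         function(v) c(mean(v), length(v)))
  data.frame(lateral = ag$lateral, depth = ag$depth,
             mean_flow = ag$x[, 1], n_edges = ag$x[, 2])
}
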