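#' Parameters for synthetic vasculature generation
#'
#' Defaults emulate a layered cortical micro-angioarchitecture inside a
#' 954 x 1453 x 853 um bounding box: a handful of large penetrating vessels
#' descending from the cortical surface with tapering side branches, and a
#' dense capillary mesh whose density increases with depth, wired by
#' nearest-neighbour proximity to a mean degree of about 3.  Radii are drawn
#' from truncated normal distributions chosen so the conventional diameter
#' thresholds (6 um capillary, 14 um large) produce all three vessel
#' classes.
#'
#' @param extent 3-vector, box size in um (x, y, z); depth runs along
#'   `depth_axis`.
#' @param n_capillary_nodes number of capillary mesh nodes.
#' @param n_penetrating_vessels number of large penetrating vessels.
#' @param capillary_radius `c(mean, sd, min)` of the truncated normal for
#'   capillary node radii, um.
#' @param large_radius `c(mean, sd, min)` for penetrating-vessel root radii,
#'   um.
#' @param knn neighbours per capillary node when wiring the mesh (mean
#'   degree approximately `2 * knn * (1 - overlap)`, about 3 for `knn = 2`).
#' @param n_exit_stubs dangling venous drainage stubs grafted onto deep
#'   capillary nodes; these guarantee degree-1 exit nodes for the boundary
#'   conditions.
#' @param depth_axis coordinate of increasing cortical depth (default 2).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list of class `synthesis_params`.
#' @export
synthesis_params <- function(extent = c(954, 1453, 853),
                             n_capillary_nodes = 3700L,
                             n_penetrating_vessels = 3L,
                             capillary_radius = c(mean = 2.5, sd = 0.5, min = 0.5),
                             large_radius = c(mean = 10, sd = 3, min = 7),
                             knn = 2L,
                             n_exit_stubs = 8L,
                             depth_axis = 2L,
                             seed = 1L) {
  stopifnot(length(extent) == 3L, all(extent > 0),
            n_capillary_nodes > 0, n_penetrating_vessels >= 0,
            capillary_radius[["min"]] > 0, large_radius[["min"]] > 0,
            knn >= 1L, n_exit_stubs >= 0L)
  structure(list(extent = extent,
                 n_capillary_nodes = as.integer(n_capillary_nodes),
                 n_penetrating_vessels = as.integer(n_penetrating_vessels),
                 capillary_radius = capillary_radius,
                 large_radius = large_radius,
                 knn = as.integer(knn),
                 n_exit_stubs = as.integer(n_exit_stubs),
                 depth_axis = as.integer(depth_axis),
                 seed = as.integer(seed)),
            class = "synthesis_params")
}

rtruncnorm_pos <- function(n, mean, sd, min) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < min)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < min]
  }
  x
}

# depth density linearly increasing: f(z) proportional to 1 + z on [0, 1];
# inverse-CDF sampling gives the deep-capillary dominance seen in cortex
sample_depth <- function(n, depth_extent) {
  u <- stats::runif(n)
  depth_extent * (sqrt(1 + 3 * u) - 1) / 1
}

#' Generate a layered synthetic vascular network
#'
#' Builds penetrating large vessels descending from the top (shallow) face,
#' each with tapering connector branches, plus a proximity-wired capillary
#' mesh with depth-increasing density; the result is reduced to a single
#' connected component by adding shortest bridging edges where needed.
#' Deterministic given `params$seed`.
#'
#' @param params a [synthesis_params()] object.
#' @return a connected `vascular_graph`.
#' @export
generate_vasculature <- function(params = synthesis_params()) {
  stopifnot(inherits(params, "synthesis_params"))
  withr::with_seed(params$seed, generate_vasculature_impl(params))
}

generate_vasculature_impl <- function(params) {
  ax <- params$depth_axis
  lat <- setdiff(1:3, ax)            # the two lateral axes
  D <- params$extent[ax]

  pos <- matrix(numeric(0), 0, 3)
  rad <- numeric(0)
  ea <- integer(0); eb <- integer(0)
  pen_tip <- integer(0)              # connector-branch tips to splice into the mesh

  add_node <- function(p, r) {
    pos <<- rbind(pos, p); rad <<- c(rad, r); nrow(pos)
  }
  add_edge <- function(i, j) { ea <<- c(ea, i); eb <<- c(eb, j) }

  ## penetrating large vessels: straight descending trunks with taper
  for (v in seq_len(params$n_penetrating_vessels)) {
    r0 <- rtruncnorm_pos(1, params$large_radius[["mean"]],
                         params$large_radius[["sd"]], params$large_radius[["min"]])
    base <- numeric(3)
    base[lat] <- stats::runif(2, 0.15, 0.85) * params$extent[lat]
    step <- 40
    depth_reach <- stats::runif(1, 0.55, 0.75) * D
    depths <- seq(0, depth_reach, by = step)
    n_tr <- length(depths)
    # trunk radius tapers from root to the large-vessel floor (7 um)
    r_tr <- seq(r0, max(7, params$large_radius[["min"]]), length.out = n_tr)
    prev <- NA_integer_
    trunk_nodes <- integer(0)
    for (i in seq_len(n_tr)) {
      p <- base
      p[ax] <- depths[i]
      p[lat] <- p[lat] + stats::rnorm(2, 0, 4)
      id <- add_node(p, r_tr[i])
      trunk_nodes <- c(trunk_nodes, id)
      if (!is.na(prev)) add_edge(prev, id)
      prev <- id
    }
    # connector branches: short chains tapering from trunk to capillary scale
    branch_at <- trunk_nodes[seq(2L, n_tr, by = 3L)]
    for (b in branch_at) {
      r_chain <- c(4.5, 3.0)         # pass through "other" sizes down to capillary
      prev_b <- b
      p <- pos[b, ]
      for (rc in r_chain) {
        p[lat] <- p[lat] + stats::rnorm(2, 0, 25)
        p[ax] <- p[ax] + abs(stats::rnorm(1, 15, 8))
        p <- pmin(pmax(p, 0), params$extent)
        id <- add_node(p, rc)
        add_edge(prev_b, id)
        prev_b <- id
      }
      pen_tip <- c(pen_tip, prev_b)
    }
  }

  ## capillary mesh: depth-weighted positions, truncated-normal radii
  nc <- params$n_capillary_nodes
  cap_pos <- matrix(0, nc, 3)
  cap_pos[, lat[1]] <- stats::runif(nc) * params$extent[lat[1]]
  cap_pos[, lat[2]] <- stats::runif(nc) * params$extent[lat[2]]
  cap_pos[, ax] <- sample_depth(nc, D)
  cap_rad <- rtruncnorm_pos(nc, params$capillary_radius[["mean"]],
                            params$capillary_radius[["sd"]],
                            params$capillary_radius[["min"]])
  off <- nrow(pos)
  pos <- rbind(pos, cap_pos)
  rad <- c(rad, cap_rad)
  cap_idx <- off + seq_len(nc)

  # k-nearest-neighbour wiring within the capillary cloud (chunked distances)
  k <- params$knn
  nn <- matrix(0L, nc, k)
  chunk <- 256L
  for (s in seq(1L, nc, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nc)
    d2 <- outer(cap_pos[idx, ax], cap_pos[, ax], "-")^2 +
          outer(cap_pos[idx, lat[1]], cap_pos[, lat[1]], "-")^2 +
          outer(cap_pos[idx, lat[2]], cap_pos[, lat[2]], "-")^2
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf
      nn[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  for (j in seq_len(k)) {
    add_edge(cap_idx, off + nn[, j])
  }

  # splice penetrating-branch tips into the capillary mesh (nearest capillary)
  for (tip in pen_tip) {
    d2 <- rowSums(sweep(cap_pos, 2, pos[tip, ])^2)
    add_edge(tip, off + which.min(d2))
  }

  # venous drainage stubs: dangling degree-1 exits grafted onto deep nodes
  if (params$n_exit_stubs > 0L) {
    deep <- which(cap_pos[, ax] > 0.5 * D)
    host <- sample(deep, min(params$n_exit_stubs, length(deep)))
    for (h in host) {
      p <- cap_pos[h, ]
      p[lat] <- p[lat] + stats::rnorm(2, 0, 20)
      p[ax] <- min(p[ax] + abs(stats::rnorm(1, 30, 10)), D)
      id <- add_node(pmin(pmax(p, 0), params$extent), cap_rad[h])
      add_edge(off + h, id)
    }
  }

  ## deduplicate undirected edges, drop accidental loops
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  keep <- !duplicated(cbind(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]

  ## connect remaining components by shortest bridges
  g <- igraph::make_graph(rbind(lo, hi), n = nrow(pos), directed = FALSE)
  comp <- igraph::components(g)
  guard <- 0L
  while (comp$no > 1L && guard < 1000L) {
    main <- which.max(comp$csize)
    other <- which(comp$membership != main)
    inm <- which(comp$membership == main)
    # nearest pair between the main component and the rest
    best <- c(NA_integer_, NA_integer_, Inf)
    for (o in other[order(pos[other, ax])][seq_len(min(50L, length(other)))]) {
      d2 <- rowSums(sweep(pos[inm, , drop = FALSE], 2, pos[o, ])^2)
      w <- which.min(d2)
      if (d2[w] < best[3]) best <- c(o, inm[w], d2[w])
    }
    lo <- c(lo, min(best[1], best[2])); hi <- c(hi, max(best[1], best[2]))
    g <- igraph::make_graph(rbind(lo, hi), n = nrow(pos), directed = FALSE)
    comp <- igraph::components(g)
    guard <- guard + 1L
  }
  if (comp$no > 1L) stop("could not connect synthetic network within retry budget")

  nodes <- data.frame(id = seq_len(nrow(pos)),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      radius = rad)
  edges <- data.frame(id = seq_along(lo), node_a = lo, node_b = hi)
  vascular_graph(nodes, edges, depth_axis = params$depth_axis)
}

#' Place astrocytic endfeet on vessel segments
#'
#' Each astrocyte contributes two endfeet.  An endfoot attaches to an edge
#' with probability proportional to the edge's lateral surface area
#' (2 pi r l) times a vessel-class weight, which biases the coverage toward
#' capillaries.  Deterministic given `seed`.
#'
#' @param graph a nonempty `vascular_graph`.
#' @param n_astrocytes number of astrocytes (endfeet count is twice this).
#' @param seed integer seed.
#' @param class_weights named weights for `capillary`, `large`, `other`.
#' @param classes optional precomputed [classify_vessels()] factor.
#' @param endfeet_per_astrocyte endfeet per astrocyte (default 2).
#' @param ensure_edges edge ids guaranteed to carry at least one endfoot
#'   (endfeet are reassigned to them deterministically if the weighted draw
#'   misses them).  Typically the entry edges, which in the reference
#'   anatomy are all endfoot-connected, so the imposed inflow inherits
#'   their stochastic dilation.
#' @return an `endfoot_coupling` data.frame with columns `endfoot_id`,
#'   `astrocyte_id`, `edge_id`.
#' @export
place_endfeet <- function(graph, n_astrocytes, seed = 1L,
                          class_weights = c(capillary = 1, large = 0.3, other = 0.6),
                          classes = NULL,
                          endfeet_per_astrocyte = 2L,
                          ensure_edges = NULL) {
  if (graph$M == 0L) stop("graph has no edges")
  if (n_astrocytes <= 0) stop("n_astrocytes must be positive")
  if (is.null(classes)) classes <- classify_vessels(graph, cap_range = c(0, 6))
  w <- 2 * pi * graph$edges$radius * graph$edges$length *
       unname(class_weights[as.character(classes)])
  if (!any(w > 0)) stop("all placement weights are zero")
  n_end <- as.integer(n_astrocytes) * as.integer(endfeet_per_astrocyte)
  pick <- withr::with_seed(seed, sample.int(graph$M, n_end, replace = TRUE, prob = w))
  edge_id <- graph$edges$id[pick]
  missing <- setdiff(ensure_edges, edge_id)
  if (length(missing)) {
    if (length(missing) > n_end) stop("more ensure_edges than endfeet")
    edge_id[seq_along(missing)] <- missing
  }
  structure(data.frame(endfoot_id = seq_len(n_end),
                       astrocyte_id = rep(seq_len(n_astrocytes),
                                          each = endfeet_per_astrocyte),
                       edge_id = edge_id),
            class = c("endfoot_coupling", "data.frame"))
}

#' Exactly solvable hydraulic toy fixtures
#'
#' Small networks whose steady Hagen-Poiseuille solution is known in closed
#' form, used as solver oracles.  Each fixture returns the graph plus a
#' descriptor with the analytic conductances / flow splits.
#'
#' Available fixtures: `single_tube` (one pipe), `series_chain` (three pipes
#' in series), `y_junction` (parent splitting into two identical daughters),
#' `parallel_loop` (two two-pipe limbs between a common inlet and outlet),
#' `line_n` (a path of `n` pipes), `star_n` (a hub with `n` rays).
#'
#' @param name fixture name.
#' @param params a [hydraulic_params()] object used for the analytic
#'   conductances.
#' @param n number of edges for `line_n` / rays for `star_n`.
#' @param l,r default pipe length and radius (um).
#' @return list with elements `graph` and `descriptor`.
#' @export
make_toy_fixture <- function(name = c("single_tube", "series_chain", "y_junction",
                                      "parallel_loop", "line_n", "star_n"),
                             params = hydraulic_params(), n = 5L, l = 100, r = 2) {
  name <- match.arg(name)
  g_of <- function(l, r) pi * r^2 / (corrected_resistance(r, params) * l)
  nd <- function(id, x, y, z, radius) data.frame(id = id, x = x, y = y, z = z, radius = radius)
  switch(name,
    single_tube = {
      nodes <- nd(1:2, 0, c(0, l), 0, r)
      edges <- data.frame(id = 1L, node_a = 1L, node_b = 2L)
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(g = g_of(l, r), l = l, r = r))
    },
    series_chain = {
      rr <- c(2, 3, 1.5); ll <- c(100, 80, 120)
      nodes <- nd(1:4, 0, c(0, cumsum(ll)), 0, radius = c(rr[1], (rr[1] + rr[2]) / 2, (rr[2] + rr[3]) / 2, rr[3]))
      edges <- data.frame(id = 1:3, node_a = 1:3, node_b = 2:4, length = ll, radius = rr)
      gs <- g_of(ll, rr)
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(g = gs, R_total = sum(1 / gs),
                             # pressure drop per edge for unit total flow
                             dp_frac = (1 / gs) / sum(1 / gs)))
    },
    y_junction = {
      nodes <- nd(1:4, c(0, 0, -50, 50), c(0, 100, 200, 200), 0, radius = c(3, 3, 2, 2))
      edges <- data.frame(id = 1:3, node_a = c(1L, 2L, 2L), node_b = c(2L, 3L, 4L),
                          length = c(100, sqrt(50^2 + 100^2), sqrt(50^2 + 100^2)),
                          radius = c(3, 2, 2))
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(split = c(0.5, 0.5), parent_edge = 1L, daughters = c(2L, 3L)))
    },
    parallel_loop = {
      # inlet pipe into node 2, two parallel three-pipe limbs of unequal
      # radius rejoining at outlet node 7; split ratio = limb conductances
      nodes <- nd(1:8,
                  x = c(0, 0, -60, -60, 60, 60, 0, 0),
                  y = c(0, 80, 150, 250, 150, 250, 330, 410),
                  z = 0,
                  radius = c(3, 3, 2.5, 2.5, 1.8, 1.8, 3, 3))
      lA <- c(95, 100, 110); rA <- c(2.5, 2.5, 2.5)
      lB <- c(95, 100, 110); rB <- c(1.8, 1.8, 1.8)
      edges <- data.frame(id = 1:8,
                          node_a = c(1L, 2L, 3L, 4L, 2L, 5L, 6L, 7L),
                          node_b = c(2L, 3L, 4L, 7L, 5L, 6L, 7L, 8L),
                          length = c(80, lA, lB, 80),
                          radius = c(3, rA, rB, 3))
      gA <- 1 / sum(1 / g_of(lA, rA))
      gB <- 1 / sum(1 / g_of(lB, rB))
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(split = c(A = gA, B = gB) / (gA + gB),
                             limb_edges = list(A = 2:4, B = 5:7),
                             inlet_edge = 1L))
    },
    line_n = {
      nodes <- nd(seq_len(n + 1L), 0, seq(0, by = l, length.out = n + 1L), 0, r)
      edges <- data.frame(id = seq_len(n), node_a = seq_len(n), node_b = seq_len(n) + 1L)
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(g = g_of(l, r), R_total = n / g_of(l, r), n = n))
    },
    star_n = {
      th <- 2 * pi * seq_len(n) / n
      nodes <- nd(seq_len(n + 1L),
                  x = c(0, l * cos(th)), y = c(0, 100 + l * sin(th)), z = 0, radius = r)
      edges <- data.frame(id = seq_len(n), node_a = 1L, node_b = seq_len(n) + 1L,
                          length = l, radius = r)
      list(graph = vascular_graph(nodes, edges),
           descriptor = list(g = g_of(l, r), n = n, hub = 1L))
    }
  )
}
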