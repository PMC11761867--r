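# shared fixtures built in code

# minimal two-node, one-edge graph
tiny_graph <- function(l = 100, r = c(2, 4)) {
  vascular_graph(
    nodes = data.frame(id = 1:2, x = c(0, l), y = 0, z = 0, radius = r),
    edges = data.frame(id = 1L, node_a = 1L, node_b = 2L),
    depth_axis = 1L
  )
}

# small synthetic network memoized across tests
small_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_vasculature(synthesis_params(
        n_capillary_nodes = 600L, extent = c(400, 600, 400), seed = 42L))
    }
    cache
  }
})

# a short stimulated simulation on the small network, memoized
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- small_net()
      bc <- select_boundary_nodes(g)
      ef <- place_endfeet(g, n_astrocytes = 40L, seed = 7L,
                          ensure_edges = bc$entry_edges)
      cfg <- simulation_config(n_steps = 120L, stim_end = 0.8, seed = 3L,
                               sigma = c(capillary = 0.3, large = 0.17))
      cache <<- list(graph = g, bc = bc, coupling = ef, config = cfg,
                     result = run_simulation(g, ef, cfg, bc = bc))
    }
    cache
  }
})

# brute-force all-pairs shortest paths on the line graph (independent oracle
# for distance orders): Floyd-Warshall over the edge-adjacency matrix
brute_force_edge_orders <- function(graph) {
  m <- graph$M
  d <- matrix(Inf, m, m)
  diag(d) <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      share <- length(intersect(c(graph$edges$ia[i], graph$edges$ib[i]),
                                c(graph$edges$ia[j], graph$edges$ib[j]))) > 0
      if (share) d[i, j] <- d[j, i] <- 1
    }
  }
  for (k in seq_len(m)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# interior-node net-flux residuals for every recorded step of a result
interior_residuals <- function(result) {
  graph <- result$graph
  bd <- match(c(result$bc$entry_nodes, result$bc$exit_nodes), graph$nodes$id)
  interior <- setdiff(seq_len(graph$N), bd)
  inc_a <- result$graph$edges$ia
  inc_b <- result$graph$edges$ib
  vapply(seq_along(result$time), function(i) {
    q <- result$Q[i, ]
    net <- numeric(graph$N)
    agg_a <- rowsum(-q, inc_a); net[as.integer(rownames(agg_a))] <- agg_a[, 1]
    agg_b <- rowsum(q, inc_b)
    net[as.integer(rownames(agg_b))] <- net[as.integer(rownames(agg_b))] + agg_b[, 1]
    max(abs(net[interior])) / max(abs(q))
  }, numeric(1))
}
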