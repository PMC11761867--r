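test_that("Poiseuille friction follows 8*eta/r^2 in both radius and area form", {
  expect_equal(poiseuille_resistance(2, 1.2e-6), 2.4e-6, tolerance = 1e-12)
  r <- c(0.7, 2, 5.3)
  expect_equal(poiseuille_resistance(r), 8 * 1.2e-6 * pi / (pi * r^2), tolerance = 1e-12)
  expect_equal(poiseuille_resistance(2) / poiseuille_resistance(4), 4, tolerance = 1e-12)
  expect_error(poiseuille_resistance(0), "positive")
})

test_that("corrected resistance applies the exponential correction factor", {
  p0 <- hydraulic_params()
  expect_equal(corrected_resistance(3, p0), 4 * poiseuille_resistance(3), tolerance = 1e-12)
  p1 <- hydraulic_params(alpha = 0.5, beta = 5, gamma = 0.1, delta = 10)
  expect_equal(corrected_resistance(5, p1),
               4 * poiseuille_resistance(5) * (1 - 0.5 * exp(-1) + 0.1 * exp(-0.5)),
               tolerance = 1e-12)
  # exponentials vanish at large radius
  expect_equal(corrected_resistance(1e4, p1) / (4 * poiseuille_resistance(1e4)), 1,
               tolerance = 1e-10)
  expect_error(corrected_resistance(0.01, hydraulic_params(alpha = 10, beta = 100)),
               "unphysical")
})

test_that("edge conductance reduces to pi r^4 / (32 eta l) and scales correctly", {
  g <- edge_conductance(100, 2)
  expect_equal(g, pi * 16 / (32 * 1.2e-6 * 100), tolerance = 1e-12)
  expect_equal(edge_conductance(100, 4) / g, 16, tolerance = 1e-12)
  expect_equal(edge_conductance(200, 2) / g, 0.5, tolerance = 1e-12)
})

test_that("entry selection ranks degree-1 nodes by radius then shallowness", {
  fx <- make_toy_fixture("single_tube")
  bc <- select_boundary_nodes(fx$graph, k_entries = 1L)
  expect_equal(bc$entry_nodes, 1L)   # the shallower endpoint
  expect_equal(bc$exit_nodes, 2L)

  # three top arterioles of radii 12, 10, 9 among smaller leaves
  nodes <- data.frame(id = 1:8,
                      x = c(0, 100, 200, 300, 0, 100, 200, 300),
                      y = c(0, 0, 0, 500, 1000, 1000, 1000, 0),
                      z = 0,
                      radius = c(12, 10, 9, 5, 2, 2, 2, 8))
  edges <- data.frame(id = 1:7, node_a = c(1, 2, 3, 8, 4, 4, 4),
                      node_b = c(4, 4, 4, 4, 5, 6, 7))
  g <- vascular_graph(nodes, edges)
  bc3 <- select_boundary_nodes(g, k_entries = 3L)
  expect_setequal(bc3$entry_nodes, c(1L, 2L, 3L))
  expect_error(select_boundary_nodes(g, k_entries = 7L), "degree-1")
})

test_that("boundary inflow is velocity times entry cross-section", {
  nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0, radius = 5)
  g <- vascular_graph(nodes, data.frame(id = 1L, node_a = 1L, node_b = 2L))
  bc <- select_boundary_nodes(g, k_entries = 1L)
  q <- boundary_inflow(0, bc, g)
  expect_equal(q, 3.5e4 * pi * 25, tolerance = 1e-12)
  # dilation of the entry edge scales inflow with the area
  expect_equal(boundary_inflow(0, bc, g, radii = 6) / q, 1.44, tolerance = 1e-12)
  # constant in time with zero modulation amplitude
  expect_equal(boundary_inflow(2.3, bc, g), q)
})

test_that("single tube, series chain, junction and loop match closed forms", {
  tol <- 1e-10

  fx <- make_toy_fixture("single_tube")
  bc <- select_boundary_nodes(fx$graph, k_entries = 1L)
  fs <- solve_flow(fx$graph, bc = bc)
  expect_equal(fs$Q[1], fs$inflow, tolerance = tol)
  expect_equal(fs$Q[1] / (fs$p[1] - fs$p[2]), fx$descriptor$g, tolerance = tol)

  fc <- make_toy_fixture("series_chain")
  bcc <- select_boundary_nodes(fc$graph, k_entries = 1L)
  fsc <- solve_flow(fc$graph, bc = bcc)
  expect_equal(fsc$Q, rep(fsc$inflow, 3), tolerance = tol)        # same Q on all edges
  drops <- abs(diff(fsc$p))
  expect_equal(drops / sum(drops), fc$descriptor$dp_frac, tolerance = tol)
  expect_equal(max(abs(fsc$p)) / fsc$inflow, fc$descriptor$R_total, tolerance = tol)

  fy <- make_toy_fixture("y_junction")
  bcy <- select_boundary_nodes(fy$graph, k_entries = 1L)
  fsy <- solve_flow(fy$graph, bc = bcy)
  expect_equal(abs(fsy$Q[2:3]) / fsy$inflow, c(0.5, 0.5), tolerance = tol)

  fp <- make_toy_fixture("parallel_loop")
  bcp <- select_boundary_nodes(fp$graph, k_entries = 1L)
  fsp <- solve_flow(fp$graph, bc = bcp)
  qa <- abs(fsp$Q[fp$descriptor$limb_edges$A[1]])
  qb <- abs(fsp$Q[fp$descriptor$limb_edges$B[1]])
  expect_equal(c(qa, qb) / (qa + qb), unname(fp$descriptor$split), tolerance = tol)
})

test_that("flow at fixed pressure drop scales as r^4", {
  q_over_dp <- function(r) {
    g <- tiny_graph(l = 100, r = c(r, r))
    bc <- select_boundary_nodes(g, k_entries = 1L)
    fs <- solve_flow(g, bc = bc)
    fs$Q[1] / (fs$p[1] - fs$p[2])
  }
  expect_equal(q_over_dp(4) / q_over_dp(2), 16, tolerance = 1e-10)
})

test_that("mass is conserved and backends agree on a synthetic network", {
  g <- small_net()
  bc <- select_boundary_nodes(g)
  fd <- solve_flow(g, bc = bc, backend = "direct")
  expect_lt(conservation_residual(g, fd, bc), 1e-8 * max(abs(fd$Q)))
  expect_lt(fd$balance, 1e-8)
  expect_equal(sum(fd$exit_flows), fd$inflow, tolerance = 1e-8)

  fi <- solve_flow(g, bc = bc, backend = "iterative", tol = 1e-12)
  expect_equal(fi$p, fd$p, tolerance = 1e-6)
  expect_equal(fi$Q, fd$Q, tolerance = 1e-6)
})

test_that("flipping an edge orientation only flips the sign of its flow", {
  g <- small_net()
  bc <- select_boundary_nodes(g)
  fs1 <- solve_flow(g, bc = bc)
  g2 <- g
  flip <- 10L
  g2$edges$ia[flip] <- g$edges$ib[flip]
  g2$edges$ib[flip] <- g$edges$ia[flip]
  fs2 <- solve_flow(g2, bc = bc)
  expect_equal(fs2$p, fs1$p, tolerance = 1e-12)
  expect_equal(fs2$Q[flip], -fs1$Q[flip], tolerance = 1e-12)
  expect_equal(fs2$Q[-flip], fs1$Q[-flip], tolerance = 1e-12)
})

test_that("degenerate boundary setups raise clear errors", {
  g <- tiny_graph()
  expect_error(boundary_conditions(entry_nodes = 1L, exit_nodes = integer(),
                                   entry_edges = 1L), "nonempty")
  expect_error(boundary_conditions(entry_nodes = 1L, exit_nodes = 1L,
                                   entry_edges = 1L), "disjoint")
})
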