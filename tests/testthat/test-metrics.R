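ratio_series_from <- function(rs, edge_ids = seq_len(ncol(rs))) {
  structure(list(rs = rs, edge_ids = edge_ids, n_excluded = 0L),
            class = "ratio_series")
}

test_that("resting-state ratios are baseline-normalized and start at 1", {
  traj <- cbind(c(2, 2, 2), c(1, 2, 4))
  rs <- resting_state_ratio(traj)
  expect_equal(rs$rs[, 1], c(1, 1, 1))
  expect_equal(rs$rs[, 2], c(1, 2, 4))
  expect_true(all(rs$rs[1, ] == 1))

  # signed flows are ratioed on magnitude
  rs2 <- resting_state_ratio(cbind(c(-2, 4)), use_abs = TRUE)
  expect_equal(rs2$rs[2, 1], 2)

  # zero-baseline edges are excluded with a warning
  expect_warning(rs3 <- resting_state_ratio(cbind(c(0, 1), c(1, 3))), "excluded")
  expect_equal(rs3$n_excluded, 1L)
  expect_equal(ncol(rs3$rs), 1L)
  expect_warning(rs4 <- resting_state_ratio(cbind(c(0, 0))), "zero baseline")
  expect_equal(ncol(rs4$rs), 0L)
})

test_that("average ratio nests subset mean then time mean", {
  rs <- ratio_series_from(cbind(c(1, 1, 1), c(1, 3, 5)))
  # singleton subset equals that edge's RS series
  a1 <- average_ratio(rs, subset = 2L)
  expect_equal(a1$ar_t, c(1, 3, 5))
  # two edges with ratios 1 and 3 average to 2
  expect_equal(average_ratio(rs)$ar_t[2], 2)
  # time-constant series collapse to the constant
  expect_equal(average_ratio(rs, subset = 1L)$ar, 1)
  expect_error(average_ratio(rs, subset = 99L), "empty subset")
})

test_that("distance orders follow the line-graph shortest paths", {
  ln <- make_toy_fixture("line_n", n = 5L)$graph
  km <- distance_orders(ln, k = 3L, m_max = 3L)
  expect_setequal(km[[1]], c(2L, 4L))
  expect_setequal(km[[2]], c(1L, 5L))
  expect_length(km[[3]], 0L)

  st <- make_toy_fixture("star_n", n = 6L)$graph
  ks <- distance_orders(st, k = 1L, m_max = 2L)
  expect_setequal(ks[[1]], 2:6)   # all rays share the hub
  expect_length(ks[[2]], 0L)

  expect_error(distance_orders(ln, k = 3L, m_max = 0L), "m_max")
  expect_error(distance_orders(ln, k = 99L), "unknown edge")
})

test_that("distance orders match a brute-force Floyd-Warshall oracle", {
  graphs <- list(
    make_toy_fixture("parallel_loop")$graph,
    make_toy_fixture("star_n", n = 8L)$graph,
    generate_vasculature(synthesis_params(n_capillary_nodes = 150L,
                                          extent = c(300, 400, 300), seed = 77L))
  )
  for (g in graphs) {
    expect_lte(g$M, 300L)
    oracle <- brute_force_edge_orders(g)
    m_max <- 6L
    for (k_row in seq_len(g$M)) {
      km <- distance_orders(g, k = g$edges$id[k_row], m_max = m_max)
      for (m in seq_len(m_max)) {
        expect_setequal(km[[m]], g$edges$id[which(oracle[k_row, ] == m)])
      }
    }
  }
})

test_that("order ratio uses the nested averaging order, never pooled", {
  # path of 3 edges, endfeet on edges 1 and 2, time-constant ratios 2, 3, 5
  ln <- make_toy_fixture("line_n", n = 3L)$graph
  rs <- ratio_series_from(matrix(rep(c(2, 3, 5), each = 4), nrow = 4))
  coupling <- data.frame(endfoot_id = 1:2, astrocyte_id = 1L, edge_id = 1:2)
  or <- order_ratio(rs, ln, coupling, m_max = 2L)
  # hand computation: k=1 -> mean({3})/2 = 3/2 ; k=2 -> mean({2,5})/3 = 7/6
  # nested mean = (3/2 + 7/6)/2 = 4/3 ; pooled mean would be 23/18
  expect_equal(or$or[1], 4 / 3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(or$or[1], 23 / 18)))

  # no dilation: identically 1 at every order
  rs1 <- ratio_series_from(matrix(1, 4, 3))
  or1 <- order_ratio(rs1, ln, coupling, m_max = 2L)
  expect_equal(or1$or, rep(1, 2))

  expect_error(order_ratio(ratio_series_from(matrix(1, 2, 3), edge_ids = 7:9),
                           ln, coupling), "endfoot")
})

test_that("order ratio decays with distance from dilated interior edges", {
  # interior capillaries dilating in a mesh: the perturbation attenuates
  # with distance order, for both the raw-ratio and the variation profile
  g <- generate_vasculature(synthesis_params(n_capillary_nodes = 250L,
                                             extent = c(300, 450, 300), seed = 12L))
  bc <- select_boundary_nodes(g)
  cls <- classify_vessels(g, cap_range = c(0, 6))
  fs0 <- solve_flow(g, bc = bc)
  cand <- setdiff(which(cls == "capillary" & abs(fs0$Q) > 1e-6 * max(abs(fs0$Q))),
                  match(bc$entry_edges, g$edges$id))
  m_max <- 8L
  curves <- sapply(1:6, function(s) {
    hosts <- withr::with_seed(s, sample(cand, 4L))
    coupling <- data.frame(endfoot_id = 1:4, astrocyte_id = rep(1:2, each = 2),
                           edge_id = g$edges$id[hosts])
    cfg <- simulation_config(n_steps = 150L, stim_end = 1.5, seed = s, sigma = 0.3)
    res <- run_simulation(g, coupling, cfg, bc = bc)
    fr <- suppressWarnings(flow_ratio(res))
    cbind(order_ratio(fr, g, coupling, m_max = m_max)$or,
          order_ratio(fr, g, coupling, m_max = m_max, on = "variation")$or)
  }, simplify = "array")
  ratio_avg <- rowMeans(curves[, 1, ])
  var_avg <- rowMeans(curves[, 2, ])
  # seed-averaged curves trend downward with order
  expect_lt(stats::cor(ratio_avg, seq_len(m_max)), 0)
  expect_lt(mean(ratio_avg[6:8]), ratio_avg[1])
  expect_lt(mean(var_avg[4:6]), var_avg[1])
})

test_that("exponential fit recovers known decay parameters", {
  m <- 1:20
  truth <- c(a = 0.39, b = 0.07, c = 0.01)
  y <- truth["a"] * exp(-truth["b"] * m) + truth["c"]
  fit <- fit_order_decay(data.frame(m = m, or = y))
  expect_equal(fit$a, unname(truth["a"]), tolerance = 1e-6)
  expect_equal(fit$b, unname(truth["b"]), tolerance = 1e-6)
  expect_equal(fit$c, unname(truth["c"]), tolerance = 1e-6)

  # constant curve degenerates gracefully
  flat <- fit_order_decay(data.frame(m = m, or = rep(0.5, 20)))
  expect_equal(flat$a, 0)
  expect_equal(flat$c, 0.5)

  # 1% multiplicative noise: amplitude and rate recovered within 10%;
  # the offset c = 0.01 sits below the per-point noise, so it is checked
  # at its achievable absolute precision instead
  set.seed(99)
  errs <- replicate(100, {
    yn <- y * (1 + stats::rnorm(20, 0, 0.01))
    f <- fit_order_decay(data.frame(m = m, or = yn))
    abs(c(f$a, f$b, f$c) - truth)
  })
  expect_lt(stats::median(errs[1, ] / truth["a"]), 0.10)
  expect_lt(stats::median(errs[2, ] / truth["b"]), 0.10)
  expect_lt(stats::median(errs[3, ]), 0.007)
  expect_error(fit_order_decay(data.frame(m = 1:3, or = c(1, 0.5, 0.3))), "4 orders")
})

test_that("neighbor-endfeet counting includes the edge itself at order 0", {
  ln <- make_toy_fixture("line_n", n = 5L)$graph
  coupling <- data.frame(endfoot_id = 1:2, astrocyte_id = 1L, edge_id = c(2L, 3L))
  out <- neighbor_endfeet_analysis(ln, coupling, m_max = 1L)
  counts <- out$per_edge$n_endfeet
  # edge 2: own endfoot + order-1 neighbor's endfoot = 2
  expect_equal(counts[2], 2)
  expect_equal(counts, c(1, 2, 2, 1, 0))
  expect_equal(sum(out$histogram$n_edges), ln$M)

  # no endfeet anywhere: every edge in class 0
  none <- neighbor_endfeet_analysis(ln, coupling[0, ], m_max = 2L)
  expect_true(all(none$per_edge$n_endfeet == 0))
})

test_that("neighbor classes on a simulated run report per-class flow ratios", {
  sc <- small_sim()
  ann <- assign_layers(sc$graph, boundaries = seq(0, 600, by = 100))
  out <- neighbor_endfeet_analysis(sc$graph, sc$coupling, flow_ratio(sc$result),
                                   m_max = 5L, layers = ann)
  expect_equal(sum(out$histogram$n_edges), sc$graph$M)
  expect_true(all(out$class_means$mean_flow_ratio > 0))
  for (pct in out$layer_percentages) {
    if (!is.null(pct)) expect_equal(sum(pct$percent), 100, tolerance = 1e-9)
  }
})

test_that("group summaries normalize shares and separate vessel classes", {
  sc <- small_sim()
  ann <- assign_layers(sc$graph, boundaries = seq(0, 600, by = 100))
  sm <- summarize_by_group(sc$result, ann)
  # shares sum to 100% within each layer
  for (s in split(sm$shares, sm$shares$layer)) {
    expect_equal(sum(s$share), 100, tolerance = 1e-9)
  }
  # large vessels carry far more flow than capillaries
  cls <- classify_vessels(sc$graph, cap_range = c(0, 6))
  mean_cap <- mean(abs(sc$result$Q[, cls == "capillary"]))
  mean_lv <- mean(abs(sc$result$Q[, cls == "large"]))
  expect_gt(mean_lv, 10 * mean_cap)
  ts_cap <- subset(sm$timeseries, class == "capillary")
  expect_equal(nrow(ts_cap) %% length(sc$result$time), 0L)

  # single-class network: that class holds 100% share everywhere
  ln <- make_toy_fixture("line_n", n = 4L)$graph
  coupling <- data.frame(endfoot_id = 1L, astrocyte_id = 1L, edge_id = 2L)
  cfg <- simulation_config(n_steps = 10L, stim_end = 0.05, seed = 1L,
                           sigma = 0.2, n_entries = 1L)
  res1 <- run_simulation(ln, coupling, cfg)
  ann1 <- assign_layers(ln, boundaries = c(0, 200, 400))
  sm1 <- summarize_by_group(res1, ann1)
  expect_true(all(sm1$shares$share == 100))
  expect_true(all(sm1$shares$class == "capillary"))
})

test_that("flow heatmaps aggregate edge midpoints on the planar grid", {
  sc <- small_sim()
  hm <- flow_heatmap(sc$result, time_point = 0.5, cell = c(50, 50))
  expect_true(all(hm$n_edges >= 1))
  expect_equal(sum(hm$n_edges), sc$graph$M)
  expect_true(all(hm$mean_flow >= 0))
})
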