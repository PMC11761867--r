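#' Simulation configuration
#'
#' Defaults reproduce the standard protocol: 500 steps of 0.01 s (5 s
#' total), stochastic astrocytic stimulation during the first 3 s, then a
#' noise-free passive relaxation, with blood injected at three entry nodes
#' at a constant velocity of 3.5e4 um/s.
#'
#' @param dt time step, s.
#' @param n_steps number of steps (the trajectory has `n_steps + 1` points).
#' @param stim_end end of the astrocytic stimulation window `[0, stim_end]`, s.
#' @param seed master seed; every stochastic component derives from it.
#' @param n_entries number of entry nodes.
#' @param entry_velocity imposed entry velocity, um/s.
#' @param inflow_amplitude relative amplitude of the sinusoidal inflow
#'   modulation hook (default 0: constant velocity).
#' @param kappa mean-reversion / relaxation rate, s^-1.
#' @param sigma named `c(capillary=, large=)` noise amplitudes, or
#'   `"calibrate"` to calibrate both from `(ratio_max, t_peak)`, or a
#'   single number applied to every class.
#' @param ratio_max named `c(capillary=, large=)` maximum radius ratios.
#' @param t_peak named `c(capillary=, large=)` times to peak, s.
#' @param cap_diameter_max capillary diameter upper bound for dynamics, um;
#'   endfoot-bearing vessels with diameter between this and
#'   `large_diameter_min` get linearly interpolated dilation parameters.
#' @param large_diameter_min large-vessel diameter lower bound, um.
#' @param hydraulic a [hydraulic_params()] object.
#' @param backend flow-solver backend, `"direct"` or `"iterative"`.
#' @param calib_paths Monte-Carlo paths used when `sigma = "calibrate"`.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, n_steps = 500L, stim_end = 3,
                              seed = 1L, n_entries = 3L,
                              entry_velocity = 3.5e4, inflow_amplitude = 0,
                              kappa = 1,
                              sigma = "calibrate",
                              ratio_max = c(capillary = 1.38, large = 1.23),
                              t_peak = c(capillary = 2.7, large = 3.3),
                              cap_diameter_max = 6, large_diameter_min = 14,
                              hydraulic = hydraulic_params(),
                              backend = "direct",
                              calib_paths = 1000L) {
  stopifnot(dt > 0, n_steps >= 1L, stim_end <= dt * n_steps,
            cap_diameter_max < large_diameter_min)
  structure(list(dt = dt, n_steps = as.integer(n_steps), stim_end = stim_end,
                 seed = as.integer(seed), n_entries = as.integer(n_entries),
                 entry_velocity = entry_velocity,
                 inflow_amplitude = inflow_amplitude,
                 kappa = kappa, sigma = sigma,
                 ratio_max = ratio_max, t_peak = t_peak,
                 cap_diameter_max = cap_diameter_max,
                 large_diameter_min = large_diameter_min,
                 hydraulic = hydraulic, backend = backend,
                 calib_paths = as.integer(calib_paths)),
            class = "simulation_config")
}

# per-edge dilation parameters: capillary values below cap_diameter_max,
# large-vessel values above large_diameter_min, linear interpolation between
interp_class_param <- function(d, value, d_lo, d_hi) {
  w <- pmin(pmax((d - d_lo) / (d_hi - d_lo), 0), 1)
  (1 - w) * value[["capillary"]] + w * value[["large"]]
}

# deterministic per-edge noise streams derived from the master seed, so
# adding or removing unrelated edges does not reshuffle a given edge's path
edge_noise_matrix <- function(master_seed, edge_ids, n_steps) {
  out <- matrix(0, n_steps, length(edge_ids))
  for (j in seq_along(edge_ids)) {
    sub <- (as.numeric(master_seed) * 1000003 + as.numeric(edge_ids[j])) %% 2147483647
    out[, j] <- withr::with_seed(as.integer(sub), stats::rnorm(n_steps))
  }
  out
}

#' Run the coupled radii/flow simulation
#'
#' The time loop: at each step, (1) advance the radii of endfoot-bearing
#' edges -- a reflected Ornstein-Uhlenbeck step while `t <= stim_end`, the
#' closed-form exponential relaxation afterwards; (2) recompute edge
#' conductances and the entry inflows from the current entry-edge
#' cross-sections; (3) solve the quasi-static pressure/flow problem;
#' (4) record radii, flows, velocities and pressures.  Time 0 is solved at
#' resting radii and defines the baseline for all ratio metrics.
#'
#' @param graph a connected `vascular_graph` (apply [largest_component()]
#'   first if needed).
#' @param coupling an `endfoot_coupling` from [place_endfeet()] (or any
#'   data.frame with an `edge_id` column).
#' @param config a [simulation_config()].
#' @param bc optional `boundary_conditions`; selected automatically from
#'   the config when omitted.
#' @param verbose print per-phase progress.
#' @return a `simulation_result`: list with `time` (length `n_steps + 1`),
#'   matrices `radii`, `Q`, `u` (time x edge) and `p` (time x node),
#'   `graph`, `coupling`, `bc`, `config`, `sigma` (per-class calibrated
#'   values) and per-step `balance` diagnostics.
#' @export
run_simulation <- function(graph, coupling, config = simulation_config(),
                           bc = NULL, verbose = FALSE) {
  stopifnot(inherits(graph, "vascular_graph"))
  if (igraph::components(as_igraph(graph))$no != 1L) {
    stop("graph must be connected; apply largest_component() first")
  }
  if (is.null(bc)) {
    bc <- select_boundary_nodes(graph, k_entries = config$n_entries,
                                entry_velocity = config$entry_velocity,
                                amplitude = config$inflow_amplitude)
  }

  # class-resolved stochastic parameters
  sig <- config$sigma
  if (identical(sig, "calibrate")) {
    sig <- c(
      capillary = as.numeric(calibrate_rou(config$ratio_max[["capillary"]],
                                           config$t_peak[["capillary"]],
                                           kappa = config$kappa, dt = config$dt,
                                           n_paths = config$calib_paths,
                                           seed = config$seed)),
      large = as.numeric(calibrate_rou(config$ratio_max[["large"]],
                                       config$t_peak[["large"]],
                                       kappa = config$kappa, dt = config$dt,
                                       n_paths = config$calib_paths,
                                       seed = config$seed))
    )
  } else if (length(sig) == 1L && is.numeric(sig)) {
    sig <- c(capillary = unname(sig), large = unname(sig))
  }

  ef_edges <- sort(unique(coupling$edge_id))
  ef_row <- match(ef_edges, graph$edges$id)
  if (anyNA(ef_row)) stop("coupling references unknown edge ids")
  r0 <- graph$edges$radius
  d_ef <- 2 * r0[ef_row]
  sigma_e <- interp_class_param(d_ef, sig, config$cap_diameter_max, config$large_diameter_min)
  rmax_e <- interp_class_param(d_ef, config$ratio_max, config$cap_diameter_max, config$large_diameter_min)

  n_t <- config$n_steps + 1L
  stim_steps <- sum(seq_len(config$n_steps) * config$dt <= config$stim_end + 1e-12)
  noise <- edge_noise_matrix(config$seed, ef_edges, stim_steps)

  radii <- matrix(0, n_t, graph$M)
  Qm <- matrix(0, n_t, graph$M)
  um <- matrix(0, n_t, graph$M)
  pm <- matrix(0, n_t, graph$N)
  balance <- numeric(n_t)
  time <- seq(0, by = config$dt, length.out = n_t)

  # symbolic factorization reused across steps (pattern is fixed)
  g0 <- edge_conductance(graph$edges$length, r0, config$hydraulic)
  L0 <- build_laplacian(graph, g0)
  keep <- setdiff(seq_len(graph$N), match(bc$exit_nodes, graph$nodes$id))
  chol0 <- if (config$backend == "direct") {
    Matrix::Cholesky(Matrix::forceSymmetric(L0[keep, keep, drop = FALSE]), LDL = FALSE)
  } else NULL

  y <- numeric(length(ef_edges))
  y_tau <- NULL
  r_cur <- r0
  for (i in seq_len(n_t)) {
    t_i <- time[i]
    if (i > 1L) {
      if (i - 1L <= stim_steps) {
        y <- rou_step(y, r0[ef_row], config$kappa, sigma_e, config$dt,
                      noise[i - 1L, ], rmax_e)
      } else {
        if (is.null(y_tau)) y_tau <- y
        y <- y_tau * exp(-config$kappa * (t_i - stim_steps * config$dt))
      }
      r_cur <- r0
      r_cur[ef_row] <- r0[ef_row] + y
    }
    fs <- solve_flow(graph, r_cur, bc, config$hydraulic,
                     backend = config$backend, t = t_i, factor = chol0)
    radii[i, ] <- r_cur
    Qm[i, ] <- fs$Q
    um[i, ] <- fs$u
    pm[i, ] <- fs$p
    balance[i] <- fs$balance
    if (verbose && (i %% 100L == 0L)) {
      message(sprintf("step %d/%d  t = %.2f s  balance = %.2e", i - 1L, config$n_steps, t_i, fs$balance))
    }
  }

  structure(list(time = time, radii = radii, Q = Qm, u = um, p = pm,
                 balance = balance, graph = graph, coupling = coupling,
                 bc = bc, config = config, sigma = sig,
                 seed = config$seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d time points x %d edges (%d nodes), dt = %g s, seed = %d\n",
              length(x$time), ncol(x$Q), ncol(x$p), x$config$dt, x$seed))
  cat(sprintf("  stimulation window [0, %g] s; max balance error %.2e\n",
              x$config$stim_end, max(x$balance)))
  invisible(x)
}
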