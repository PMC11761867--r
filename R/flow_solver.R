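#' Hydraulic parameters
#'
#' Parameters of the corrected Hagen-Poiseuille resistance law
#' `R(r) = 4 * RPois(r) * (1 - alpha * exp(-r/beta) + gamma * exp(-r/delta))`
#' with `RPois(r) = 8 * eta / r^2`.  Units: radii in um, viscosity in
#' g um^-1 s^-1, so resistances come out in g um^-3 s^-1 and flows in
#' um^3 s^-1.  The default correction coefficients `alpha = gamma = 0`
#' reduce the law to four times the classical Poiseuille friction.  Blood
#' density `rho` is carried for completeness; it cancels in the
#' quasi-static solve.
#'
#' @param eta plasma viscosity (default 1.2e-6 g um^-1 s^-1).
#' @param alpha,beta,gamma,delta correction coefficients (`beta`, `delta`
#'   in um; both must be positive when the matching amplitude is nonzero).
#' @param rho blood density, g um^-3.
#' @return a list of class `hydraulic_params`.
#' @export
hydraulic_params <- function(eta = 1.2e-6, alpha = 0, beta = 1, gamma = 0,
                             delta = 1, rho = 1.04e-12) {
  if (eta <= 0) stop("eta must be positive")
  if ((alpha != 0 && beta <= 0) || (gamma != 0 && delta <= 0)) {
    stop("beta and delta must be positive when alpha or gamma is nonzero")
  }
  structure(list(eta = eta, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, rho = rho),
            class = "hydraulic_params")
}

#' Classical Poiseuille friction coefficient
#'
#' `RPois(r) = 8 * eta / r^2`, equivalently `8 * eta * pi / A` with
#' `A = pi r^2`.
#'
#' @param r vessel radius, um (positive).
#' @param eta plasma viscosity, g um^-1 s^-1.
#' @return friction coefficient, g um^-3 s^-1.
#' @export
poiseuille_resistance <- function(r, eta = 1.2e-6) {
  if (any(r <= 0)) stop("radius must be positive")
  8 * eta / r^2
}

#' Corrected resistance law
#'
#' `R(r) = 4 * RPois(r) * (1 - alpha * exp(-r/beta) + gamma * exp(-r/delta))`.
#' Errors if the correction factor is non-positive for any radius
#' (unphysical coefficient choice).
#'
#' @param r vessel radius, um.
#' @param params a [hydraulic_params()] object.
#' @return friction coefficient, g um^-3 s^-1.
#' @export
corrected_resistance <- function(r, params = hydraulic_params()) {
  if (any(r <= 0)) stop("radius must be positive")
  fac <- 1 - params$alpha * exp(-r / params$beta) + params$gamma * exp(-r / params$delta)
  if (any(fac <= 0)) stop("correction factor non-positive for some radii (unphysical coefficients)")
  4 * poiseuille_resistance(r, params$eta) * fac
}

#' Edge hydraulic conductance
#'
#' `g = A / (R(r) * l)` with `A = pi r^2`, so the edge flow is
#' `Q = g * (p_a - p_b)`.  With `alpha = gamma = 0` this is the familiar
#' `pi r^4 / (32 eta l)`.
#'
#' @param l edge length, um.
#' @param r edge radius, um.
#' @param params a [hydraulic_params()] object.
#' @return conductance, um^3 s^-1 per unit pressure.
#' @export
edge_conductance <- function(l, r, params = hydraulic_params()) {
  if (any(l <= 0)) stop("length must be positive")
  pi * r^2 / (corrected_resistance(r, params) * l)
}

#' Boundary conditions for the network solve
#'
#' @param entry_nodes node ids where flux is imposed.
#' @param exit_nodes node ids grounded at reference pressure 0.
#' @param entry_edges edge ids of the (unique) edge incident to each entry
#'   node; their time-varying cross-section sets the imposed inflow.
#' @param entry_velocity imposed blood velocity at the entries, um s^-1.
#' @param amplitude relative amplitude of an optional sinusoidal inflow
#'   modulation (hook; default 0 means constant-velocity inflow).
#' @param period modulation period, s.
#' @return a list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(entry_nodes, exit_nodes, entry_edges,
                                entry_velocity = 3.5e4, amplitude = 0,
                                period = 1) {
  if (!length(entry_nodes) || !length(exit_nodes)) stop("entry and exit sets must be nonempty")
  if (length(intersect(entry_nodes, exit_nodes))) stop("entry and exit sets must be disjoint")
  if (length(entry_edges) != length(entry_nodes)) stop("one entry edge per entry node required")
  structure(list(entry_nodes = entry_nodes, exit_nodes = exit_nodes,
                 entry_edges = entry_edges, entry_velocity = entry_velocity,
                 amplitude = amplitude, period = period),
            class = "boundary_conditions")
}

#' Select entry and exit nodes
#'
#' Blood enters through `k_entries` boundary (degree-1) nodes chosen by
#' decreasing radius, ties broken toward the cortical surface (smaller
#' depth); every remaining degree-1 node is an exit grounded at pressure 0.
#'
#' @param graph a `vascular_graph`.
#' @param k_entries number of entry nodes (default 3).
#' @param entry_velocity,amplitude,period passed to [boundary_conditions()].
#' @return a `boundary_conditions` object.
#' @export
select_boundary_nodes <- function(graph, k_entries = 3L, entry_velocity = 3.5e4,
                                  amplitude = 0, period = 1) {
  deg <- node_degree(graph)
  b_idx <- which(deg == 1L)
  if (length(b_idx) < k_entries + 1L) {
    stop(sprintf("need at least %d degree-1 nodes, found %d", k_entries + 1L, length(b_idx)))
  }
  depth <- node_depth(graph)
  ord <- b_idx[order(-graph$nodes$radius[b_idx], depth[b_idx])]
  entry_idx <- ord[seq_len(k_entries)]
  exit_idx <- setdiff(b_idx, entry_idx)
  # the unique incident edge of each entry node
  entry_edge <- vapply(entry_idx, function(i) {
    graph$edges$id[which(graph$edges$ia == i | graph$edges$ib == i)[1L]]
  }, numeric(1))
  boundary_conditions(entry_nodes = graph$nodes$id[entry_idx],
                      exit_nodes = graph$nodes$id[exit_idx],
                      entry_edges = entry_edge,
                      entry_velocity = entry_velocity,
                      amplitude = amplitude, period = period)
}

#' Boundary inflow at time t
#'
#' `Qb(t) = u_in * A_entry(t)` per entry node, with `A_entry = pi r(t)^2`
#' the cross-section of the entry edge; when that edge carries an endfoot
#' the inflow inherits its stochastic dilation.  A nonzero `amplitude`
#' multiplies the inflow by `1 + amplitude * sin(2 pi t / period)`.
#'
#' @param t time, s.
#' @param bc a `boundary_conditions` object.
#' @param graph the `vascular_graph`.
#' @param radii current edge radii, um (vector over edge rows); defaults to
#'   resting radii.
#' @return numeric vector of inflows, um^3 s^-1, one per entry node.
#' @export
boundary_inflow <- function(t, bc, graph, radii = graph$edges$radius) {
  row <- match(bc$entry_edges, graph$edges$id)
  if (anyNA(row)) stop("unknown entry edge id")
  q <- bc$entry_velocity * pi * radii[row]^2
  if (bc$amplitude != 0) q <- q * (1 + bc$amplitude * sin(2 * pi * t / bc$period))
  q
}

# conductance-weighted graph Laplacian (sparse, symmetric)
build_laplacian <- function(graph, g) {
  ia <- graph$edges$ia; ib <- graph$edges$ib
  Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib),
    j = c(ia, ib, ib, ia),
    x = c(g, g, -g, -g),
    dims = c(graph$N, graph$N)
  )
}

#' Solve the quasi-static flow problem
#'
#' Assembles the conductance-weighted graph Laplacian, imposes the entry
#' fluxes `Qb` and grounds all exit nodes at pressure 0, and solves the
#' reduced symmetric positive-definite system for the remaining node
#' pressures.  Edge flows are `Q = g * (p_a - p_b)` (signed along the
#' stored edge orientation) and velocities `u = Q / (pi r^2)`.
#'
#' @param graph a connected `vascular_graph`.
#' @param radii current edge radii, um; defaults to resting radii.
#' @param bc a `boundary_conditions` object.
#' @param params a [hydraulic_params()] object.
#' @param backend `"direct"` (sparse Cholesky) or `"iterative"`
#'   (Jacobi-preconditioned conjugate gradient).
#' @param t time, s, passed to [boundary_inflow()].
#' @param factor optional cached `Matrix::Cholesky` factor of the reduced
#'   Laplacian (same sparsity pattern); updated in place for repeated
#'   solves along a trajectory.
#' @param tol relative residual tolerance of the iterative backend.
#' @return a `flow_state`: list with node pressures `p` (g um^-1 s^-2),
#'   edge flows `Q` (um^3 s^-1), velocities `u` (um s^-1), the imposed
#'   `inflow`, the recovered `outflow`, and the relative `balance` error.
#' @export
solve_flow <- function(graph, radii = graph$edges$radius, bc,
                       params = hydraulic_params(),
                       backend = c("direct", "iterative"),
                       t = 0, factor = NULL, tol = 1e-10) {
  backend <- match.arg(backend)
  if (graph$M == 0L) stop("graph has no edges")
  g <- edge_conductance(graph$edges$length, radii, params)
  L <- build_laplacian(graph, g)

  exit_idx <- match(bc$exit_nodes, graph$nodes$id)
  entry_idx <- match(bc$entry_nodes, graph$nodes$id)
  if (anyNA(exit_idx) || anyNA(entry_idx)) stop("boundary node ids not present in graph")
  keep <- setdiff(seq_len(graph$N), exit_idx)
  if (!length(keep)) stop("no free nodes after grounding exits")

  qb <- boundary_inflow(t, bc, graph, radii)
  b <- numeric(graph$N)
  b[entry_idx] <- qb
  Lkk <- Matrix::forceSymmetric(L[keep, keep, drop = FALSE])
  bk <- b[keep]

  p <- numeric(graph$N)
  if (backend == "direct") {
    ch <- if (is.null(factor)) Matrix::Cholesky(Lkk, LDL = FALSE)
          else Matrix::.updateCHMfactor(factor, Lkk, mult = 0)
    pk <- as.numeric(Matrix::solve(ch, bk))
  } else {
    pk <- pcg_solve(Lkk, bk, tol = tol)
  }
  p[keep] <- pk

  Q <- g * (p[graph$edges$ia] - p[graph$edges$ib])
  u <- Q / (pi * radii^2)

  # exit flows read off as residual fluxes at the grounded nodes
  net <- as.numeric(L %*% p)   # equals imposed flux at entries, -outflow at exits
  outflow <- -sum(net[exit_idx])
  inflow <- sum(qb)
  structure(list(p = p, Q = Q, u = u, inflow = inflow, outflow = outflow,
                 exit_flows = -net[exit_idx],
                 balance = abs(inflow - outflow) / max(abs(inflow), .Machine$double.eps),
                 conductance = g),
            class = "flow_state")
}

# Jacobi-preconditioned conjugate gradient for the SPD reduced Laplacian
pcg_solve <- function(A, b, tol = 1e-10, maxit = 20L * length(b)) {
  n <- length(b)
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- dinv * r
  pv <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% pv)
    alpha <- rz / sum(pv * Ap)
    x <- x + alpha * pv
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    pv <- z + (rz_new / rz) * pv
    rz <- rz_new
  }
  stop(sprintf("conjugate gradient did not converge in %d iterations (relative residual %.3e)",
               maxit, sqrt(sum(r * r)) / bnorm))
}

#' Interior-node mass-conservation residual
#'
#' Maximum absolute net signed flow over all non-boundary nodes, a direct
#' check of Kirchhoff's law on the solved network.
#'
#' @param graph a `vascular_graph`.
#' @param flow a `flow_state`.
#' @param bc the `boundary_conditions` used for the solve.
#' @return max interior net flux, um^3 s^-1.
#' @export
conservation_residual <- function(graph, flow, bc) {
  net <- numeric(graph$N)
  net <- net + tabulate_signed(graph$edges$ia, -flow$Q, graph$N) +
               tabulate_signed(graph$edges$ib, flow$Q, graph$N)
  bd <- match(c(bc$entry_nodes, bc$exit_nodes), graph$nodes$id)
  interior <- setdiff(seq_len(graph$N), bd)
  if (!length(interior)) return(0)
  max(abs(net[interior]))
}

tabulate_signed <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
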