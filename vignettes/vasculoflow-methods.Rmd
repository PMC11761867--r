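---
title: "Methods: quasi-static network hemodynamics with stochastic astrocytic vasodilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-static network hemodynamics with stochastic astrocytic vasodilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculoflow)
```

## The model

`vasculoflow` simulates blood flow in a cortical microvascular network
represented as a graph: nodes carry a 3D position (µm) and a radius, and
each edge is a straight cylindrical pipe between two branch points, with a
length (Euclidean by default, or the true tortuous length if supplied) and
a radius equal to the arithmetic mean of its endpoint radii.

**Hydraulics.** Blood is treated as an incompressible Newtonian fluid of
constant plasma viscosity η = 1.2×10⁻⁶ g µm⁻¹ s⁻¹. Each pipe obeys a
corrected Hagen–Poiseuille friction law

R(r) = 4 · R_Pois(r) · (1 − α e^(−r/β) + γ e^(−r/δ)),   R_Pois(r) = 8η/r²,

so the edge conductance is g = πr² / (R(r)·l); with the default
α = γ = 0 this is the familiar g = πr⁴/(32ηl). The correction
coefficients are configuration-exposed (`hydraulic_params()`); the package
default is the pure 4×Poiseuille law, stated rather than guessed, because
no canonical coefficient set ships with the package.

**Quasi-static solve.** Radii change on a timescale of seconds while the
flow field equilibrates in milliseconds, so the inertial and advective
terms of the 1D momentum balance are dropped and each time step solves the
steady resistive network: Kirchhoff balance at every interior node gives a
conductance-weighted graph Laplacian system L·p = b. Entry nodes impose a
flux Q_b = u_in · πr²_entry (default u_in = 3.5×10⁴ µm/s), all exit nodes
are grounded at reference pressure 0 (which makes the solution unique and
conserves mass by construction), and edge flows follow as
Q = g·(p_a − p_b), velocities as u = Q/(πr²). The reduced system is
symmetric positive definite; the `direct` backend uses a sparse Cholesky
factorization whose symbolic analysis is computed once per simulation and
numerically refreshed each step, and the `iterative` backend is a
Jacobi-preconditioned conjugate gradient (tolerance 10⁻¹⁰) intended for
networks too large to factor. Entry nodes are the k (default 3) degree-1
nodes with the largest radii, ties broken toward the cortical surface;
every other degree-1 node is an exit. Flow signs follow the stored edge
orientation; all metrics use |Q|.

**Endfoot-driven dilation.** Astrocytic endfeet dilate the vessel segments
they contact. The deviation y = r − r₀ of an endfoot-bearing edge above
its resting radius follows a reflected Ornstein–Uhlenbeck process,
discretized by Euler–Maruyama at dt = 0.01 s:

y ← | y − κ·y·dt + σ·r₀·√dt·ξ |,  then  y ← min(y, r₀·(ratio_max − 1)).

Reflection at zero encodes dilation-only dynamics (the radius never drops
below rest); the hard cap encodes the literature ceiling on dilation,
ratio_max = 1.38 for capillaries and 1.23 for large vessels. Noise is
scaled by r₀ so σ is dimensionless and comparable across vessel classes.
One process drives each endfoot-bearing *edge*; multiple endfeet on one
edge share it. Vessels of intermediate diameter (6–14 µm) that carry
endfeet use linearly interpolated (ratio_max, t_peak, σ) between the
capillary and large-vessel values, since dilation data anchor only the two
extreme classes.

**Calibration.** The literature constrains the peak dilation (ratio_max)
and the mean time to reach it (t_peak: 2.7 s capillaries, 3.3 s large
vessels), but not σ directly. `calibrate_rou()` bisects on σ until the
median over 1000 simulated stimulation paths of the running-maximum radius
ratio at t_peak equals ratio_max, using common random numbers so the
objective is monotone and the result deterministic. Calibration runs
*without* the cap: with the cap active the median running maximum
saturates exactly at ratio_max and the bisection target would sit on a
plateau; in simulation the cap then clips the excursions. The
mean-reversion rate defaults to κ = 1 s⁻¹, so the relaxation time constant
1/κ is one second.

**Passive phase.** A standard run spans 5 s in 500 steps: stochastic
stimulation during [0, 3] s, then noise-free relaxation. After stimulation
ceases at τ the package uses the closed-form decay
r(t) = r₀ + e^(−κ(t−τ))·(r_τ − r₀) rather than σ = 0 Euler steps — it is
exact, and the same law applied to mean radii gives the network-average
relaxation.

**Stochastic inflow.** The entry inflow is velocity times the entry edge's
instantaneous cross-section. In the reference anatomy all entry vessels
are endfoot-contacted, so their dilation makes the inflow itself
stochastic during stimulation; `place_endfeet(ensure_edges = ...)`
reproduces this condition. It is the dominant mechanism by which mean
network flow rises during stimulation — without it, interior dilation only
redistributes a fixed total inflow and the mean capillary flow increase is
weak.

## Analysis metrics

*Resting-state ratio*: RS(i,k) = value(i,k)/value(0,k), computed on |Q|
for flow and on r for radius; RS(0,k) = 1 by construction. Edges whose
baseline flow is numerically zero (below 10⁻¹² of the network maximum) are
excluded with a logged count — dividing by them is meaningless, and
pendant loops in any network carry exactly zero steady flow.

*Average ratio*: the arithmetic mean of RS over an edge subset per time
point, then over time points.

*Distance order*: the minimum number of edges traversed between two edges,
i.e. shortest-path distance in the line graph (edges sharing a node are at
order 1).

*Order ratio*: how dilation on endfoot edges perturbs flow m hops away.
Two variants share the same strict nesting (innermost over the order-m
shell K_m(k), then over endfoot edges k, then over time — never pooled,
because shells have unequal sizes):

* `on = "ratio"` averages RS(i,k̃)/RS(i,k); it equals 1 identically on a
  dilation-free run, which makes it the variant used for invariant
  checking. When the inflow itself is stochastic this curve saturates at
  the global fluctuation level rather than decaying.
* `on = "variation"` averages v(k̃)/v(k) with v(k) the time-mean |RS−1|.
  This is the locality profile proper: it decays with order and is the
  curve summarized by the exponential fit f(m) = a·e^(−bm) + c
  (`fit_order_decay()`, nonlinear least squares with a, b ≥ 0, started at
  (OR(1)−OR(m_max), 0.1, OR(m_max))). It is undefined without dilation.
  Locality is only identifiable under constant inflow: with dilating
  entries, every edge inherits the global fluctuation and the profile
  flattens. The conventional cutoffs — neighborhood order 20 and a 0.1
  negligibility threshold — apply to this profile.

*Neighbor-endfeet classes*: each edge is classified by the number of
endfeet attached to edges within order 20, counting the edge's own endfeet
at order 0; the summary reports the class histogram, the mean
time-averaged flow ratio per class, and per-layer-group class percentages.

*Group summaries*: mean |Q| time series per cortical layer × vessel class,
per-layer percentage shares of the time-averaged flow ratio (summing to
100% per layer), per-layer quantiles, depth profiles in 25 µm bins, and
planar heatmap grids (default 17 × 21 µm cells).

Vessel classes are defined by diameter: capillaries 4–6 µm, large vessels
≥ 14 µm, the remainder "other". Flow-share accounting conventionally
counts everything below 6 µm as capillary; both conventions are exposed
(`cap_range`).

## The synthetic network generator

Real cortical microvasculature datasets at the million-edge scale are not
redistributable with a package, so `generate_vasculature()` builds layered
networks with the features the simulator exercises: a handful of large
penetrating vessels descending from the cortical surface (root radii from
a truncated normal, mean 10, sd 3, floor 7 µm, tapering with depth) with
short tapering connector branches; a capillary mesh (radii truncated
normal, mean 2.5, sd 0.5, floor 0.5 µm) whose node density increases
linearly with depth, wired by 2-nearest-neighbor proximity to a mean
degree near 3; dangling deep "venous" stubs that guarantee degree-1 exit
nodes; and bridging edges that make the network a single component. The
default bounding box is 954 × 1453 × 853 µm with depth along the second
axis. Endfeet are placed with probability proportional to the edge's
lateral surface 2πr·l times a class weight (capillary 1, other 0.6, large
0.3), reflecting reported capillary-biased coverage; the default endfoot
count preserves the reference density of ≈ 0.021 endfeet per edge.

What the generator reproduces: the depth segregation of vessel classes
(capillary length dominating the deep half, large-vessel length the upper
half), realistic radius-class mixtures across the 6/14 µm thresholds,
surface-weighted endfoot coverage, and boundary nodes suitable for the
entry/exit protocol. What it does not claim: anatomically exact branching
statistics, measured per-layer volume fractions, or the measured
endfeet-per-depth profile. Passing tests on these networks therefore
demonstrate correctness of the solver, dynamics and metrics under
realistic topology and scale — not quantitative agreement with any
specific anatomical dataset, whose headline numbers (per-layer flow
shares, flow-by-diameter tables) are dataset properties.

## Numerical choices and degenerate inputs

* Multi-edges and self-loops are rejected at load: the pipe model and the
  Laplacian assembly assume simple edges (a parallel vessel pair is
  represented by splitting one limb with a node, as the toy fixtures do).
* Layer intervals are half-open [upper, lower): a node exactly on a
  boundary belongs to the deeper layer; out-of-range nodes get sentinel
  labels with a warning.
* Largest-component ties break toward the component containing the
  smallest node id.
* Solver tolerances: iterative relative residual 10⁻¹⁰; mass-conservation
  diagnostics are recorded every step (interior net flux and global
  inflow−outflow balance, both ≲ 10⁻¹³ relative in practice).
* Determinism: every stochastic component derives from one master seed.
  Per-edge noise streams are seeded by (master·1000003 + edge_id) mod
  (2³¹−1), so adding or removing unrelated edges does not reshuffle a
  given edge's path; identical seeds reproduce results bit-identically,
  and the on-disk container (CSV tables written at 17 significant digits
  plus JSON metadata) round-trips arrays exactly.
* The exponential locality fit refuses fewer than 4 orders and returns the
  degenerate (0, 0, mean) fit for a numerically constant curve. At the
  realistic noise level, the offset c is near the per-point noise floor
  and is the least identifiable of the three parameters (a and c are
  nearly collinear when b·m_max is small).
* Single-host locality replicates are heavy-tailed (a shell can hit an
  edge whose own baseline variation is atypically small), so seed-wise
  medians, not means, summarize locality curves.

## Problem sizes

The package's standard analyses run at desk scale: default synthetic
networks of ≈ 5,000 edges (≈ 3,800 nodes) with 500-step trajectories
(seconds per run with the cached factorization), calibration with 1,000
Monte-Carlo paths, locality experiments on ≈ 1,100-edge networks with 10
single-host replicates, and property checks on fixtures and ≤ 300-edge
networks where brute-force oracles (closed-form pipe laws, Floyd–Warshall
line-graph distances, half-normal stationary moments) are exact.

## Known limitations

Blood is Newtonian here: no hematocrit dependence, no biphasic
red-blood-cell rheology, no shear-dependent viscosity. Only vasodilation is
modelled — vasoconstriction, pericyte contractility and endothelial
signalling are out of scope. The inflow modulation hook (`amplitude`,
sinusoidal) is a placeholder for richer time-dependent entry protocols.
The solver is single-process; the iterative backend is the intended hook
for scales beyond direct factorization.
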