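Package: vasculoflow
Title: Quasi-Static Blood Flow on Cortical Microvascular Networks with
    Stochastic Astrocytic Vasodilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cerebral blood flow on a microvascular graph in the
    quasi-static Hagen-Poiseuille regime.  Node pressures are obtained at
    each time step from a conductance-weighted graph Laplacian system with
    imposed entry fluxes and grounded exit nodes; astrocytic endfeet dilate
    the radii of the vessel segments they contact via a reflected
    Ornstein-Uhlenbeck process calibrated to literature dilation amplitudes
    and times-to-peak, followed by noise-free exponential relaxation.
    Includes a layered synthetic-vasculature generator with endfoot
    placement, exactly solvable hydraulic fixtures, and analysis metrics
    (resting-state ratios, averaged ratios, distance-order ratios with
    exponential locality fits, neighbor-endfeet classification, and
    layer/vessel-class summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
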