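Package: nucleopack
Title: Multiscale Structural and Dynamic Analysis of Chromatin Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing nucleosome packing in chromatin condensates
    across scales: per-fiber geometric descriptors (inter-nucleosome distances,
    plane and signed dihedral angles, radius of gyration) from rigid-body
    nucleosome pose tables; condensate-scale pairwise statistics (radial
    distribution functions against random-bath references, nearest-neighbour
    orientation distributions, face/side packing-geometry classification and
    intra- versus inter-array contact censuses); array-level interaction
    graphs with normalized algebraic connectivity and digestion-style
    percolation curves; residue-level histone-tail contact profiling on
    coarse-grained frames; voxelized occupancy, pore-size (local thickness)
    and number-density estimation with genomic-content conversions; passive
    optical-trap microrheology (mean-squared displacement, trap stiffness,
    complex modulus via the generalized Stokes-Einstein relation, zero-shear
    viscosity and modulus crossovers) and stress-relaxation moduli; and
    single-particle-tracking statistics (diffusion coefficients, jump angles,
    asymmetry coefficients). A synthetic-data module generates fibers,
    condensates, random orientation baths, coarse-grained frames and
    trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    yaml,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
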