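---
title: "Multiscale analysis of nucleosome packing in chromatin condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of nucleosome packing in chromatin condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleopack)
```

# Scope and model

Chromatin in the nucleus, and reconstituted nucleosome-array condensates in
vitro, are dense liquids of nucleosomes whose material behaviour is set by
how the nucleosomes pack and interact.  `nucleopack` analyses this system at
four scales:

1. **Fiber geometry** — per-array descriptors from rigid-body nucleosome
   poses: the center distance `D` and folded plane angle `para` of
   semi-adjacent (N, N+2) nucleosomes, the signed full-circle dihedral
   `alpha` of adjacent (N, N+1) nucleosomes, and the radius of gyration.
2. **Condensate packing** — radial distribution functions against a
   random-bath reference, nearest-neighbour orientation distributions
   against the isotropic (sinusoidal) reference, face/side packing-geometry
   classification, and intra- versus inter-array contact censuses.
3. **Interaction networks and voids** — array-level graphs, normalized
   algebraic connectivity, digestion-style percolation, voxelized occupancy,
   pore sizes (local thickness), number density and genomic content.
4. **Dynamics** — trap-based passive microrheology (complex modulus via the
   generalized Stokes–Einstein relation), stress-relaxation moduli from
   simulation stress series, and single-molecule tracking statistics
   (diffusion coefficients, jump angles, asymmetry coefficients).

Everywhere a physical extent is needed the nucleosome is a rigid cylinder of
radius 5.5 nm and height 6.0 nm (canonical core-particle dimensions), with
the disc normal along the superhelical axis and the dyad in the disc plane.
Coordinates are nanometers throughout, except residue-resolution
coarse-grained frames, which are Angstrom.

# Fiber descriptors and their conventions

A pose is a center plus an orthonormal right-handed frame (normal = local
+z, dyad = local +x).  Three conventions are deliberate and worth stating:

* **`para` is folded to [0, 90 degrees]** (the plane angle
  `acos(|n1 . n2|)`).  All reported experimental values of this quantity
  fall in that range, and the folded form is invariant to the arbitrary sign
  of a fitted disc normal.  The signed alternative would inherit that sign
  ambiguity from upstream template matching.
* **`alpha` is a signed, full-circle dihedral** about the N-to-N+1 center
  axis (right-hand rule, fiber order).  Values near 230 degrees versus 50
  degrees distinguish linker-length phasing that a folded angle would
  collapse; reversing the fiber order maps `alpha` to `360 - alpha`, which
  is documented rather than hidden.  Step tables summarize `alpha`
  circularly (circular mean and SD); the other columns are summarized
  arithmetically.
* **Radius of gyration uses nucleosome centers, unweighted.**  Pose tables
  carry no mass information, and for rigid identical particles the
  center-of-mass trace is the natural object.

A disc normal parallel to the step axis makes the dihedral undefined; the
package raises an error (degenerate geometry) rather than returning an
arbitrary value.

# Idealized fiber builders

`build_ideal_fiber()` provides two constructions with exact round trips.

**Zigzag** (open fibers, 25-bp-like): the fiber grows step by step.  Each
step advances `d_adj` along a direction in the current disc frame and
rotates the whole frame by exactly `alpha` about the step axis — a rotation
about the step axis changes the projected dihedral by exactly that angle, so
the measured `alpha` reproduces the configured one identically.  The
remaining freedom, the step's polar angle, is solved per step (root finding)
so that the N to N+2 plane angle equals the configured `para`.  When several
roots exist the builder prefers, in order of continuity with the previous
step, a root whose new disc does not interpenetrate earlier discs.

**Two-start** (30-bp-like): stacked fibers are built as short segments of
two coaxial, criss-crossing face-to-face stacks.  The segment length
defaults to 4 nucleosomes because stacked runs of ~4-6 nucleosomes are what
dense two-start chromatin actually shows; a single long double stack is also
geometrically impossible if one demands simultaneously (i) stacking rise
equal to the disc height, (ii) nonzero adjacent dihedral on every step, and
(iii) no disc interpenetration — with rise = height, any tilt of one stack
against the other wedges the sharp-edged cylinders into each other.  Within
a segment the N:N+2 center distance equals the rise exactly and the N:N+2
plane angle is 0 (face-to-face).  The crossing angle between the two stacks
is calibrated by one-dimensional root finding so that the *measured*
circular-mean `alpha` of the finished fiber (junction steps included) equals
the configured value to 1e-6; the calibration is deterministic and cached.

Builders check all disc pairs and fail on interpenetration deeper than 1 nm,
naming the first offending pair.  Generator (noisy) builds relax this
tolerance to 3.5 nm: orientation noise on touching stacked discs wedges the
sharp-edged cylinder model even though rounded real nucleosomes would
simply tilt in place.  This is an artifact of the disc idealization, not a
physical statement.

# The synthetic condensate and what it does and does not emulate

`gen_condensate()` sizes a cubic box from the target number density (the
default, 6e5 nucleosomes per cubic micrometer, is the density scale of dense
nuclear chromatin foci), places randomly oriented fibers on a near-cubic
lattice whose few excess slots are dropped at random, and resolves
inter-fiber overlaps by rigid push-apart sweeps (a C++ cell-list pass;
conflict-free fibers drift gently back toward their home slots so the
packing stays homogeneous).  Fibers may overhang the box walls the way a
region sampled from bulk would; only slot centroids are confined.  The
relaxation stops when no inter-fiber nucleosome pair is closer than 6 nm or
after `max_sweeps` sweeps, and aborts with the achieved density if deep
overlaps persist.

What this reproduces: the target density, rigid intra-fiber geometry (so
stacking signatures such as the 6-nm g(r) peak are exact), array
assignments, and a well-defined mask.  What it does not: thermal
conformational ensembles, tail-mediated energetics, attractive ordering
between fibers (neighbouring stacks do not align beyond what packing
forces), or liquid-liquid interface structure.  Passing round-trip tests on
these synthetics therefore validates the *estimators*, not any claim about
real chromatin.

# Pairwise statistics

The radial distribution function normalizes the pair-distance histogram by
the mean histogram of random uniform placements of the same number of
centers inside the same mask (Monte-Carlo edge correction; masks are
irregular in general, so no analytic box correction is assumed).  Bins are
`[0, b), [b, 2b), ...` and reported at midpoints; a stacking rise sitting
exactly on a bin edge is therefore reported at the adjacent midpoint, within
half a bin of the true value.

Nearest-neighbour orientation histograms come with the isotropic reference
density proportional to sin(theta) on [0, 90 degrees], normalized to the
observed pair count; for isotropic orientations the mean plane angle is
1 radian (57.30 degrees), a useful anchor.

Packing classes use the exact distance between solid cylinders (alternating
convex projections, in C++).  A pair is "in contact" when the surface
separation is at most 2.0 nm — chosen to include tail-bridged contacts,
since histone tails extend roughly 2-3 nm — and each disc contributes a
facet: "face" if its closest point lies on a flat cap within 90% of the cap
radius, else "side".  The 0.9 cap fraction avoids rim ambiguity; both knobs
are arguments, and the contact gate is recorded in outputs.  Overlapping
pairs (possible in noisy synthetics and experimental pose tables) are
flagged and classified by the facets of deepest overlap, estimated by
shrinking both cylinders to first separation.

The census excludes covalently adjacent intra-array pairs (|i - j| = 1)
when fiber order is known: those are trivially proximal and carry no
packing information.

# Interaction networks

Arrays become nodes; an edge exists when at least one inter-array nucleosome
contact does, weighted by contact count and by a summed class energy with
defaults 3 : 2 : 1 for face-to-face : face-to-side : side-to-side,
reflecting their energetic ordering.  Connectivity is the second-smallest
eigenvalue of the unweighted Laplacian, normalized by that of a
deterministic circulant k-regular graph on the same node count, k being the
maximum observed degree ("all nodes connected with the highest node
degree"); the circulant realization is chosen because it is deterministic,
degree-exact and reproducible.  For odd k on an odd node count no k-regular
graph exists; the reference is then near-regular and a warning is issued.
The digestion model deletes each nucleosome-level contact independently with
probability p and rebuilds the array graph from survivors — the simplest
faithful reading of "reducing the number of potential interactions" — and
reports the largest-component fraction over replicates.

# Histone-tail contact profiles

Coarse-grained frames are one-bead-per-residue/nucleotide tables.  Two beads
are in contact below a 7.0 Angstrom cutoff (about 1.2 bead spacings for such
models; configurable and recorded in output), excluding pairs on the same
chain within two residues (bonded exclusion).  Scopes partition exactly:
intra-nucleosome, intra-array (same array, different nucleosome), and
inter-array.  A residue's count is the number of contact pairs it
participates in, so a residue touching three partners counts three.  SDs
across frames use the population convention (divide by n), since the frames
are the entire analyzed set, not a sample from a larger one.  The cell-list
search is required to reproduce the quadratic scan exactly and is tested
against it.

The frame generator builds rigid nucleosome templates (DNA beads on a
superhelical path, core beads on an inner cylinder) and grows tails as
anchored, biased self-avoiding walks with a 3.8 Angstrom step.  Biasing the
H4 walks toward the partner face reproduces the stacking-bridge motif;
biasing tails toward their own DNA reproduces the low-salt regime in which
tails make almost exclusively intra-nucleosome contacts.  Ground-truth
totals are recorded by an independent quadratic scan at generation time.

# Occupancy, pores, density and genomic content

Occupancy grids rasterize the disc model (default 1-nm voxels, a compromise
between the 14-25 nm pore scales of interest and memory).  The condensate
mask is the morphological closing of the occupancy with a 12-nm-radius ball,
computed by two Euclidean distance transforms; closing with that radius
subsumes internal voids up to roughly 24 nm in diameter — the scale of
pores observed in chromatin condensates — while following the outer
surface.  "Pore size" is local thickness: for each void voxel, the diameter
of the largest inscribed ball containing it, computed from the distance
transform by ball covering with exact pruning of dominated balls.  Number
density is mask-and-count.  When a thinning series is analyzed (an
acetylation-like time course emulated by pose deletion), the mask of the
untreated condensate should be reused (`occupancy_grid(..., bounds = )`),
otherwise voids that grow beyond the closing scale silently leave the mask.

Genomic conversions are closed-form: bp density = number density times the
nucleosome repeat length (default 192 bp); a spherical focus of diameter d
holds density x (pi/6) d^3 nucleosomes.  The genome size default is the
human haploid 3.1e9 bp.

# Trapped-bead microrheology

From a trapped-bead record the per-axis mean-squared displacement (FFT
time-averaged estimator, tested against the double loop) is normalized to
`Pi(tau) = kappa MSD / (2 kB T)`, which rises from 0 to 1 in a trap.  Its
one-sided Fourier transform is evaluated exactly for the piecewise-linear
interpolant with a constant plateau beyond the last lag, and the
trap-corrected generalized Stokes-Einstein relation gives

G*(omega) = kappa / (6 pi a) * (1 / (i omega Pi_hat(omega)) - 1).

For an exponential `Pi` (Newtonian medium) this inversion is exact, which is
the estimator's closed-form anchor.  Two numerical choices matter:

* **Smoothing before transforming.**  Estimator noise makes the
  piecewise-linear interpolant kinked, and the kinks' transform decays like
  the signal itself at high frequency, so 1% MSD noise becomes ~20% modulus
  error.  A stiff smoothing spline in log-log coordinates (df = 12 over
  roughly three decades of lag; `spline_df` argument, `NULL` disables)
  removes the kinks while preserving the slowly varying physical curve.
* **Ensemble averaging.**  `complex_modulus()` accepts a list of independent
  bead recordings and averages their raw moduli before trimming, as
  experimental moduli are averaged over beads.

Frequencies are reported one decade inside the record-length and Nyquist
limits; grid points with negative moduli are trimmed, never silently
clipped into the output.  Trap stiffness defaults to equipartition
calibration (kB T / Var(x)) with a linear-drift guard that asks for
detrending rather than quietly absorbing drift.  Temperature defaults to
298 K; the bead radius has no default on purpose.  Zero-shear viscosity is
fitted as the slope of G'' against angular frequency over the lowest
reliable decade where viscous response dominates (G'' > 3 G'); when no such
region exists the value is flagged as a lower bound.  Crossover frequencies
are sign changes of log G' - log G'', interpolated in log-log.

The stress-relaxation module is independent of the trap route:
G(t) = (V / kB T) <sigma_ab(t0) sigma_ab(t0 + t)>, averaged over supplied
off-diagonal components and time origins, truncated so at least 10 origins
contribute at the largest lag.

The trapped-bead generator integrates overdamped Langevin dynamics with
fluctuation-dissipation-balanced noise: Newtonian and Kelvin-Voigt media
reduce to an exactly discretized Ornstein-Uhlenbeck process (the medium
spring simply adds to the trap), and the Maxwell medium uses an
auxiliary-variable spring-dashpot scheme with substeps plus a small solvent
viscosity (1% of the Maxwell viscosity) for well-posedness.

# Single-molecule tracking

Diffusion coefficients come from the ensemble-averaged time-averaged MSD
fitted over lags 1..3 by default — few points minimize confinement bias —
with the intercept absorbing localization error (4 sigma^2 in 2-D) and a
bootstrap over tracks for the confidence interval.  Tracks are split at
frame gaps.  Jump angles are the angles between consecutive displacements
(0 = directed, 180 = back-and-forth); the asymmetry coefficient is
log2(f_fwd / f_bwd) with 30-degree windows at each end, following the
single-nucleosome-tracking convention; the windows are arguments because
conventions differ between studies.  A naive nearest-neighbour linker is
included as convenience plumbing for localization tables and is documented
as non-validated: it is only trustworthy for sparse, well-separated
emitters.

# Numerical choices, sizes and limitations

Test and validation sizes were chosen to exercise every estimator at
desk scale: condensates of 200 twelve-nucleosome fibers (2,400 poses) for
packing statistics, 500-nm boxes (75,000 poses) for density round trips,
three 200,000-sample bead recordings per rheology oracle, and 2,000 tracks
of 20 steps for tracking statistics.  Cell-list searches, distance
transforms and the push-apart relaxation are C++; everything else is plain
R on top of igraph, bio3d and base stats.

Known limitations: the disc model has sharp edges (contact classes near the
rim boundary are sensitive to the 0.9 cap fraction); the condensate
generator produces packings, not thermal ensembles, so census and
connectivity numbers from it characterize the generator, not chromatin
thermodynamics; the Maxwell bead scheme is first-order in its substep; the
STAR reader covers RELION-style particle blocks only; and mask-and-count
density on a finite synthetic region carries a few-percent surface bias
that shrinks with box size.
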