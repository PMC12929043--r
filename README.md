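# nucleopack

Multiscale structural and dynamic analysis of chromatin condensates.

Dense phases of nucleosome arrays — reconstituted condensates in vitro and
chromatin foci in nuclei — are liquids whose material behaviour is set by
how individual nucleosomes pack, stack and bridge between arrays.
`nucleopack` turns the raw observables of such systems (rigid-body
nucleosome pose tables from subtomogram analysis, residue-resolution
coarse-grained frames, trapped-bead and single-molecule trajectories) into
quantitative descriptors at every scale:

* **Fiber geometry** — for nucleosomes N, N+1, N+2 along an array: the
  semi-adjacent center distance *D* and folded plane angle *para*
  (0–90°), the signed full-circle adjacent-plane dihedral *α* about the
  N→N+1 axis, and the radius of gyration
  *R<sub>g</sub>* = √(mean |c<sub>i</sub> − c̄|²) over nucleosome centers.
* **Condensate packing** — radial distribution function
  *g(r)* = *H*<sub>data</sub>(*r*) / ⟨*H*<sub>random</sub>(*r*)⟩ with a
  Monte-Carlo in-mask random reference; nearest-neighbour disc-plane-angle
  distributions against the isotropic sin θ reference; face-to-face /
  face-to-side / side-to-side contact classification on a 5.5 × 6.0 nm
  disc model with a 2 nm surface gate; intra- vs inter-array contact
  censuses.
* **Networks and voids** — array-level interaction graphs, normalized
  algebraic connectivity λ₂/λ₂(k-regular reference) on a 0–1 scale,
  digestion-style percolation curves, voxelized occupancy with
  morphological-closing masks, pore sizes as local thickness (largest
  inscribed ball), number density, and genomic-content conversions
  (density × NRL, focus contents, genome fraction).
* **Dynamics** — trap-corrected passive microrheology
  *G*\*(ω) = κ/(6πa) · (1/(iω Π̂(ω)) − 1) with
  Π(τ) = κ·MSD(τ)/(2k<sub>B</sub>T), zero-shear viscosity and G′/G″
  crossovers; stress-relaxation moduli
  G(t) = (V/k<sub>B</sub>T)⟨σ(t₀)σ(t₀+t)⟩; and single-particle tracking
  statistics (ensemble MSD diffusion fits, jump angles, asymmetry
  coefficient AC = log₂ f<sub>fwd</sub>/f<sub>bwd</sub>).

A synthetic-data module generates every input with known ground truth —
zig-zag and two-start helical fibers, packed condensates, random
orientation baths, coarse-grained frames with constructed tail contacts,
trapped beads in Newtonian/Kelvin–Voigt/Maxwell media, and free or
confined tracking data — so each estimator is validated by round trip
against construction parameters or closed forms.

## Worked example

```r
library(nucleopack)

# a synthetic condensate of 200 two-start 12-mers at nuclear-focus density
m <- gen_condensate("bp30_like", n_fibers = 200, target_density = 6e5,
                    seed = 42)
m
#> condensate model: 2400 poses, 200 assigned arrays, mask: box_mask

# radial distribution function against a 100-draw random reference
g <- radial_distribution(m, r_max = 20, bin = 0.5,
                         n_reference_draws = 100, seed = 1)
rdf_first_peak(g)
#> [1] 5.75

# per-fiber geometry of one generated fiber
st <- fiber_step_table(gen_fiber("bp30_like", 12, "high", seed = 1))
round(attr(st, "summary"), 2)
#>   mean_D_nm sd_D_nm mean_para_deg sd_para_deg mean_alpha_deg sd_alpha_deg
#> 1     12.63    8.83         25.45        28.9          80.66        47.78
#>   mean_d_adj_nm sd_d_adj_nm
#> 1         12.78        2.12

# what a 300-nm focus at 6e5 nucleosomes/um^3 contains
str(genomic_content(6e5, nrl = 192, focus_diameter_nm = 300))
#> $ bp_per_um3          : num 1.15e+08
#> $ nucleosomes_in_focus: num 8482
#> $ bp_in_focus         : num 1628602
#> $ genome_fraction     : num 0.000525
```

The g(r) peak within half a bin of 6 nm is the face-to-face stacking rise
of the two-start fibers (disc height 6 nm).  The 300-nm focus numbers read:
115 Mbp of DNA per cubic micrometer, ~8,500 nucleosomes and ~1.6 Mbp per
focus — about 0.05% of a haploid human genome.

A command-line interface wrapping the same functions ships in
`inst/cli/nucleopack` (subcommands `simulate`, `geometry`, `rdf`, `orient`,
`census`, `network`, `digest`, `pores`, `density`, `genomic`, `pmot`, `gt`,
`spt`).

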