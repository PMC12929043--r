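# Voxelized occupancy grids, pore-size (local thickness) distributions,
# nucleosome number density, and genomic-content conversions.

#' Voxelized occupancy grid of a condensate
#'
#' Voxels whose centers fall inside any nucleosome cylinder (radius 5.5 nm,
#' height 6.0 nm, axis = disc normal) are marked occupied.  The condensate
#' mask is the morphological closing of the occupancy with a ball
#' (default radius 12 nm), which fills inter-nucleosome voids while
#' following the outer surface; the occupancy is always a subset of the
#' mask.
#'
#' @param m A `condensate_model` with at least one pose.
#' @param voxel Voxel edge, nm (0.5 to 4; default 1).
#' @param closing_radius_nm Ball radius of the morphological closing, nm.
#' @param r,h Disc dimensions, nm.
#' @param bounds Optional list with `lo` and `hi` corners (nm) fixing the
#'   gridded region, for grids that must be comparable across models (for
#'   example a thinning time course measured against one footprint).
#' @return Object of class `occupancy_grid`: `voxel_size`, `origin`, `dims`,
#'   `occupied` and `mask` (3-D logical arrays).
#' @export
occupancy_grid <- function(m, voxel = 1, closing_radius_nm = 12,
                           r = .NUC_RADIUS, h = .NUC_HEIGHT, bounds = NULL) {
  stopifnot(inherits(m, "condensate_model"))
  if (!nrow(m$centers)) stop("empty model")
  if (voxel < 0.5 || voxel > 4) stop("voxel size must be in [0.5, 4] nm")
  rb <- sqrt(r^2 + (h / 2)^2)
  pad <- rb + closing_radius_nm + 2 * voxel
  if (is.null(bounds)) {
    lo <- apply(m$centers, 2, min) - pad
    hi <- apply(m$centers, 2, max) + pad
  } else {
    lo <- bounds$lo
    hi <- bounds$hi
  }
  dims <- as.integer(ceiling((hi - lo) / voxel))
  occ <- cpp_fill_cylinders(m$centers, m$normals, r, h, lo, voxel, dims)
  rv <- closing_radius_nm / voxel
  # closing = erosion of the dilation; both via Euclidean distance transforms
  d_occ <- cpp_edt3d(occ, dims)
  dil <- d_occ <= rv + 1e-9
  d_bg <- cpp_edt3d(!dil, dims)
  mask <- d_bg > rv - 1e-9
  mask <- mask | occ  # discretization guard: closing contains the input
  dim(occ) <- dims; dim(mask) <- dims
  structure(list(voxel_size = voxel, origin = lo, dims = dims,
                 occupied = occ, mask = mask,
                 closing_radius_nm = closing_radius_nm),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy grid %d x %d x %d, voxel %.2f nm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size))
  cat(sprintf("  occupied %.1f%%, mask %.1f%% of grid\n",
              100 * mean(x$occupied), 100 * mean(x$mask)))
  invisible(x)
}

#' Pore-size (local thickness) distribution
#'
#' For every void voxel (inside the mask, not occupied) the local thickness
#' is the diameter of the largest ball that contains the voxel and fits
#' entirely in the void; computed from the Euclidean distance transform by
#' ball covering.
#'
#' @param g An `occupancy_grid`.
#' @param bin Histogram bin width, nm.
#' @return List with `histogram` (columns `diameter_nm` midpoint, `count`),
#'   `max_pore_nm`, `void_voxels`, and flag `empty` when the mask has no
#'   void.
#' @export
pore_size_distribution <- function(g, bin = 1) {
  stopifnot(inherits(g, "occupancy_grid"))
  if (!any(g$mask)) stop("mask is empty")
  void <- g$mask & !g$occupied
  if (!any(void)) {
    return(list(histogram = data.frame(diameter_nm = numeric(0),
                                       count = integer(0)),
                max_pore_nm = 0, void_voxels = 0L, empty = TRUE))
  }
  dt <- cpp_edt3d(as.logical(!void), g$dims)
  lt <- cpp_local_thickness(dt, as.logical(void), g$dims) * g$voxel_size
  ltv <- lt[as.logical(void)]
  mx <- max(ltv)
  breaks <- seq(0, max(bin, ceiling(mx / bin) * bin), by = bin)
  cnt <- tabulate(pmin(length(breaks) - 1, floor(ltv / bin) + 1),
                  nbins = length(breaks) - 1)
  list(histogram = data.frame(diameter_nm = breaks[-length(breaks)] + bin / 2,
                              count = cnt),
       max_pore_nm = mx, void_voxels = sum(void), empty = FALSE)
}

#' Nucleosome number density
#'
#' Pose count inside the mask divided by the mask volume.
#'
#' @param m A `condensate_model` with a mask, or an `occupancy_grid` plus
#'   the model via `model`.
#' @param grid Optional `occupancy_grid` whose mask supersedes the model's.
#' @return Density in nucleosomes per cubic micrometer.
#' @export
number_density <- function(m, grid = NULL) {
  stopifnot(inherits(m, "condensate_model"))
  mask <- if (!is.null(grid)) grid else m$mask
  if (is.null(mask)) stop("no mask defined")
  vol <- mask_volume_nm3(mask)
  if (vol <= 0) stop("mask volume is zero")
  count <- sum(points_in_mask(m$centers, mask))
  count / vol * 1e9  # nm^-3 -> um^-3
}

#' Genomic content of chromatin foci
#'
#' Closed-form conversions from nucleosome number density: base pairs per
#' cubic micrometer (`density * nrl`), nucleosomes in a spherical focus of
#' the given diameter (`density * pi/6 * d^3`), base pairs in the focus, and
#' the fraction of the genome it represents.
#'
#' @param density Nucleosomes per cubic micrometer.
#' @param nrl Nucleosome repeat length, bp (default 192).
#' @param focus_diameter_nm Focus diameter, nm.
#' @param genome_size_bp Genome size in bp (default 3.1e9, human haploid).
#' @return List with `bp_per_um3`, `nucleosomes_in_focus`, `bp_in_focus`,
#'   `genome_fraction`.
#' @export
#' @examples
#' genomic_content(6e5, 192, 300)  # 115.2 Mbp/um^3; ~8500 nucleosomes
genomic_content <- function(density, nrl = 192, focus_diameter_nm = 200,
                            genome_size_bp = 3.1e9) {
  stopifnot(density >= 0, nrl > 0, focus_diameter_nm > 0, genome_size_bp > 0)
  bp_per_um3 <- density * nrl
  focus_vol_um3 <- pi / 6 * (focus_diameter_nm / 1000)^3
  nucs <- density * focus_vol_um3
  bp <- nucs * nrl
  list(bp_per_um3 = bp_per_um3,
       nucleosomes_in_focus = nucs,
       bp_in_focus = bp,
       genome_fraction = bp / genome_size_bp)
}
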