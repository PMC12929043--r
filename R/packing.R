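# Condensate-scale pairwise statistics: radial distribution functions,
# nearest-neighbour orientation distributions, packing-geometry
# classification, and intra/inter-array contact censuses.

# ---- cylinder-cylinder separation ------------------------------------------

#' Minimal separation between two nucleosome discs
#'
#' Distance between the surfaces of two solid cylinders (alternating
#' Euclidean projections between the convex bodies).  For overlapping discs
#' a negative separation is estimated by shrinking both cylinders about
#' their centers until disjoint.
#'
#' @param c1,c2 Centers, nm.
#' @param n1,n2 Unit axis (disc normal) vectors.
#' @param r Cylinder radius, nm.
#' @param h Cylinder height, nm.
#' @param face_frac Cap radial fraction defining the "face" region.
#' @return List with `separation` (nm, negative if overlapping), `facets`
#'   (character 2-vector, "face"/"side"), `points` (2 x 3 closest points) and
#'   `overlap` flag.
#' @export
cylinder_separation <- function(c1, n1, c2, n2, r = .NUC_RADIUS,
                                h = .NUC_HEIGHT, face_frac = 0.9) {
  n1 <- .unit(n1); n2 <- .unit(n2)
  res <- cpp_cyl_separation(as.numeric(c1), n1, as.numeric(c2), n2,
                            r, h, face_frac)
  list(separation = res$separation,
       facets = c("face", "side")[c(res$fa, res$fb) + 1L],
       points = res$points, overlap = res$overlap)
}

#' Classify the packing geometry of a nucleosome pair
#'
#' Each nucleosome is modeled as a solid cylinder (axis = disc normal).  A
#' pair is in contact when the minimal surface-surface separation is at most
#' `gate_nm`.  The contacting facet of each disc is "face" when the closest
#' point lies on a flat cap within radial fraction `face_frac` of the cap,
#' else "side"; the pair class is `face-to-face`, `face-to-side` or
#' `side-to-side`.  Overlapping discs are flagged and classified by the
#' facets of deepest overlap.
#'
#' @param a,b `nucleosome_pose` objects.
#' @param gate_nm Contact gate on surface separation, nm.
#' @param r,h,face_frac Disc geometry, see [cylinder_separation()].
#' @return List with `class` (`NA` when the contact gate fails),
#'   `separation_nm`, `facets` and `overlap`.
#' @export
classify_contact <- function(a, b, gate_nm = 2.0, r = .NUC_RADIUS,
                             h = .NUC_HEIGHT, face_frac = 0.9) {
  validate_pose(a); validate_pose(b)
  cs <- cylinder_separation(a$center, a$normal, b$center, b$normal,
                            r = r, h = h, face_frac = face_frac)
  if (cs$separation > gate_nm)
    return(list(class = NA_character_, separation_nm = cs$separation,
                facets = cs$facets, overlap = FALSE))
  fl <- sort(cs$facets)  # "face" sorts before "side"
  cls <- paste(fl[1], "to", fl[2], sep = "-")
  list(class = cls, separation_nm = cs$separation, facets = cs$facets,
       overlap = cs$overlap)
}

# ---- radial distribution function ------------------------------------------

#' Radial distribution function of nucleosome centers
#'
#' Pair-distance histogram of the model's centers normalized by the mean
#' histogram of `n_reference_draws` random placements of the same number of
#' centers uniformly inside the mask (Monte-Carlo edge correction): for a
#' random input, g tends to 1 at large r.
#'
#' @param m A `condensate_model` with at least 100 poses and a mask.
#' @param r_max Largest distance, nm; must not exceed the mask extent.
#' @param bin Bin width, nm.
#' @param n_reference_draws Number of random reference draws.
#' @param seed Integer seed for the reference draws.
#' @return Data.frame of class `rdf` with columns `r_nm` (bin midpoint),
#'   `g_r`, `pairs_data`, `pairs_reference`.
#' @export
radial_distribution <- function(m, r_max, bin = 0.5, n_reference_draws = 100,
                                seed = 1) {
  stopifnot(inherits(m, "condensate_model"))
  n <- nrow(m$centers)
  if (n < 100) stop("radial_distribution needs at least 100 poses")
  if (bin <= 0) stop("bin width must be positive")
  if (is.null(m$mask)) stop("the model has no mask")
  if (mask_volume_nm3(m$mask) <= 0) stop("empty mask")
  if (r_max > mask_extent_nm(m$mask))
    stop("r_max exceeds the mask extent")
  breaks <- seq(0, r_max + bin, by = bin)
  nb <- length(breaks) - 1
  hist_pairs <- function(coords) {
    pr <- cpp_neighbor_pairs(coords, r_max)
    if (!nrow(pr)) return(numeric(nb))
    tabulate(pmin(nb, floor(pr$dist / bin) + 1), nbins = nb)
  }
  h_data <- hist_pairs(m$centers)
  h_ref <- with_seed(seed, {
    acc <- numeric(nb)
    for (k in seq_len(n_reference_draws))
      acc <- acc + hist_pairs(sample_in_mask(n, m$mask))
    acc / n_reference_draws
  })
  g <- ifelse(h_ref > 0, h_data / h_ref, NA_real_)
  out <- data.frame(r_nm = breaks[-length(breaks)] + bin / 2, g_r = g,
                    pairs_data = h_data, pairs_reference = h_ref)
  out <- out[out$r_nm <= r_max, ]
  class(out) <- c("rdf", "data.frame")
  attr(out, "n_poses") <- n
  attr(out, "n_reference_draws") <- n_reference_draws
  out
}

#' First local maximum of a radial distribution function
#'
#' @param rdf Output of [radial_distribution()].
#' @param min_g Minimum g value for a peak to count (suppresses noise in the
#'   near-empty small-r bins).
#' @return Radius (bin midpoint, nm) of the first local maximum, or `NA`.
#' @export
rdf_first_peak <- function(rdf, min_g = 1) {
  g <- rdf$g_r
  for (i in seq_along(g)) {
    if (!is.finite(g[i]) || g[i] < min_g) next
    left_ok <- i == 1 || !is.finite(g[i - 1]) || g[i] > g[i - 1]
    right_ok <- i == length(g) || !is.finite(g[i + 1]) || g[i] >= g[i + 1]
    if (left_ok && right_ok) return(rdf$r_nm[i])
  }
  NA_real_
}

#' @export
plot.rdf <- function(x, ...) {
  graphics::plot(x$r_nm, x$g_r, type = "l", xlab = "r (nm)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 2, col = "grey")
  invisible(x)
}

# ---- nearest neighbours -----------------------------------------------------

#' Nearest-neighbour pose pairs
#'
#' In k-mode each pose is paired with its `k` nearest centers (deterministic
#' tie-break: the lower pose id wins); in cutoff-mode all pairs within
#' `cutoff` nm are returned.  Pairs are deduplicated and unordered (i < j).
#'
#' @param m A `condensate_model`.
#' @param k Number of nearest neighbours per pose (ignored when `cutoff`
#'   given).
#' @param cutoff Optional distance cutoff in nm.
#' @return Data.frame with columns `i`, `j` (pose ids) and `dist_nm`.
#' @export
nearest_neighbor_pairs <- function(m, k = 1, cutoff = NULL) {
  stopifnot(inherits(m, "condensate_model"))
  n <- nrow(m$centers)
  if (n < 2) stop("need at least 2 poses")
  if (!is.null(cutoff)) {
    pr <- cpp_neighbor_pairs(m$centers, cutoff)
    return(data.frame(i = m$ids[pr$i], j = m$ids[pr$j], dist_nm = pr$dist))
  }
  if (k >= n) stop("k must be smaller than the number of poses")
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(m$centers) - m$centers[i, ])^2))
    d[i] <- Inf
    # order by (distance, id): deterministic tie-break by ascending id
    ord <- order(d, m$ids)[seq_len(k)]
    res_i <- c(res_i, rep(i, k)); res_j <- c(res_j, ord)
    res_d <- c(res_d, d[ord])
  }
  a <- pmin(res_i, res_j); b <- pmax(res_i, res_j)
  keep <- !duplicated(cbind(a, b))
  data.frame(i = m$ids[a[keep]], j = m$ids[b[keep]], dist_nm = res_d[keep])
}

#' Nearest-neighbour orientation distribution
#'
#' Histogram over \[0, 90\] degrees of the plane angles of the given pose
#' pairs, with the random reference curve: for isotropic orientations the
#' plane-angle density is proportional to sin(theta), normalized here to the
#' same total count.
#'
#' @param pairs Data.frame with pose-id columns `i`, `j` (as returned by
#'   [nearest_neighbor_pairs()]).
#' @param m The `condensate_model` the ids refer to.
#' @param bin Bin width in degrees.
#' @return Data.frame with columns `theta_deg` (bin midpoint), `count` and
#'   `reference`; attribute `mean_angle_deg`.
#' @export
orientation_distribution <- function(pairs, m, bin = 5) {
  if (!nrow(pairs)) stop("no pairs supplied")
  idx <- match(pairs$i, m$ids); jdx <- match(pairs$j, m$ids)
  if (anyNA(idx) || anyNA(jdx)) stop("pair ids not found in model")
  ang <- vplane_angle(m$normals[idx, , drop = FALSE],
                      m$normals[jdx, , drop = FALSE])
  breaks <- seq(0, 90, by = bin)
  cnt <- tabulate(pmin(length(breaks) - 1, floor(ang / bin) + 1),
                  nbins = length(breaks) - 1)
  ref <- (cos(breaks[-length(breaks)] * pi / 180) -
          cos(breaks[-1] * pi / 180)) * length(ang)
  out <- data.frame(theta_deg = breaks[-length(breaks)] + bin / 2,
                    count = cnt, reference = ref)
  attr(out, "mean_angle_deg") <- mean(ang)
  attr(out, "angles_deg") <- ang
  out
}

# ---- contact census ---------------------------------------------------------

# classify all candidate pairs of a model; returns the contact records table
contact_records <- function(m, gate_nm = 2.0, r = .NUC_RADIUS, h = .NUC_HEIGHT,
                            face_frac = 0.9) {
  cutoff <- 2 * sqrt(r^2 + (h / 2)^2) + gate_nm
  pr <- cpp_neighbor_pairs(m$centers, cutoff)
  if (!nrow(pr))
    return(data.frame(pose_i = integer(0), pose_j = integer(0),
                      geometry_class = character(0), scope = character(0),
                      center_distance_nm = numeric(0)))
  cls <- character(nrow(pr)); sep <- numeric(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    cc <- cylinder_separation(m$centers[i, ], m$normals[i, ],
                              m$centers[j, ], m$normals[j, ],
                              r = r, h = h, face_frac = face_frac)
    sep[k] <- cc$separation
    cls[k] <- if (cc$separation > gate_nm) NA_character_ else {
      fl <- sort(cc$facets)
      paste(fl[1], "to", fl[2], sep = "-")
    }
  }
  keep <- !is.na(cls)
  pr <- pr[keep, , drop = FALSE]; cls <- cls[keep]
  ai <- aj <- rep(NA_integer_, nrow(pr))
  if (!is.null(m$array_of)) {
    ai <- unname(m$array_of[as.character(m$ids[pr$i])])
    aj <- unname(m$array_of[as.character(m$ids[pr$j])])
  }
  scope <- ifelse(is.na(ai) | is.na(aj), "unassigned",
                  ifelse(ai == aj, "intra-array", "inter-array"))
  # drop covalently adjacent intra-array pairs when fiber order is known
  if (!is.null(m$seq_index)) {
    adj <- scope == "intra-array" &
      abs(m$seq_index[pr$i] - m$seq_index[pr$j]) < 2
    pr <- pr[!adj, , drop = FALSE]; cls <- cls[!adj]; scope <- scope[!adj]
  }
  data.frame(pose_i = m$ids[pr$i], pose_j = m$ids[pr$j],
             geometry_class = cls, scope = scope,
             center_distance_nm = pr$dist)
}

#' Intra- and inter-array contact census
#'
#' Classifies every in-contact nucleosome pair (candidate pairs from a
#' cell-list neighbour search) and summarizes, per focal array, the number
#' of intra-array contacts (same array, sequence separation >= 2 when the
#' fiber order is known) and inter-array contacts, broken down by packing
#' geometry class.
#'
#' @param m A `condensate_model` with array assignments.
#' @param gate_nm Contact gate on surface separation, nm.
#' @param r,h,face_frac Disc geometry.
#' @return List with `records` (per-contact table), `per_array` (per-array
#'   counts), and `summary` (ensemble means and SDs).
#' @export
contact_census <- function(m, gate_nm = 2.0, r = .NUC_RADIUS, h = .NUC_HEIGHT,
                           face_frac = 0.9) {
  stopifnot(inherits(m, "condensate_model"))
  if (is.null(m$array_of) || !length(m$array_of))
    stop("contact_census needs array assignments (array_of)")
  rec <- contact_records(m, gate_nm = gate_nm, r = r, h = h,
                         face_frac = face_frac)
  arrays <- sort(unique(unname(m$array_of)))
  classes <- c("face-to-face", "face-to-side", "side-to-side")
  per <- do.call(rbind, lapply(arrays, function(a) {
    ids_a <- as.integer(names(m$array_of))[m$array_of == a]
    touches <- rec$pose_i %in% ids_a | rec$pose_j %in% ids_a
    intra <- sum(touches & rec$scope == "intra-array")
    inter <- sum(touches & rec$scope == "inter-array")
    cl <- table(factor(rec$geometry_class[touches], levels = classes))
    data.frame(array = a, intra = intra, inter = inter,
               face_to_face = as.integer(cl[1]),
               face_to_side = as.integer(cl[2]),
               side_to_side = as.integer(cl[3]))
  }))
  summary <- data.frame(
    mean_intra = mean(per$intra), sd_intra = sd(per$intra),
    mean_inter = mean(per$inter), sd_inter = sd(per$inter),
    frac_face_to_face = mean(rec$geometry_class == "face-to-face"),
    frac_face_to_side = mean(rec$geometry_class == "face-to-side"),
    frac_side_to_side = mean(rec$geometry_class == "side-to-side"),
    n_contacts = nrow(rec))
  list(records = rec, per_array = per, summary = summary)
}
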