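# Condensate models: a set of nucleosome poses with optional array (traced
# molecule) assignments and a spatial mask delimiting the condensate region.

#' Construct a condensate model
#'
#' @param centers n x 3 matrix of pose centers, nm.
#' @param normals n x 3 matrix of unit disc normals.
#' @param dyads Optional n x 3 matrix of unit dyad axes.
#' @param ids Integer pose ids (unique); default `1:n`.
#' @param array_of Optional named integer vector mapping pose id (name) to
#'   array id, for poses that belong to traced arrays.
#' @param seq_index Optional integer vector: position of each pose within its
#'   array (DNA order), used to separate trivially adjacent intra-array pairs.
#' @param mask A mask object (`box_mask()` or an `occupancy_grid`), or `NULL`.
#' @param density_target Optional target density, nucleosomes per cubic
#'   micrometer (metadata).
#' @return An object of class `condensate_model`.
#' @export
condensate_model <- function(centers, normals, dyads = NULL, ids = NULL,
                             array_of = NULL, seq_index = NULL, mask = NULL,
                             density_target = NULL) {
  centers <- as.matrix(centers); normals <- as.matrix(normals)
  n <- nrow(centers)
  stopifnot(ncol(centers) == 3, all(dim(normals) == dim(centers)))
  normals <- normals / sqrt(rowSums(normals^2))
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("pose ids must be unique")
  if (is.null(dyads)) {
    dyads <- t(apply(normals, 1, function(nv) {
      ref <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      .unit(.cross(ref, nv))
    }))
  }
  if (!is.null(array_of)) {
    if (is.null(names(array_of))) stop("array_of must be named by pose id")
    bad <- setdiff(as.integer(names(array_of)), ids)
    if (length(bad)) stop("array_of keys are not pose ids: ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(centers = centers, normals = normals, dyads = dyads,
                 ids = ids, array_of = array_of, seq_index = seq_index,
                 mask = mask, density_target = density_target),
            class = "condensate_model")
}

#' @export
print.condensate_model <- function(x, ...) {
  na <- if (is.null(x$array_of)) 0L else length(unique(x$array_of))
  cat(sprintf("condensate model: %d poses, %d assigned arrays, mask: %s\n",
              nrow(x$centers), na,
              if (is.null(x$mask)) "none" else class(x$mask)[1]))
  invisible(x)
}

#' @export
length.condensate_model <- function(x) nrow(x$centers)

# ---- masks ------------------------------------------------------------------

#' Axis-aligned box mask
#'
#' @param lo,hi Numeric 3-vectors, opposite corners in nm.
#' @return An object of class `box_mask`.
#' @export
box_mask <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) == 1) lo <- rep(lo, 3)
  if (length(hi) == 1) hi <- rep(hi, 3)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  structure(list(lo = lo, hi = hi), class = "box_mask")
}

#' Mask volume
#'
#' @param mask A `box_mask` or `occupancy_grid`.
#' @return Volume in cubic nanometers.
#' @export
mask_volume_nm3 <- function(mask) {
  if (inherits(mask, "box_mask")) return(prod(mask$hi - mask$lo))
  if (inherits(mask, "occupancy_grid")) return(sum(mask$mask) * mask$voxel_size^3)
  stop("unsupported mask type")
}

# largest distance spanned by the mask along any axis
mask_extent_nm <- function(mask) {
  if (inherits(mask, "box_mask")) return(max(mask$hi - mask$lo))
  if (inherits(mask, "occupancy_grid")) return(max(mask$dims) * mask$voxel_size)
  stop("unsupported mask type")
}

# n uniform points inside the mask
sample_in_mask <- function(n, mask) {
  if (inherits(mask, "box_mask")) {
    return(cbind(runif(n, mask$lo[1], mask$hi[1]),
                 runif(n, mask$lo[2], mask$hi[2]),
                 runif(n, mask$lo[3], mask$hi[3])))
  }
  if (inherits(mask, "occupancy_grid")) {
    idx <- which(mask$mask)
    if (!length(idx)) stop("empty mask")
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    d <- mask$dims
    iz <- (pick - 1) %/% (d[1] * d[2])
    iy <- ((pick - 1) %% (d[1] * d[2])) %/% d[1]
    ix <- (pick - 1) %% d[1]
    return(cbind(mask$origin[1] + (ix + runif(n)) * mask$voxel_size,
                 mask$origin[2] + (iy + runif(n)) * mask$voxel_size,
                 mask$origin[3] + (iz + runif(n)) * mask$voxel_size))
  }
  stop("unsupported mask type")
}

# logical: which points fall inside the mask
points_in_mask <- function(points, mask) {
  points <- as.matrix(points)
  if (inherits(mask, "box_mask")) {
    return(points[, 1] >= mask$lo[1] & points[, 1] <= mask$hi[1] &
           points[, 2] >= mask$lo[2] & points[, 2] <= mask$hi[2] &
           points[, 3] >= mask$lo[3] & points[, 3] <= mask$hi[3])
  }
  if (inherits(mask, "occupancy_grid")) {
    d <- mask$dims
    ix <- floor((points[, 1] - mask$origin[1]) / mask$voxel_size)
    iy <- floor((points[, 2] - mask$origin[2]) / mask$voxel_size)
    iz <- floor((points[, 3] - mask$origin[3]) / mask$voxel_size)
    inside <- ix >= 0 & iy >= 0 & iz >= 0 & ix < d[1] & iy < d[2] & iz < d[3]
    out <- logical(nrow(points))
    lin <- 1 + ix[inside] + d[1] * (iy[inside] + d[2] * iz[inside])
    out[inside] <- mask$mask[lin]
    return(out)
  }
  stop("unsupported mask type")
}

# ---- random bath ------------------------------------------------------------

#' Random orientation bath
#'
#' A reference condensate of `n` nucleosomes placed uniformly in a cubic box
#' sized to give the requested number density, with orientations uniform on
#' the rotation group.
#'
#' @param n Number of nucleosomes.
#' @param density Number density, nucleosomes per cubic micrometer.
#' @param seed Integer seed (mandatory: the bath is stochastic).
#' @return A `condensate_model` with a cubic `box_mask`.
#' @export
#' @examples
#' b <- random_bath(600, 6e5, seed = 1)
#' mask_volume_nm3(b$mask)  # (100 nm)^3
random_bath <- function(n, density, seed) {
  stopifnot(n > 0, density > 0)
  vol_nm3 <- n / density * 1e9  # 1 um^3 = 1e9 nm^3
  disc_vol <- pi * .NUC_RADIUS^2 * .NUC_HEIGHT
  if (n * disc_vol / vol_nm3 > 0.6)
    stop("requested density implies a volume fraction above 60%")
  side <- vol_nm3^(1 / 3)
  with_seed(seed, {
    centers <- matrix(runif(3 * n, 0, side), n, 3)
    q <- random_quaternions(n)
    normals <- t(apply(q, 1, function(qi) quat_to_matrix(qi)[, 3]))
    dyads <- t(apply(q, 1, function(qi) quat_to_matrix(qi)[, 1]))
    condensate_model(centers, normals, dyads,
                     mask = box_mask(c(0, 0, 0), rep(side, 3)),
                     density_target = density)
  })
}
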