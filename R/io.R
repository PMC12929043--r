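# Readers and writers: pose tables (CSV and RELION-style STAR), trajectory
# CSV with YAML metadata sidecars, MRC volume export, and disc-frame
# derivation from template structures.
#
# Conventions: coordinates are nm internally (coarse-grained frames are
# Angstrom); pose quaternions are scalar-first, with disc normal = local +z
# and dyad = local +x; STAR Euler angles follow the RELION 3.1 ZYZ
# convention.

# ---- pose CSV ---------------------------------------------------------------

#' Write a pose table as CSV
#'
#' Columns: `id`, `fiber_id` (when array assignments exist), `x_nm`, `y_nm`,
#' `z_nm`, `qw`, `qx`, `qy`, `qz` (unit quaternion, scalar-first; disc
#' normal = local +z, dyad = local +x; right-handed coordinates).
#'
#' @param m A `condensate_model` or `fiber`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(m, path) {
  if (inherits(m, "fiber")) {
    ids <- seq_len(nrow(m$centers))
    fid <- rep(1L, length(ids))
    centers <- m$centers; normals <- m$normals; dyads <- m$dyads
  } else {
    stopifnot(inherits(m, "condensate_model"))
    ids <- m$ids
    fid <- if (is.null(m$array_of)) rep(NA_integer_, length(ids)) else
      unname(m$array_of[as.character(ids)])
    centers <- m$centers; normals <- m$normals; dyads <- m$dyads
  }
  q <- t(vapply(seq_along(ids), function(i) {
    M <- cbind(dyads[i, ], .cross(normals[i, ], dyads[i, ]), normals[i, ])
    matrix_to_quat(M)
  }, numeric(4)))
  df <- data.frame(id = ids, fiber_id = fid,
                   x_nm = centers[, 1], y_nm = centers[, 2],
                   z_nm = centers[, 3],
                   qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose table
#'
#' CSV dialect: columns as written by [write_pose_csv()], lengths in nm.
#' STAR dialect: RELION-style particle blocks with `rlnCoordinateX/Y/Z`
#' (optionally minus `rlnOriginX/Y/Z`), scaled by `pixel_size_nm`, and
#' `rlnAngleRot/Tilt/Psi` Euler angles (ZYZ, degrees).
#'
#' @param path Input path.
#' @param format `"csv"` or `"star"` (default from the file extension).
#' @param pixel_size_nm Pixel size for STAR coordinates (nm per pixel);
#'   required for STAR input.
#' @return A `condensate_model` (array assignments from `fiber_id` when
#'   present).
#' @export
read_poses <- function(path, format = NULL, pixel_size_nm = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "csv"
  if (format == "star") return(.read_poses_star(path, pixel_size_nm))
  df <- utils::read.csv(path)
  need <- c("id", "x_nm", "y_nm", "z_nm", "qw", "qx", "qy", "qz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing pose columns: ", paste(miss, collapse = ", "))
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  qn <- sqrt(rowSums(q^2))
  if (any(abs(qn - 1) > 1e-3))
    stop("non-unit quaternions beyond tolerance in ", path)
  q <- q / qn
  n <- nrow(df)
  normals <- matrix(0, n, 3); dyads <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- quat_to_matrix(q[i, ])
    normals[i, ] <- M[, 3]; dyads[i, ] <- M[, 1]
  }
  ao <- NULL
  if ("fiber_id" %in% names(df) && !all(is.na(df$fiber_id))) {
    ao <- as.integer(df$fiber_id)
    names(ao) <- as.character(df$id)
    ao <- ao[!is.na(ao)]
  }
  condensate_model(as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
                   normals, dyads, ids = df$id, array_of = ao)
}

# minimal RELION-style STAR block reader: returns a data.frame of the first
# loop block containing the requested columns
read_star_block <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "loop_") {
      cols <- character(0)
      j <- i + 1
      while (j <= length(lines) && startsWith(lines[j], "_")) {
        cols <- c(cols, sub("^_([^ #]+).*$", "\\1", lines[j]))
        j <- j + 1
      }
      rows <- list()
      while (j <= length(lines) && nzchar(lines[j]) &&
             !startsWith(lines[j], "data_") && lines[j] != "loop_") {
        rows[[length(rows) + 1]] <- strsplit(lines[j], "[ \t]+")[[1]]
        j <- j + 1
      }
      if (length(rows)) {
        m <- do.call(rbind, rows)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- cols[seq_len(ncol(df))]
        for (k in names(df)) {
          sup <- suppressWarnings(as.numeric(df[[k]]))
          if (!anyNA(sup)) df[[k]] <- sup
        }
        return(df)
      }
    }
    i <- i + 1
  }
  stop("no loop block found in ", path)
}

# RELION 3.1 ZYZ Euler angles (degrees) -> rotation matrix whose columns are
# the particle frame axes in the lab frame
euler_zyz_to_matrix <- function(rot, tilt, psi) {
  Rz <- function(a) rotation_about(c(0, 0, 1), a)
  Ry <- function(a) rotation_about(c(0, 1, 0), a)
  t(Rz(psi) %*% Ry(tilt) %*% Rz(rot))
}

matrix_to_euler_zyz <- function(M) {
  A <- t(M)
  tilt <- acos(max(-1, min(1, A[3, 3]))) * 180 / pi
  if (abs(A[3, 3]) > 1 - 1e-12) {
    rot <- 0
    psi <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  } else {
    rot <- atan2(A[3, 2], -A[3, 1]) * 180 / pi
    psi <- atan2(A[2, 3], A[1, 3]) * 180 / pi
  }
  c(rot = rot %% 360, tilt = tilt, psi = psi %% 360)
}

.read_poses_star <- function(path, pixel_size_nm) {
  df <- read_star_block(path)
  need <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing STAR columns: ", paste(miss, collapse = ", "))
  if (is.null(pixel_size_nm)) {
    if ("rlnPixelSize" %in% names(df)) {
      pixel_size_nm <- df$rlnPixelSize[1] / 10  # Angstrom -> nm
    } else stop("pixel_size_nm is required for STAR input")
  }
  xyz <- cbind(df$rlnCoordinateX, df$rlnCoordinateY, df$rlnCoordinateZ)
  for (k in 1:3) {
    oc <- c("rlnOriginX", "rlnOriginY", "rlnOriginZ")[k]
    if (oc %in% names(df)) xyz[, k] <- xyz[, k] - df[[oc]]
  }
  xyz <- xyz * pixel_size_nm
  n <- nrow(df)
  normals <- matrix(0, n, 3); dyads <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- euler_zyz_to_matrix(df$rlnAngleRot[i], df$rlnAngleTilt[i],
                             df$rlnAnglePsi[i])
    normals[i, ] <- M[, 3]; dyads[i, ] <- M[, 1]
  }
  ids <- if ("rlnImageName" %in% names(df)) seq_len(n) else seq_len(n)
  ao <- NULL
  if ("rlnHelicalTubeID" %in% names(df)) {
    ao <- as.integer(df$rlnHelicalTubeID); names(ao) <- as.character(ids)
  }
  condensate_model(xyz, normals, dyads, ids = ids, array_of = ao)
}

#' Write a pose table as a RELION-style STAR file
#'
#' @param m A `condensate_model` or `fiber`.
#' @param path Output path.
#' @param pixel_size_nm Pixel size used to express coordinates in pixels.
#' @return `path`, invisibly.
#' @export
write_pose_star <- function(m, path, pixel_size_nm = 1) {
  if (inherits(m, "fiber")) {
    centers <- m$centers; normals <- m$normals; dyads <- m$dyads
    tube <- rep(1L, nrow(centers))
  } else {
    centers <- m$centers; normals <- m$normals; dyads <- m$dyads
    tube <- if (is.null(m$array_of)) rep(1L, nrow(centers)) else
      unname(m$array_of[as.character(m$ids)])
  }
  eul <- t(vapply(seq_len(nrow(centers)), function(i) {
    M <- cbind(dyads[i, ], .cross(normals[i, ], dyads[i, ]), normals[i, ])
    matrix_to_euler_zyz(M)
  }, numeric(3)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_particles", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2",
               "_rlnCoordinateZ #3", "_rlnAngleRot #4", "_rlnAngleTilt #5",
               "_rlnAnglePsi #6", "_rlnHelicalTubeID #7"), con)
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %.6f %d",
                     centers[, 1] / pixel_size_nm,
                     centers[, 2] / pixel_size_nm,
                     centers[, 3] / pixel_size_nm,
                     eul[, 1], eul[, 2], eul[, 3], tube), con)
  invisible(path)
}

# ---- trajectory CSV ---------------------------------------------------------

#' Write a bead or particle trajectory as CSV with a YAML sidecar
#'
#' CSV columns: `time_s`, `x_nm`, `y_nm`(, `z_nm`); the sidecar
#' (`<path>.yaml`) stores bead radius, temperature and trap stiffness.
#'
#' @param t A `bead_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(t, path) {
  stopifnot(inherits(t, "bead_trajectory"))
  pos <- t$positions
  df <- data.frame(time_s = seq_len(nrow(pos)) * t$dt - t$dt)
  for (k in seq_len(ncol(pos)))
    df[[c("x_nm", "y_nm", "z_nm")[k]]] <- pos[, k]
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(bead_radius_um = t$bead_radius_um,
                        temperature_K = t$temperature_K,
                        kappa = t$kappa, dt_s = t$dt),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a trapped-bead trajectory from CSV (+ optional YAML sidecar)
#'
#' @param path CSV path with `time_s` and `x_nm`(, `y_nm`, `z_nm`) columns.
#' @param bead_radius_um,temperature_K,kappa Metadata overriding the
#'   sidecar.
#' @return A `bead_trajectory`.
#' @export
read_trajectory_csv <- function(path, bead_radius_um = NULL,
                                temperature_K = NULL, kappa = NULL) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  dts <- diff(df$time_s)
  if (length(dts) && (max(dts) - min(dts)) > 1e-9 * max(abs(dts)))
    stop("non-uniform sampling in ", path)
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  axes <- intersect(c("x_nm", "y_nm", "z_nm"), names(df))
  if (!length(axes)) stop("no position columns found")
  bead_trajectory(as.matrix(df[, axes, drop = FALSE]), dts[1],
                  bead_radius_um %||% meta$bead_radius_um,
                  temperature_K %||% meta$temperature_K %||% 298,
                  kappa %||% meta$kappa)
}

#' Read single-particle tracks from CSV
#'
#' Columns: `track_id`, `frame`, `x_um`, `y_um` (optionally `t_s`).
#'
#' @param path CSV path.
#' @param dt Frame interval, seconds (derived from `t_s` when present).
#' @return List of `trajectory` objects.
#' @export
read_tracks_csv <- function(path, dt = NULL) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing track columns: ", paste(miss, collapse = ", "))
  if (is.null(dt)) {
    if (!"t_s" %in% names(df)) stop("dt is required without a t_s column")
    one <- df[df$track_id == df$track_id[1], ]
    dt <- diff(one$t_s[order(one$frame)])[1]
  }
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    trajectory(as.matrix(d[, c("x_um", "y_um")]), dt, d$frame,
               track_id = d$track_id[1])
  })
}

# ---- MRC export -------------------------------------------------------------

#' Write an occupancy grid as an MRC volume
#'
#' Mode-2 (float32) MRC with voxel size recorded in the header; the
#' occupancy (or mask) is written as 0/1 values.
#'
#' @param g An `occupancy_grid`.
#' @param path Output path.
#' @param what `"occupied"` or `"mask"`.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(g, path, what = c("occupied", "mask")) {
  stopifnot(inherits(g, "occupancy_grid"))
  what <- match.arg(what)
  vol <- g[[what]]
  d <- g$dims
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L,
                        d[1], d[2], d[3])), con, size = 4, endian = "little")
  # cell dimensions in Angstrom (1 nm = 10 A)
  writeBin(as.numeric(d * g$voxel_size * 10), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 1, mean(vol))), con, size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L, 0L)), con, size = 4, endian = "little")
  writeBin(raw(1024 - 25 * 4), con)
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

# ---- template frame derivation ---------------------------------------------

#' Derive the disc frame from a nucleosome template structure
#'
#' The disc normal is the smallest-variance principal axis of the DNA
#' phosphate coordinates (the superhelix is flat, so its thin direction is
#' the disc axis).  The sign is fixed toward the centroid of a reference
#' atom selection (for example the H4 tail residues of one face) when
#' given, else toward the structure's first protein chain N-terminus, else
#' arbitrary (+ of the principal axis).  The dyad is the projection onto
#' the disc plane of the vector from the DNA centroid to the middle DNA
#' phosphate (the pseudo-symmetry axis).
#'
#' @param pdb Path to a PDB file or a `bio3d` `pdb` object containing
#'   nucleosomal DNA.
#' @param face_selection Optional `bio3d` atom selection (result of
#'   `bio3d::atom.select`) marking the reference face.
#' @return List with unit vectors `normal` and `dyad`, the DNA centroid
#'   `center` (nm), and a `report` string.
#' @export
derive_frame_from_template <- function(pdb, face_selection = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  atoms <- pdb$atom
  psel <- atoms$elety %in% c("P", "P1", "P2")
  if (!any(psel)) {
    # fall back to any nucleic-acid atoms
    psel <- atoms$resid %in% c("DA", "DT", "DG", "DC", "A", "T", "G", "C",
                               "U", "DU")
  }
  if (!any(psel)) stop("no DNA phosphate atoms found in the template")
  P <- as.matrix(atoms[psel, c("x", "y", "z")])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  normal <- ev$vectors[, 3]  # smallest-variance axis, PCA seed
  # refine to the superhelix axis: the helical rise biases the plain PCA
  # axis, so minimize the variance of the radial distance from the axis
  rad_var <- function(ang) {
    a <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    ax <- Pc %*% a
    var(sqrt(pmax(0, rowSums(Pc^2) - ax^2)))
  }
  th0 <- acos(max(-1, min(1, normal[3])))
  ph0 <- atan2(normal[2], normal[1])
  op <- stats::optim(c(th0, ph0), rad_var, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  normal <- c(sin(op$par[1]) * cos(op$par[2]),
              sin(op$par[1]) * sin(op$par[2]), cos(op$par[1]))
  refpt <- NULL
  if (!is.null(face_selection)) {
    refpt <- colMeans(as.matrix(atoms[face_selection$atom, c("x", "y", "z")]))
  } else {
    prot <- atoms$resid %in% bio3d::aa.table$aa3
    if (any(prot)) {
      ch <- atoms$chain[prot][1]
      sel <- prot & atoms$chain == ch
      refpt <- as.matrix(atoms[sel, c("x", "y", "z")])[1, ]
    }
  }
  if (!is.null(refpt) && sum((refpt - ctr) * normal) < 0) normal <- -normal
  # dyad: middle phosphate projected onto the disc plane
  mid <- P[round(nrow(P) / 2), ]
  dv <- mid - ctr
  dv <- dv - sum(dv * normal) * normal
  dyad <- .unit(dv)
  list(normal = normal, dyad = dyad, center = ctr / 10,  # Angstrom -> nm
       report = sprintf(
         "frame from %d phosphate atoms; normal variance fraction %.3g; sign %s",
         nrow(P), ev$values[3] / sum(ev$values),
         if (is.null(refpt)) "arbitrary" else "fixed by reference selection"))
}
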