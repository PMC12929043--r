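# Synthetic-data generators with known ground truth for every pipeline
# stage: fibers, packed condensates, random baths, coarse-grained frames,
# trapped-bead and single-particle trajectories.  Generators are statistical
# stand-ins for tomographic and trajectory data, not molecular dynamics.

#' Generate a synthetic nucleosome fiber
#'
#' Two fiber families mirroring short-linker versus long-linker chromatin:
#' \describe{
#'   \item{`bp25_like`}{Heterogeneous zig-zag fiber (no N:N+2 stacking).
#'     Mean adjacent dihedral alpha = 230 degrees at low salt, 200 at high
#'     salt, with wrapped-normal noise (SD default 25 degrees); N:N+2 plane
#'     angle para = 45 degrees (low salt) or 30 (high salt).}
#'   \item{`bp30_like`}{Two-start helical fiber with face-to-face N:N+2
#'     stacking at a 6 nm disc-height rise, alpha = 50 degrees at low salt,
#'     80 at high salt, with small orientation (tilt) noise, SD default 8
#'     degrees.}
#' }
#' The two low-salt defaults differ in alpha by close to 180 degrees,
#' reflecting the phasing imposed by the ~10 bp/turn helical pitch of the
#' linker DNA.
#'
#' @param kind `"bp25_like"` or `"bp30_like"`.
#' @param n Number of nucleosomes (default 12; dodecameric arrays).
#' @param salt_regime `"low"` or `"high"`.
#' @param seed Integer seed (mandatory for noisy output), or `NULL` for the
#'   noiseless idealized fiber.
#' @param ... Overrides passed to the underlying builder parameters.
#' @return A `fiber` with attribute `truth` recording the generator
#'   configuration.
#' @export
gen_fiber <- function(kind = c("bp25_like", "bp30_like"), n = 12,
                      salt_regime = c("low", "high"), seed = NULL, ...) {
  kind <- match.arg(kind)
  salt_regime <- match.arg(salt_regime)
  stopifnot(n >= 3)
  dots <- list(...)
  if (kind == "bp25_like") {
    params <- utils::modifyList(list(
      alpha_deg = if (salt_regime == "low") 230 else 200,
      para_deg = if (salt_regime == "low") 45 else 30,
      d_adj_nm = 10,
      alpha_sd_deg = if (is.null(seed)) 0 else 25,
      d_sd_nm = if (is.null(seed)) 0 else 0.5,
      para_sd_deg = if (is.null(seed)) 0 else 5,
      linker_bp = 25L, fiber_id = "bp25_like"), dots)
    # orientation noise wedges the sharp-edged disc model at touching
    # interfaces; noisy builds therefore use a looser steric tolerance
    f <- build_ideal_fiber("zigzag", n, params, seed = seed,
                           steric_tol_nm = if (is.null(seed)) 1 else 3.5)
  } else {
    params <- utils::modifyList(list(
      alpha_deg = if (salt_regime == "low") 50 else 80,
      rise_nm = 6,
      tilt_sd_deg = if (is.null(seed)) 0 else 8,
      linker_bp = 30L, fiber_id = "bp30_like"), dots)
    f <- build_ideal_fiber("two_start", n, params, seed = seed,
                           steric_tol_nm = if (is.null(seed)) 1 else 3.5)
  }
  tr <- attr(f, "truth")
  attr(f, "truth") <- c(tr, list(kind = kind, salt_regime = salt_regime))
  f
}

#' Generate a synthetic chromatin condensate
#'
#' Fibers are generated, rotated randomly, placed on a jittered cubic
#' lattice inside a cubic box sized for the target density, and relaxed by
#' rigid pairwise push-apart sweeps until no inter-fiber nucleosome pair is
#' closer than `min_sep_nm`.  All pose centers remain inside the box, so the
#' achieved number density matches the target.
#'
#' @param fiber_kind Passed to [gen_fiber()].
#' @param n_fibers Number of fibers (ignored if `box_nm` given and
#'   `n_fibers` is `NULL`).
#' @param target_density Nucleosomes per cubic micrometer (default 6e5, the
#'   density scale of dense nuclear chromatin foci).
#' @param box_nm Optional cubic box side, nm; derived from `n_fibers` and
#'   `target_density` when `NULL`.
#' @param seed Integer seed (mandatory).
#' @param salt_regime Passed to [gen_fiber()].
#' @param fiber_length Nucleosomes per fiber (default 12).
#' @param min_sep_nm Minimal allowed inter-fiber center distance (default
#'   6 nm, the disc height).
#' @param max_sweeps Relaxation sweep budget.
#' @param ... Extra fiber parameters for [gen_fiber()].
#' @return A `condensate_model` with array assignments, sequence indices, a
#'   cubic `box_mask`, and attribute `truth`.
#' @export
gen_condensate <- function(fiber_kind = "bp30_like", n_fibers = 200,
                           target_density = 6e5, box_nm = NULL, seed = 1,
                           salt_regime = "high", fiber_length = 12,
                           min_sep_nm = 6, max_sweeps = 200, ...) {
  if (is.null(box_nm)) {
    box_nm <- (n_fibers * fiber_length / target_density * 1e9)^(1 / 3)
  } else if (is.null(n_fibers)) {
    n_fibers <- round(target_density * box_nm^3 / 1e9 / fiber_length)
  }
  n_pose <- n_fibers * fiber_length
  disc_vol <- pi * .NUC_RADIUS^2 * .NUC_HEIGHT
  phi <- n_pose * disc_vol / box_nm^3
  if (phi > 0.45)
    stop(sprintf("implied volume fraction %.0f%% exceeds 45%%", 100 * phi))
  with_seed(seed, {
    # near-cubic lattice with minimal slot excess; unused slots are dropped
    # at random so no systematic void larger than one cell can form
    base <- floor(n_fibers^(1 / 3))
    best <- NULL
    for (nx in base:(base + 2)) for (ny in base:(base + 2))
      for (nz in base:(base + 2)) {
        if (nx * ny * nz < n_fibers) next
        if (is.null(best) || nx * ny * nz < prod(best)) best <- c(nx, ny, nz)
      }
    grid3 <- as.matrix(expand.grid(seq_len(best[1]), seq_len(best[2]),
                                   seq_len(best[3])))
    cell3 <- box_nm / best
    slots <- grid3[sample.int(nrow(grid3), n_fibers), , drop = FALSE]
    slots <- sweep(sweep(slots, 2, 0.5), 2, cell3, "*")
    slots <- slots + matrix(runif(3 * n_fibers, -0.2, 0.2), n_fibers, 3) *
      matrix(cell3, n_fibers, 3, byrow = TRUE)
    centers <- NULL; normals <- NULL; dyads <- NULL
    array_of <- integer(0); seq_index <- integer(0)
    for (k in seq_len(n_fibers)) {
      f <- gen_fiber(fiber_kind, n = fiber_length, salt_regime = salt_regime,
                     seed = sample.int(.Machine$integer.max, 1), ...)
      R <- quat_to_matrix(random_quaternions(1)[1, ])
      ctr <- f$centers - matrix(colMeans(f$centers), fiber_length, 3,
                                byrow = TRUE)
      ctr <- t(R %*% t(ctr)) + matrix(slots[k, ], fiber_length, 3,
                                      byrow = TRUE)
      centers <- rbind(centers, ctr)
      normals <- rbind(normals, t(R %*% t(f$normals)))
      dyads <- rbind(dyads, t(R %*% t(f$dyads)))
      array_of <- c(array_of, rep(k, fiber_length))
      seq_index <- c(seq_index, seq_len(fiber_length))
    }
    # fibers may overhang the generation volume like a region sampled from
    # bulk; only their slot centroids are confined
    overhang <- 16
    rex <- cpp_relax_fibers(centers, as.integer(array_of - 1L),
                            rep(-overhang, 3), rep(box_nm + overhang, 3),
                            min_sep_nm, max_sweeps,
                            anchors = slots, anchor_gain = 0.1)
    centers <- rex$pos
    if (is.finite(rex$worst_dist) && rex$worst_dist < 0.5 * min_sep_nm)
      stop(sprintf(
        "overlap relaxation failed (worst inter-fiber distance %.2f nm after %d sweeps; achieved density %.3g /um^3)",
        rex$worst_dist, rex$sweeps, n_pose / box_nm^3 * 1e9))
    ids <- seq_len(n_pose)
    ao <- array_of; names(ao) <- as.character(ids)
    m <- condensate_model(centers, normals, dyads, ids = ids, array_of = ao,
                          seq_index = seq_index,
                          mask = box_mask(c(0, 0, 0), rep(box_nm, 3)),
                          density_target = target_density)
    attr(m, "truth") <- list(fiber_kind = fiber_kind, n_fibers = n_fibers,
                             fiber_length = fiber_length,
                             target_density = target_density,
                             box_nm = box_nm, seed = seed,
                             salt_regime = salt_regime,
                             relax_sweeps = rex$sweeps,
                             worst_inter_fiber_nm = rex$worst_dist)
    m
  })
}

# ---- coarse-grained frame generator ----------------------------------------

.tail_lengths <- c("tail-H3" = 38, "tail-H4" = 25, "tail-H2A(N)" = 13,
                   "tail-H2B" = 27)

# beads of one rigid nucleosome template (Angstrom, local frame: normal = +z)
.nucleosome_template <- function(n_dna = 147, n_core = 60) {
  # DNA: 1.65-turn superhelix, radius 41.8 A, pitch 23.9 A
  s <- seq(0, 1.65 * 2 * pi, length.out = n_dna)
  dna <- cbind(41.8 * cos(s), 41.8 * sin(s), 23.9 * (s / (2 * pi)) -
                 23.9 * 1.65 / 2)
  # core: beads on an inner cylinder r = 30 A, |z| <= 20 A
  ang <- seq(0, 2 * pi, length.out = n_core + 1)[-1]
  core <- cbind(30 * cos(ang), 30 * sin(ang),
                rep(seq(-20, 20, length.out = 5), length.out = n_core))
  # tail anchor points on the two faces / sides (one copy per tail role here)
  anchors <- rbind(
    "tail-H3" = c(35, 0, -28), "tail-H4" = c(0, 35, 28),
    "tail-H2A(N)" = c(-35, 0, 28), "tail-H2B" = c(0, -35, -28))
  list(dna = dna, core = core, anchors = anchors)
}

# anchored biased self-avoiding walk, step 3.8 A
.grow_tail <- function(anchor, n_res, target = NULL, bias = 0.7,
                       min_sep = 3.5, max_retry = 30) {
  pts <- matrix(0, n_res, 3)
  pts[1, ] <- anchor
  for (i in seq_len(n_res - 1)) {
    for (try in seq_len(max_retry)) {
      dir <- .unit(rnorm(3))
      if (!is.null(target)) {
        pull <- target - pts[i, ]
        if (sqrt(sum(pull^2)) > 1e-6)
          dir <- .unit(bias * .unit(pull) + (1 - bias) * dir)
      }
      cand <- pts[i, ] + 3.8 * dir
      prev <- pts[seq_len(max(1, i - 1)), , drop = FALSE]
      if (i == 1 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep)
        break
    }
    pts[i + 1, ] <- cand
  }
  pts
}

#' Generate coarse-grained frames with constructed tail contacts
#'
#' Builds residue-resolution bead frames for a small nucleosome cluster:
#' DNA beads on a superhelical path, core beads on an inner cylinder, and
#' histone tails as anchored biased self-avoiding walks (3.8 Angstrom
#' steps).  Tail walks can be biased toward the partner nucleosome face
#' (emulating stacking-bridging tails) or toward their own DNA (emulating
#' the low-salt regime of almost exclusively intra-nucleosome tail
#' contacts).  Ground-truth contact counts are recorded per frame with a
#' quadratic reference scan.
#'
#' @param layout A `fiber`, a `condensate_model`, or a list with `centers`
#'   (n x 2+ poses) and `normals`; default: a face-to-face dinucleosome at a
#'   6 nm rise.
#' @param tail_plan Named list per tail role with elements `target`
#'   (`"partner-face"`, `"own-dna"` or `"none"`) and `bias` in \[0, 1\].
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory).
#' @param array_of Optional array id per nucleosome (default all 1).
#' @param cutoff Contact cutoff recorded in the ground truth, Angstrom.
#' @return List of `cg_frame`s with attribute `truth` (per-frame scope
#'   totals computed by brute force).
#' @export
gen_cg_frames <- function(layout = NULL, tail_plan = NULL, n_frames = 5,
                          seed = 1, array_of = NULL, cutoff = 7.0) {
  if (is.null(layout)) {
    layout <- list(centers = rbind(c(0, 0, 0), c(0, 0, 6)),
                   normals = rbind(c(0, 0, 1), c(0, 0, 1)))
  }
  if (inherits(layout, "fiber") || inherits(layout, "condensate_model"))
    layout <- list(centers = layout$centers, normals = layout$normals)
  centers <- as.matrix(layout$centers) * 10  # nm -> Angstrom
  normals <- as.matrix(layout$normals)
  n_nuc <- nrow(centers)
  if (is.null(array_of)) array_of <- rep(1L, n_nuc)
  default_plan <- list(
    "tail-H3" = list(target = "own-dna", bias = 0.6),
    "tail-H4" = list(target = "partner-face", bias = 0.7),
    "tail-H2A(N)" = list(target = "none", bias = 0),
    "tail-H2B" = list(target = "none", bias = 0))
  tail_plan <- utils::modifyList(default_plan, tail_plan %||% list())
  tmpl <- .nucleosome_template()
  frame_mats <- lapply(seq_len(n_nuc), function(i) {
    nv <- .unit(normals[i, ])
    ref <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    dx <- .unit(.cross(ref, nv))
    cbind(dx, .cross(nv, dx), nv)
  })
  nearest_partner <- vapply(seq_len(n_nuc), function(i) {
    if (n_nuc == 1) return(NA_integer_)
    d <- sqrt(rowSums(sweep(centers, 2, centers[i, ])^2))
    d[i] <- Inf
    which.min(d)
  }, 1L)
  with_seed(seed, {
    frames <- vector("list", n_frames)
    truth <- NULL
    for (fr in seq_len(n_frames)) {
      rows <- NULL
      for (i in seq_len(n_nuc)) {
        M <- frame_mats[[i]]
        place <- function(local) t(M %*% t(local)) +
          matrix(centers[i, ], nrow(local), 3, byrow = TRUE)
        dna <- place(tmpl$dna)
        core <- place(tmpl$core)
        rows <- rbind(rows,
          data.frame(chain_id = sprintf("N%d_DNA", i),
                     residue_index = seq_len(nrow(dna)),
                     residue_name = "DA", role = "DNA",
                     nucleosome_id = i, array_id = array_of[i],
                     x = dna[, 1], y = dna[, 2], z = dna[, 3]),
          data.frame(chain_id = sprintf("N%d_core", i),
                     residue_index = seq_len(nrow(core)),
                     residue_name = "ALA", role = "histone-core",
                     nucleosome_id = i, array_id = array_of[i],
                     x = core[, 1], y = core[, 2], z = core[, 3]))
        for (role in names(.tail_lengths)) {
          plan <- tail_plan[[role]]
          anchor <- place(tmpl$anchors[role, , drop = FALSE])[1, ]
          target <- switch(plan$target,
            "partner-face" = if (is.na(nearest_partner[i])) NULL else {
              j <- nearest_partner[i]
              # center of the partner face nearest to this nucleosome
              sgn <- sign(sum((centers[i, ] - centers[j, ]) * normals[j, ]))
              centers[j, ] + sgn * 30 * .unit(normals[j, ])
            },
            "own-dna" = dna[round(nrow(dna) / 2), ],
            "none" = NULL)
          tl <- .grow_tail(anchor, .tail_lengths[[role]], target,
                           bias = plan$bias)
          rows <- rbind(rows,
            data.frame(chain_id = sprintf("N%d_%s", i, role),
                       residue_index = seq_len(nrow(tl)),
                       residue_name = "LYS", role = role,
                       nucleosome_id = i, array_id = array_of[i],
                       x = tl[, 1], y = tl[, 2], z = tl[, 3]))
        }
      }
      f <- cg_frame(rows)
      frames[[fr]] <- f
      # ground truth by brute-force quadratic scan (independent of the
      # cell-list path used by count_contacts)
      truth <- rbind(truth, .brute_scope_totals(f, cutoff, frame = fr))
    }
    attr(frames, "truth") <- truth
    frames
  })
}

# quadratic reference scan of scope totals for one frame
.brute_scope_totals <- function(f, cutoff, frame = 1L) {
  xyz <- as.matrix(f[, c("x", "y", "z")])
  n <- nrow(xyz)
  tot <- c("intra-nucleosome" = 0L, "intra-array" = 0L, "inter-array" = 0L)
  d2max <- cutoff^2
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])^2)
    js <- which(d2 <= d2max) + i
    for (j in js) {
      if (f$chain_id[i] == f$chain_id[j] &&
          abs(f$residue_index[i] - f$residue_index[j]) <= 2) next
      s <- if (f$nucleosome_id[i] == f$nucleosome_id[j]) "intra-nucleosome"
      else if (f$array_id[i] == f$array_id[j]) "intra-array"
      else "inter-array"
      tot[s] <- tot[s] + 1L
    }
  }
  data.frame(frame = frame, scope = names(tot), count = as.integer(tot))
}

# ---- trapped-bead generator -------------------------------------------------

#' Simulate a trapped bead in a model viscoelastic medium
#'
#' Overdamped Langevin dynamics of an optically trapped bead.  Newtonian and
#' Kelvin-Voigt media reduce to an exactly discretized Ornstein-Uhlenbeck
#' process (the medium spring adds to the trap stiffness); a Maxwell medium
#' uses an auxiliary-variable scheme (spring in series with a dashpot, each
#' dissipative element receiving its own fluctuation-dissipation-balanced
#' noise) integrated with substeps, plus a small solvent viscosity for
#' well-posedness.
#'
#' @param material List: `list(type = "newtonian", eta)` (Pa s),
#'   `list(type = "kelvin_voigt", G0, eta)`, or
#'   `list(type = "maxwell", G0, lambda)` (Pa, s).
#' @param kappa Trap stiffness, N/m.
#' @param a_um Bead radius, micrometers.
#' @param temperature_K Temperature, kelvin.
#' @param dt Sampling interval, seconds.
#' @param n Number of samples.
#' @param seed Integer seed (mandatory).
#' @param axes Number of independent axes simulated (default 2).
#' @param eta_solvent Solvent viscosity for the Maxwell scheme, Pa s;
#'   default 1% of the Maxwell viscosity `G0 * lambda`.
#' @return A `bead_trajectory` (positions nm) with attribute `truth`.
#' @export
gen_trapped_bead <- function(material, kappa, a_um, temperature_K = 298,
                             dt, n, seed, axes = 2, eta_solvent = NULL) {
  stopifnot(is.list(material), !is.null(material$type), kappa > 0, dt > 0)
  a_m <- a_um * 1e-6
  kT <- .kB * temperature_K
  pos <- with_seed(seed, switch(material$type,
    newtonian = ,
    kelvin_voigt = {
      eta <- material$eta
      k_med <- if (material$type == "kelvin_voigt") 6 * pi * a_m * material$G0 else 0
      gamma <- 6 * pi * eta * a_m
      if (dt * kappa / gamma >= 0.1)
        stop("unstable parameters: dt * kappa / gamma must be below 0.1")
      k_eff <- kappa + k_med
      tc <- gamma / k_eff
      sd_eq <- sqrt(kT / k_eff) * 1e9  # m -> nm
      ar <- exp(-dt / tc)
      sd_step <- sd_eq * sqrt(1 - ar^2)
      vapply(seq_len(axes), function(ax) {
        x <- numeric(n)
        x[1] <- rnorm(1, 0, sd_eq)
        innov <- rnorm(n - 1, 0, sd_step)
        for (i in seq_len(n - 1)) x[i + 1] <- ar * x[i] + innov[i]
        x
      }, numeric(n))
    },
    maxwell = {
      G0 <- material$G0; lambda <- material$lambda
      k_m <- 6 * pi * a_m * G0
      c_m <- k_m * lambda
      eta_s <- eta_solvent %||% (0.01 * G0 * lambda)
      gamma_s <- 6 * pi * eta_s * a_m
      if (dt * kappa / gamma_s >= 0.1 * 20)
        stop("unstable parameters for the Maxwell scheme")
      nsub <- 20
      h <- dt / nsub
      sx <- sqrt(2 * kT * gamma_s / h)
      sy <- sqrt(2 * kT * c_m / h)
      vapply(seq_len(axes), function(ax) {
        x <- 0; y <- 0
        out <- numeric(n)
        for (i in seq_len(n)) {
          for (s in seq_len(nsub)) {
            fx <- -kappa * x - k_m * (x - y) + rnorm(1, 0, sx)
            fy <- k_m * (x - y) + rnorm(1, 0, sy)
            x <- x + h * fx / gamma_s
            y <- y + h * fy / c_m
          }
          out[i] <- x
        }
        out * 1e9
      }, numeric(n))
    },
    stop("unknown material type: ", material$type)))
  tr <- bead_trajectory(pos, dt, a_um, temperature_K, kappa = kappa)
  attr(tr, "truth") <- c(material, list(kappa = kappa, a_um = a_um,
                                        temperature_K = temperature_K,
                                        dt = dt, n = n, seed = seed))
  tr
}

# ---- single-particle tracking generator ------------------------------------

#' Simulate single-particle tracking trajectories
#'
#' Free or confined 2-D diffusion: Gaussian steps of variance 2 D dt per
#' axis; in confined mode positions are reflected at a circular boundary of
#' radius R around each track's origin.  Localization noise is added
#' i.i.d. per frame.
#'
#' @param D Diffusion coefficient, square micrometers per second.
#' @param model `list(type = "free")` or `list(type = "confined", R = ...)`
#'   (R in micrometers).
#' @param dt Frame interval, seconds.
#' @param n_tracks Number of tracks.
#' @param steps Steps per track (track length is `steps + 1` points).
#' @param localization_sd Localization error SD, micrometers.
#' @param seed Integer seed (mandatory).
#' @return List of `trajectory` objects with attribute `truth`.
#' @export
gen_spt <- function(D, model = list(type = "free"), dt = 0.02,
                    n_tracks = 100, steps = 20, localization_sd = 0,
                    seed = 1) {
  stopifnot(D > 0, dt > 0, steps >= 1)
  step_sd <- sqrt(2 * D * dt)
  if (identical(model$type, "confined")) {
    if (is.null(model$R)) stop("confined model needs a radius R")
    if (model$R < step_sd / 10)
      warning("confinement radius is far below the step scale")
  }
  out <- with_seed(seed, {
    lapply(seq_len(n_tracks), function(tk) {
      x <- matrix(0, steps + 1, 2)
      for (i in seq_len(steps)) {
        cand <- x[i, ] + rnorm(2, 0, step_sd)
        if (identical(model$type, "confined")) {
          rr <- sqrt(sum(cand^2))
          if (rr > model$R) cand <- cand * (2 * model$R - rr) / rr
        }
        x[i + 1, ] <- cand
      }
      if (localization_sd > 0)
        x <- x + matrix(rnorm(2 * (steps + 1), 0, localization_sd),
                        steps + 1, 2)
      trajectory(x, dt, track_id = tk, localization_sd = localization_sd)
    })
  })
  attr(out, "truth") <- list(D = D, model = model, dt = dt,
                             n_tracks = n_tracks, steps = steps,
                             localization_sd = localization_sd, seed = seed)
  out
}
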