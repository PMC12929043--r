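# Single-molecule trajectory statistics: diffusion coefficients from
# ensemble MSD fits, jump-angle distributions, and the asymmetry
# coefficient quantifying forward/backward bias.

#' Construct a single-particle trajectory
#'
#' @param positions n x d matrix of positions, micrometers (d = 2 or 3).
#' @param dt Frame interval, seconds.
#' @param frames Integer frame indices (strictly increasing); default
#'   `1:n`.
#' @param track_id Identifier.
#' @param localization_sd Optional localization error SD, micrometers.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(positions, dt, frames = NULL, track_id = 1L,
                       localization_sd = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(frames)) frames <- seq_len(n)
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  stopifnot(dt > 0, length(frames) == n)
  structure(list(positions = positions, dt = dt, frames = as.integer(frames),
                 track_id = track_id, localization_sd = localization_sd),
            class = "trajectory")
}

# split a trajectory at frame gaps; returns a list of gap-free trajectories
split_at_gaps <- function(tr) {
  gaps <- which(diff(tr$frames) != 1)
  if (!length(gaps)) return(list(tr))
  bounds <- c(0, gaps, length(tr$frames))
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    if (length(idx) >= 2)
      out[[length(out) + 1]] <- trajectory(tr$positions[idx, , drop = FALSE],
                                           tr$dt, tr$frames[idx],
                                           track_id = tr$track_id)
  }
  out
}

#' Ensemble diffusion coefficient from single-particle tracks
#'
#' Ensemble-averaged time-averaged MSD over all tracks, fitted over lags
#' `1..fit_points` with the weighted linear model
#' \eqn{\mathrm{MSD}(n\Delta t) = 4 D n\Delta t + b} (2-D; the offset b
#' absorbs localization error).  Confidence interval by bootstrap over
#' tracks.  Tracks with frame gaps are split at the gaps.
#'
#' @param trajs List of `trajectory` objects (2-D positions).
#' @param fit_points Number of MSD points fitted (2 to 5; default 3).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List with `D_um2_s`, `ci`, `intercept_um2`, `msd`
#'   (lag table), `n_tracks`, `n_split`.
#' @export
diffusion_coefficient <- function(trajs, fit_points = 3, n_boot = 1000,
                                  conf = 0.95, seed = 1) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (fit_points < 2 || fit_points > 5)
    stop("fit_points must be between 2 and 5")
  pieces <- unlist(lapply(trajs, split_at_gaps), recursive = FALSE)
  n_split <- length(pieces) - length(trajs)
  pieces <- Filter(function(p) nrow(p$positions) >= 5, pieces)
  if (!length(pieces)) stop("no track with at least 5 points")
  dt <- pieces[[1]]$dt
  # per-track sums of squared displacements and counts at each lag
  sums <- vapply(pieces, function(p) {
    x <- p$positions
    vapply(seq_len(fit_points), function(lag) {
      if (nrow(x) <= lag) return(c(0, 0))
      d2 <- rowSums((x[-seq_len(lag), , drop = FALSE] -
                     x[seq_len(nrow(x) - lag), , drop = FALSE])^2)
      c(sum(d2), length(d2))
    }, numeric(2))
  }, matrix(0, 2, fit_points))
  sums <- array(sums, dim = c(2, fit_points, length(pieces)))
  fit_D <- function(idx) {
    s <- apply(sums[, , idx, drop = FALSE], c(1, 2), sum)
    m <- s[1, ] / s[2, ]
    tau <- seq_len(fit_points) * dt
    ft <- lm(m ~ tau, weights = s[2, ])
    coef(ft)
  }
  cf <- fit_D(seq_along(pieces))
  D <- unname(cf[2]) / 4
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(pieces), replace = TRUE)
      unname(fit_D(idx)[2]) / 4
    }, 0)
  })
  alpha <- (1 - conf) / 2
  s <- apply(sums, c(1, 2), sum)
  list(D_um2_s = D,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       intercept_um2 = unname(cf[1]),
       msd = data.frame(lag = seq_len(fit_points),
                        tau_s = seq_len(fit_points) * dt,
                        msd_um2 = s[1, ] / s[2, ], n_obs = s[2, ]),
       n_tracks = length(pieces), n_split = n_split)
}

#' Jump angles of a trajectory
#'
#' For every pair of consecutive displacements, the angle between them in
#' degrees: 0 is directed motion, 180 back-and-forth movement.  Steps
#' shorter than `min_step` (and zero-length steps) are excluded.
#'
#' @param traj A `trajectory` or a list of them.
#' @param min_step Minimal step length, micrometers.
#' @return Numeric vector of angles in \[0, 180\], with attribute
#'   `n_excluded`.
#' @export
jump_angles <- function(traj, min_step = 0) {
  trs <- if (inherits(traj, "trajectory")) list(traj) else traj
  angles <- numeric(0); excl <- 0L
  for (tr in trs) {
    x <- tr$positions
    if (nrow(x) < 3) next
    steps <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
    len <- sqrt(rowSums(steps^2))
    for (i in seq_len(nrow(steps) - 1)) {
      if (len[i] <= min_step || len[i + 1] <= min_step ||
          len[i] == 0 || len[i + 1] == 0) {
        excl <- excl + 1L
        next
      }
      cosang <- sum(steps[i, ] * steps[i + 1, ]) / (len[i] * len[i + 1])
      angles <- c(angles, acos(max(-1, min(1, cosang))) * 180 / pi)
    }
  }
  attr(angles, "n_excluded") <- excl
  angles
}

#' Asymmetry coefficient of a jump-angle distribution
#'
#' \eqn{AC = \log_2(f_{fwd} / f_{bwd})} with the forward fraction taken on
#' \[0, 30\] degrees and the backward fraction on \[150, 180\] degrees
#' (configurable windows).  Negative values indicate backward-biased
#' (confined) motion.
#'
#' @param angles Numeric vector of jump angles, degrees.
#' @param fwd_window,bwd_window Numeric 2-vectors, degrees.
#' @return List with `ac`, `f_fwd`, `f_bwd`, `n`.
#' @export
asymmetry_coefficient <- function(angles, fwd_window = c(0, 30),
                                  bwd_window = c(150, 180)) {
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n == 0) stop("no angles supplied")
  if (n < 100) warning("fewer than 100 angles; AC will be noisy")
  f_fwd <- mean(angles >= fwd_window[1] & angles <= fwd_window[2])
  f_bwd <- mean(angles >= bwd_window[1] & angles <= bwd_window[2])
  if (f_fwd == 0 && f_bwd == 0)
    stop("no angles fall in either window; AC undefined")
  ac <- log2(f_fwd / f_bwd)
  if (!is.finite(ac))
    warning("one window is empty; AC is infinite")
  list(ac = ac, f_fwd = f_fwd, f_bwd = f_bwd, n = n)
}

#' Naive nearest-neighbour track linker
#'
#' Convenience plumbing for localization tables: links detections in
#' consecutive frames to their nearest neighbour within `max_disp`.  Not a
#' validated tracking algorithm; intended for well-separated sparse
#' emitters only.
#'
#' @param detections Data.frame with columns `frame`, `x_um`, `y_um`.
#' @param dt Frame interval, seconds.
#' @param max_disp Maximal displacement per frame, micrometers.
#' @return List of `trajectory` objects.
#' @export
link_tracks <- function(detections, dt, max_disp) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  active <- list()  # each: list(points = matrix, frames = int vector)
  done <- list()
  prev_frame <- NULL
  for (fr in frames) {
    pts <- as.matrix(detections[detections$frame == fr, c("x_um", "y_um")])
    assigned <- rep(FALSE, nrow(pts))
    if (length(active) && !is.null(prev_frame) && fr == prev_frame + 1) {
      for (ai in seq_along(active)) {
        last <- active[[ai]]$points[nrow(active[[ai]]$points), ]
        d <- sqrt(colSums((t(pts) - last)^2))
        d[assigned] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= max_disp) {
          active[[ai]]$points <- rbind(active[[ai]]$points, pts[j, ])
          active[[ai]]$frames <- c(active[[ai]]$frames, fr)
          assigned[j] <- TRUE
        }
      }
    }
    ended <- vapply(active, function(a) a$frames[length(a$frames)] != fr, TRUE)
    done <- c(done, active[ended])
    active <- active[!ended]
    for (j in which(!assigned))
      active[[length(active) + 1]] <- list(points = pts[j, , drop = FALSE],
                                           frames = fr)
    prev_frame <- fr
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= 2, done)
  lapply(seq_along(done), function(k)
    trajectory(done[[k]]$points, dt, done[[k]]$frames, track_id = k))
}
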