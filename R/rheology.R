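# Passive microrheology with optical traps: from a trapped-bead trajectory
# to the complex shear modulus G*(omega) via the trap-corrected generalized
# Stokes-Einstein relation, plus stress-autocorrelation relaxation moduli.

#' Construct a trapped-bead trajectory
#'
#' @param positions n x d matrix (d = 1..3) of bead positions, nm.
#' @param dt Sampling interval, seconds (uniform).
#' @param bead_radius_um Bead radius in micrometers (mandatory for moduli).
#' @param temperature_K Temperature, kelvin.
#' @param kappa Trap stiffness per axis, N/m (optional; estimable via
#'   [trap_stiffness()]).
#' @return Object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(positions, dt, bead_radius_um,
                            temperature_K = 298, kappa = NULL) {
  positions <- as.matrix(positions)
  stopifnot(dt > 0, bead_radius_um > 0, temperature_K > 0)
  structure(list(positions = positions, dt = dt,
                 bead_radius_um = bead_radius_um,
                 temperature_K = temperature_K, kappa = kappa),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("trapped-bead trajectory: %d samples x %d axes, dt %.2e s, a = %.2f um\n",
              nrow(x$positions), ncol(x$positions), x$dt, x$bead_radius_um))
  invisible(x)
}

# FFT-based time-averaged MSD of one coordinate (all lags 1..max_lag)
.msd_fft_1d <- function(x, max_lag) {
  n <- length(x)
  D <- x^2
  # S2: autocorrelation sum_t x_t x_{t+k} via zero-padded FFT
  nfft <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nfft - n)))
  s2 <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:n] / nfft
  # S1 recursion: S1(k) = S1(k-1) - x_{k}^2 - x_{n+1-k}^2 (1-based)
  s1 <- numeric(n)
  s1[1] <- 2 * sum(D)
  q <- 2 * sum(D)
  for (k in seq_len(n - 1)) {
    q <- q - D[k] - D[n + 1 - k]
    s1[k + 1] <- q
  }
  lags <- seq_len(max_lag)
  (s1[lags + 1] - 2 * s2[lags + 1]) / (n - lags)
}

#' Time-averaged mean-squared displacement
#'
#' Overlapping-window time average per axis and summed over axes.
#'
#' @param t A `bead_trajectory`, or an n x d position matrix with `dt`.
#' @param max_lag Largest lag in samples (default n/4).
#' @param dt Sampling interval when `t` is a bare matrix.
#' @return Data.frame with `lag`, `tau_s`, per-axis columns `msd_<k>` and
#'   the summed `msd` (squared position units).
#' @export
msd <- function(t, max_lag = NULL, dt = NULL) {
  if (inherits(t, "bead_trajectory")) {
    pos <- t$positions; dt <- t$dt
  } else {
    pos <- as.matrix(t)
    if (is.null(dt)) stop("dt is required for matrix input")
  }
  n <- nrow(pos)
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  if (max_lag >= n / 4 + 1) stop("max_lag must be below n/4")
  per_axis <- vapply(seq_len(ncol(pos)), function(k)
    .msd_fft_1d(pos[, k], max_lag), numeric(max_lag))
  per_axis <- matrix(per_axis, nrow = max_lag)
  colnames(per_axis) <- paste0("msd_", seq_len(ncol(pos)))
  out <- data.frame(lag = seq_len(max_lag), tau_s = seq_len(max_lag) * dt)
  out <- cbind(out, per_axis)
  out$msd <- rowSums(per_axis)
  out
}

#' Trap stiffness by equipartition
#'
#' kappa = kB T / Var(x) per axis.  Trajectories with substantial linear
#' drift are rejected (detrend first).
#'
#' @param t A `bead_trajectory` (positions in nm).
#' @param drift_tol Maximal allowed |drift over the record| / SD(x).
#' @return Named numeric vector of stiffnesses, N/m, one per axis.
#' @export
trap_stiffness <- function(t, drift_tol = 1.0) {
  stopifnot(inherits(t, "bead_trajectory"))
  pos <- t$positions
  tt <- seq_len(nrow(pos)) * t$dt
  kap <- vapply(seq_len(ncol(pos)), function(k) {
    x <- pos[, k]
    slope <- coef(lm(x ~ tt))[2]
    if (abs(slope) * (max(tt) - min(tt)) > drift_tol * sd(x))
      stop("trajectory axis ", k,
           " shows linear drift; detrend before estimating stiffness")
    .kB * t$temperature_K / (var(x) * 1e-18)  # nm^2 -> m^2
  }, 0)
  names(kap) <- paste0("axis_", seq_len(ncol(pos)))
  kap
}

#' Complex shear modulus from a trapped-bead trajectory
#'
#' Trap-corrected generalized Stokes-Einstein inversion: the normalized MSD
#' \eqn{\Pi(\tau) = \kappa\,\mathrm{MSD}(\tau) / (2 k_B T)} (per axis,
#' averaged over axes) is Fourier transformed exactly for its
#' piecewise-linear interpolant with a constant plateau beyond the last lag,
#' and \eqn{G^*(\omega) = \frac{\kappa}{6\pi a}\left(\frac{1}{i\omega
#' \hat\Pi(\omega)} - 1\right)}.  Frequencies are reported on a log-spaced
#' grid one decade inside the record-length and Nyquist limits; grid points
#' with negative moduli are trimmed.
#'
#' @param t A `bead_trajectory` with positions in nm, or a list of them
#'   (independent bead recordings): moduli are then averaged over the
#'   recordings, as in ensemble-averaged passive microrheology.
#' @param kappa Trap stiffness N/m (scalar or per axis); estimated by
#'   equipartition when `NULL`.
#' @param n_lags Number of log-spaced MSD lags used for the transform.
#' @param n_freq Number of frequency grid points.
#' @param spline_df Degrees of freedom of the log-log smoothing spline
#'   applied to the normalized MSD before the transform (`NULL` disables
#'   smoothing).
#' @return Data.frame of class `complex_modulus` with `freq_hz`,
#'   `G_prime_pa`, `G_double_prime_pa`.
#' @export
complex_modulus <- function(t, kappa = NULL, n_lags = 200, n_freq = 60,
                            spline_df = 12) {
  if (is.list(t) && !inherits(t, "bead_trajectory")) {
    # ensemble of independent recordings: average the raw moduli on the
    # common grid, then trim once
    parts <- lapply(t, .complex_modulus_raw, kappa = kappa, n_lags = n_lags,
                    n_freq = n_freq, spline_df = spline_df)
    freqs <- parts[[1]]$freq_hz
    for (p in parts[-1])
      if (!isTRUE(all.equal(p$freq_hz, freqs)))
        stop("recordings must share dt and length for ensemble averaging")
    out <- data.frame(
      freq_hz = freqs,
      G_prime_pa = rowMeans(vapply(parts, `[[`, freqs, "G_prime_pa")),
      G_double_prime_pa = rowMeans(vapply(parts, `[[`, freqs,
                                          "G_double_prime_pa")))
    out <- .trim_modulus(out)
    attr(out, "n_recordings") <- length(parts)
    return(out)
  }
  out <- .trim_modulus(.complex_modulus_raw(t, kappa, n_lags, n_freq,
                                            spline_df))
  out
}

.complex_modulus_raw <- function(t, kappa = NULL, n_lags = 200, n_freq = 60,
                                 spline_df = 12) {
  stopifnot(inherits(t, "bead_trajectory"))
  n <- nrow(t$positions)
  if (n < 1e4) stop("modulus estimation needs at least 1e4 samples")
  if (is.null(kappa)) kappa <- t$kappa
  if (is.null(kappa)) kappa <- trap_stiffness(t)
  kap <- mean(kappa)
  kT <- .kB * t$temperature_K
  max_lag <- floor(n / 4) - 1
  mm <- msd(t, max_lag = max_lag)
  # per-axis normalized MSD averaged over axes
  d <- ncol(t$positions)
  Pi_all <- sapply(seq_len(d), function(k)
    mm[[paste0("msd_", k)]] * 1e-18 * (if (length(kappa) == d) kappa[k] else kap) / (2 * kT))
  Pi_full <- rowMeans(matrix(Pi_all, nrow = nrow(mm)))
  # log-subsample the lag axis
  keep <- unique(round(exp(seq(log(1), log(max_lag), length.out = n_lags))))
  tau <- mm$tau_s[keep]; Pi <- Pi_full[keep]
  if (!is.null(spline_df) && length(tau) > 2 * spline_df && all(Pi > 0)) {
    # estimator-noise kinks in the interpolant feed the oscillatory
    # transform at high frequency; a stiff log-log smoothing spline removes
    # them while preserving the (slowly varying) physical curve
    ss <- stats::smooth.spline(log(tau), log(Pi), df = spline_df)
    fine <- unique(round(exp(seq(log(1), log(max_lag), length.out = 400))))
    tau <- fine * t$dt
    Pi <- exp(stats::predict(ss, log(tau))$y)
  }
  # piecewise-linear one-sided Fourier transform with plateau:
  # i*omega*Pi_hat = Pi(0) + sum_k b_k (e^{-i w t_{k-1}} - e^{-i w t_k})/(i w)
  tgrid <- c(0, tau); Pgrid <- c(0, Pi)
  b <- diff(Pgrid) / diff(tgrid)
  f_lo <- 10 / (n * t$dt); f_hi <- 1 / (10 * t$dt)
  if (f_hi <= f_lo) stop("record too short for a reliable frequency band")
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_freq))
  a_m <- t$bead_radius_um * 1e-6
  G <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    e <- exp(-1i * w * tgrid)
    iwPi <- sum(b * (e[-length(e)] - e[-1])) / (1i * w)
    gs <- kap / (6 * pi * a_m) * (1 / iwPi - 1)
    c(Re(gs), Im(gs))
  }, numeric(2))
  out <- data.frame(freq_hz = freqs, G_prime_pa = G[1, ],
                    G_double_prime_pa = G[2, ])
  attr(out, "kappa") <- kap
  out
}

# negative moduli are measurement noise; trimmed, never silently returned
.trim_modulus <- function(out) {
  neg <- out$G_double_prime_pa < 0 |
    (out$G_prime_pa < -0.02 * abs(out$G_double_prime_pa))
  if (any(neg)) out <- out[!neg, , drop = FALSE]
  out$G_prime_pa <- pmax(out$G_prime_pa, 0)
  class(out) <- c("complex_modulus", "data.frame")
  out
}

#' Zero-shear viscosity and moduli crossovers
#'
#' The zero-shear viscosity is the slope of G'' versus angular frequency
#' fitted over the lowest reliable decade where viscous behaviour dominates
#' (G'' > 3 G'); crossover frequencies are the sign changes of
#' log G' - log G'', located by log-log interpolation.
#'
#' @param G A `complex_modulus` covering at least two frequency decades.
#' @return List with `eta0_pa_s`, `eta0_is_lower_bound` flag and
#'   `crossover_hz` (possibly empty).
#' @export
viscosity_and_crossovers <- function(G) {
  stopifnot(inherits(G, "complex_modulus"))
  f <- G$freq_hz
  if (max(f) / min(f) < 99) stop("modulus must cover at least two decades")
  gp <- G$G_prime_pa; gpp <- G$G_double_prime_pa
  visc <- gpp > 3 * gp
  lower_bound <- FALSE
  sel <- visc & f <= min(f) * 10
  if (!any(sel)) {
    lower_bound <- TRUE
    sel <- f <= min(f) * 10
  }
  w <- 2 * pi * f[sel]
  eta0 <- sum(gpp[sel] * w) / sum(w^2)
  # crossovers
  ok <- gp > 0 & gpp > 0
  z <- log(gp[ok]) - log(gpp[ok])
  lf <- log(f[ok])
  cross <- c()
  if (length(z) > 1) {
    sc <- which(z[-1] * z[-length(z)] < 0)
    for (k in sc) {
      lx <- lf[k] + (0 - z[k]) * (lf[k + 1] - lf[k]) / (z[k + 1] - z[k])
      cross <- c(cross, exp(lx))
    }
  }
  list(eta0_pa_s = eta0, eta0_is_lower_bound = lower_bound,
       crossover_hz = cross)
}

#' Shear stress relaxation modulus from a stress time series
#'
#' \eqn{G(t) = \frac{V}{k_B T}\langle\sigma_{ab}(t_0)\sigma_{ab}(t_0+t)\rangle},
#' averaged over the supplied off-diagonal components and over time origins.
#'
#' @param stress n x m matrix of off-diagonal stress components, Pa.
#' @param dt Sampling interval, seconds.
#' @param volume_nm3 System volume in cubic nanometers.
#' @param temperature_K Temperature, kelvin.
#' @param max_lag Largest lag in samples; truncated (with a warning) so that
#'   at least 10 time origins contribute at the largest lag.
#' @return Data.frame with `t_s` and `G_pa`.
#' @export
stress_relaxation <- function(stress, dt, volume_nm3, temperature_K = 298,
                              max_lag = NULL) {
  stress <- as.matrix(stress)
  n <- nrow(stress)
  stopifnot(n > 10, dt > 0, volume_nm3 > 0)
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  if (n - max_lag < 10) {
    warning("truncating max_lag so at least 10 time origins remain")
    max_lag <- n - 10
  }
  nfft <- 2^ceiling(log2(2 * n))
  acfs <- vapply(seq_len(ncol(stress)), function(k) {
    x <- stress[, k]
    fx <- fft(c(x, rep(0, nfft - n)))
    s <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1)] / nfft
    s / (n - 0:max_lag)  # raw (non-centered) autocorrelation per origin
  }, numeric(max_lag + 1))
  acfs <- matrix(acfs, nrow = max_lag + 1)
  pref <- volume_nm3 * 1e-27 / (.kB * temperature_K)
  data.frame(t_s = (0:max_lag) * dt, G_pa = pref * rowMeans(acfs))
}
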