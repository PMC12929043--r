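# Trapped-bead microrheology: MSD estimation, trap calibration, the GSER
# modulus inversion and stress-relaxation moduli.

test_that("msd matches closed forms and the double-loop estimator", {
  # deterministic uniform motion: MSD = v^2 tau^2
  v <- 3
  x <- matrix(v * (1:2000) * 0.01)
  mm <- msd(x, max_lag = 100, dt = 0.01)
  expect_equal(mm$msd, (v * mm$tau_s)^2, tolerance = 1e-9)
  # i.i.d. positions: MSD = 2 sigma^2 for all lags
  set.seed(91)
  y <- matrix(rnorm(50000, sd = 2))
  my <- msd(y, max_lag = 50, dt = 1)
  expect_equal(my$msd, rep(8, 50), tolerance = 0.1)
  # brute-force double loop
  set.seed(92)
  z <- cumsum(rnorm(1000))
  mz <- msd(matrix(z), max_lag = 200, dt = 1)
  brute <- sapply(1:200, function(L)
    mean((z[(1 + L):1000] - z[1:(1000 - L)])^2))
  expect_equal(mz$msd, brute, tolerance = 1e-9)
  expect_error(msd(matrix(z), max_lag = 400, dt = 1), "n/4")
})

test_that("trap stiffness is recovered by equipartition", {
  # eta chosen so the correlation time is short against the record
  tb <- gen_trapped_bead(list(type = "newtonian", eta = 0.001),
                         kappa = 1e-5, a_um = 0.5, dt = 5e-5, n = 6e5,
                         seed = 93)
  kap <- trap_stiffness(tb)
  expect_equal(unname(kap), rep(1e-5, 2), tolerance = 0.03)
  # axes agree for isotropic input
  expect_lt(abs(kap[1] / kap[2] - 1), 0.05)
  # doubling the variance halves the stiffness estimate
  tb2 <- tb
  tb2$positions <- tb$positions * sqrt(2)
  expect_equal(unname(trap_stiffness(tb2)), unname(kap) / 2,
               tolerance = 1e-9)
  # drifting trajectories are rejected
  td <- tb
  td$positions[, 1] <- td$positions[, 1] +
    seq(0, 300, length.out = nrow(td$positions))
  expect_error(trap_stiffness(td), "drift")
})

test_that("a Newtonian medium returns G* = i omega eta", {
  recs <- lapply(1:3, function(s)
    gen_trapped_bead(list(type = "newtonian", eta = 1), kappa = 1e-5,
                     a_um = 0.5, dt = 1e-3, n = 2e5, seed = 100 + s))
  G <- complex_modulus(recs)
  f <- G$freq_hz
  mid <- sqrt(min(f) * max(f))
  sel <- f > mid / sqrt(10) & f < mid * sqrt(10)
  ratio <- G$G_double_prime_pa[sel] / (2 * pi * f[sel] * 1)
  expect_true(all(abs(ratio - 1) < 0.1))
  expect_true(all(G$G_prime_pa[sel] < 0.1 * G$G_double_prime_pa[sel]))
  # deterministic grid and trimming for fixed input
  G2 <- complex_modulus(recs)
  expect_identical(G, G2)
})

test_that("a Kelvin-Voigt medium shows the elastic plateau", {
  recs <- lapply(1:3, function(s)
    gen_trapped_bead(list(type = "kelvin_voigt", G0 = 1, eta = 0.3),
                     kappa = 1e-5, a_um = 0.5, dt = 1e-3, n = 2e5,
                     seed = 300 + s))
  G <- complex_modulus(recs)
  low <- G$freq_hz < min(G$freq_hz) * 4
  expect_true(all(abs(G$G_prime_pa[low] - 1) < 0.15))
})

test_that("zero-shear viscosity and crossovers match closed forms", {
  recs <- lapply(1:3, function(s)
    gen_trapped_bead(list(type = "newtonian", eta = 1), kappa = 1e-5,
                     a_um = 0.5, dt = 1e-3, n = 2e5, seed = 100 + s))
  G <- complex_modulus(recs)
  vc <- viscosity_and_crossovers(G)
  expect_equal(vc$eta0_pa_s, 1, tolerance = 0.1)
  expect_length(vc$crossover_hz, 0)
  # Maxwell fluid: single crossover at omega = 1/lambda
  lam <- 0.05
  mx <- lapply(1:3, function(s)
    gen_trapped_bead(list(type = "maxwell", G0 = 2, lambda = lam),
                     kappa = 1e-5, a_um = 0.5, dt = 1e-3, n = 2e5,
                     seed = 200 + s))
  Gm <- complex_modulus(mx)
  vcm <- viscosity_and_crossovers(Gm)
  expect_length(vcm$crossover_hz, 1)
  expect_equal(vcm$crossover_hz, 1 / (2 * pi * lam), tolerance = 0.15)
  # homogeneity: scaling the moduli doubles eta0 and fixes the crossovers
  G2 <- Gm
  G2$G_prime_pa <- 2 * G2$G_prime_pa
  G2$G_double_prime_pa <- 2 * G2$G_double_prime_pa
  vc2 <- viscosity_and_crossovers(G2)
  expect_equal(vc2$eta0_pa_s, 2 * vcm$eta0_pa_s, tolerance = 1e-9)
  expect_equal(vc2$crossover_hz, vcm$crossover_hz, tolerance = 1e-9)
})

test_that("eta0 is robust to subsampling the trajectory by two", {
  recs <- lapply(1:3, function(s)
    gen_trapped_bead(list(type = "newtonian", eta = 1), kappa = 1e-5,
                     a_um = 0.5, dt = 1e-3, n = 2e5, seed = 100 + s))
  sub <- lapply(recs, function(t) {
    bead_trajectory(t$positions[seq(1, nrow(t$positions), by = 2), ],
                    t$dt * 2, t$bead_radius_um, t$temperature_K, t$kappa)
  })
  e1 <- viscosity_and_crossovers(complex_modulus(recs))$eta0_pa_s
  e2 <- viscosity_and_crossovers(complex_modulus(sub))$eta0_pa_s
  expect_equal(e2 / e1, 1, tolerance = 0.15)
})

test_that("stress relaxation is the scaled stress autocorrelation", {
  kT <- 1.380649e-23 * 298
  # constant stress: G(t) = V sigma0^2 / kB T at every lag
  s0 <- matrix(2, 400, 1)
  gt <- stress_relaxation(s0, dt = 1, volume_nm3 = 1e6, max_lag = 30)
  expect_equal(gt$G_pa, rep(1e6 * 1e-27 * 4 / kT, 31), tolerance = 1e-9)
  # white noise decorrelates beyond lag zero
  set.seed(94)
  w <- matrix(rnorm(20000), ncol = 2)
  gw <- stress_relaxation(w, dt = 1, volume_nm3 = 1e6, max_lag = 50)
  expect_gt(gw$G_pa[1], 10 * max(abs(gw$G_pa[-1])))
  # brute-force double loop on a short series
  set.seed(95)
  x <- as.numeric(arima.sim(list(ar = 0.9), 500))
  gb <- stress_relaxation(matrix(x), dt = 0.1, volume_nm3 = 1e6,
                          max_lag = 60)
  brute <- sapply(0:60, function(L)
    mean(x[1:(500 - L)] * x[(1 + L):500]))
  expect_equal(gb$G_pa, 1e6 * 1e-27 / kT * brute, tolerance = 1e-9)
  # lag truncation keeps at least 10 time origins
  expect_warning(stress_relaxation(matrix(rnorm(40)), dt = 1,
                                   volume_nm3 = 1, max_lag = 35),
                 "origins")
})
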