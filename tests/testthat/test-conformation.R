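test_that("free-energy profiles recover known generating potentials", {
  ## uniform samples: flat profile within counting noise
  set.seed(1)
  u <- runif(2e5, -180, 180)
  pu <- free_energy_profile(u, bin_width = 5)
  expect_lt(max(pu$F, na.rm = TRUE), 6 * sqrt(360 / (2e5 * 5)))
  ## cosine double well, barrier 5 kBT at 1e6 samples: recovered to 0.2 kBT
  B <- 5
  U <- function(phi) B / 2 * (1 - cos(2 * phi * pi / 180))
  ang <- gen_boltzmann_angles(1e6, U, seed = 3)
  pr <- free_energy_profile(ang, bin_width = 2)
  i90 <- which.min(abs(pr$angle_grid - 89))
  expect_equal(pr$F[i90], B, tolerance = 0.2 / B)
  ## degenerate input: warning plus mostly empty, flagged bins
  expect_warning(p2 <- free_energy_profile(c(10, 20), bin_width = 2),
                 "noisy")
  expect_gt(sum(is.na(p2$F)), 150)
  expect_error(free_energy_profile(numeric(0)), "empty")
})

test_that("profile round-trips through Boltzmann resampling", {
  B <- 3
  U <- function(phi) B / 2 * (1 - cos(2 * phi * pi / 180))
  a1 <- gen_boltzmann_angles(4e5, U, seed = 5)
  p1 <- free_energy_profile(a1, bin_width = 5)
  ## resample from the estimated profile and re-estimate
  Uhat <- stats::approxfun(p1$angle_grid, p1$F, rule = 2)
  a2 <- gen_boltzmann_angles(4e5, Uhat, seed = 6)
  p2 <- free_energy_profile(a2, bin_width = 5)
  ok <- !is.na(p1$F) & !is.na(p2$F) & p1$counts > 50 & p2$counts > 50
  expect_lt(max(abs(p1$F[ok] - p2$F[ok])), 0.15)
})

test_that("helicity traces debounce recrossings and keep the tie rule", {
  ## constant positive dihedral
  h0 <- helicity_trace(rep(140, 100), dt = 2)
  expect_true(all(h0$theta == 1))
  expect_length(h0$flip_times, 0)
  ## square wave, 1 ps dwell, 100 fs debounce: a flip per alternation
  sq <- rep(rep(c(145, -145), 10), each = 500)
  hs <- helicity_trace(sq, dt = 2, debounce = 100)
  expect_length(hs$flip_times, 19)
  expect_true(all(abs(hs$dwell_times - 1000) < 1e-9))
  expect_true(all(diff(hs$flip_times) > 0))
  ## a 40 fs excursion is a recrossing, not a flip
  rc <- rep(145, 500); rc[200:220] <- -145
  hr <- helicity_trace(rc, dt = 2, debounce = 100)
  expect_length(hr$flip_times, 0)
  expect_true(all(hr$theta == 1))
  ## dihedral exactly 0/180 inherits the previous indicator
  tie <- c(145, 0, 180, -145)
  ht <- helicity_trace(tie, dt = 2, debounce = 0)
  expect_equal(ht$theta[1:3], c(1, 1, 1))
})

test_that("telegraph flip counts follow Poisson statistics", {
  k <- 0.5  # ps^-1, 100 ns of data
  tg <- sim_telegraph(5e6, 20, k, seed = 13)
  dih <- 145 * tg$theta
  ht <- helicity_trace(dih, dt = 20, debounce = 20)
  expected <- k * 5e6 * 20 / 1000
  expect_equal(length(ht$flip_times), expected, tolerance = 0.05)
})

test_that("helicity lifetimes recover the telegraph analytic value", {
  for (k in c(1 / (2 * 2.9), 1 / 3)) {
    tg <- sim_telegraph(2e6, 25, k, seed = 17)
    lt <- helicity_lifetime(tg$theta, dt = 25)
    expect_equal(lt$tau_integral_ps, 1 / (2 * k), tolerance = 0.05)
    expect_equal(lt$tau_expfit_ps, 1 / (2 * k), tolerance = 0.05)
    expect_false(lt$lower_bound)
    ## normalization and bounds of the ACF
    expect_equal(lt$C[1], 1)
    expect_true(all(lt$C <= 1 + 1e-9 & lt$C >= -1 - 1e-9))
  }
  ## constant indicator: lower-bound flag
  expect_warning(lc <- helicity_lifetime(rep(1, 5000), dt = 10),
                 "lower bound")
  expect_true(lc$lower_bound)
})

test_that("conformer classification uses the closed trans window", {
  d <- rbind(c(163, -163, 170),     # all-trans (plus-twist minima)
             c(197, 163, 163),      # 197 == -163 signed: still trans
             c(60, 170, 170),       # one gauche dihedral
             c(120, 180, 180),      # boundary: closed interval rule
             c(119.9, 180, 180))    # just outside
  lab <- classify_conformers(d, trans_window = 60)
  expect_equal(lab, c("all-trans", "all-trans", "gauche-containing",
                      "all-trans", "gauche-containing"))
})

test_that("transition-state rates match the closed form on exact profiles", {
  B <- 4
  U <- function(phi) B / 2 * (1 - cos(2 * phi * pi / 180))
  prof <- free_energy_profile_from_potential(U, bin_width = 2)
  ts <- tst_rate(prof)
  ## harmonic curvature at the minimum: U'' = 2B (kBT/rad^2)
  closed <- sqrt(2 * B) / (2 * pi) * exp(-B)
  expect_equal(ts$rate, closed, tolerance = 0.02)
  expect_equal(ts$barrier_kT, B, tolerance = 0.01)
  ## doubling the barrier at fixed attempt frequency: exact exponential law
  p2 <- free_energy_profile_from_potential(function(x) 2 * U(x), 2)
  r1 <- tst_rate(prof, attempt_frequency = 1)
  r2 <- tst_rate(p2, attempt_frequency = 1)
  ## exponential law holds exactly at the measured (gridded) barriers
  expect_equal(r2$rate / r1$rate, exp(-(r2$barrier_kT - r1$barrier_kT)),
               tolerance = 1e-9)
  expect_equal(r2$rate / r1$rate, exp(-B), tolerance = 0.01)
  ## flat profile: analysis error
  expect_error(tst_rate(free_energy_profile_from_potential(function(x) 0 * x)),
               "analysis error")
})

test_that("sampled profiles keep noise dips from truncating the barrier", {
  B <- 4
  U <- function(phi) B / 2 * (1 - cos(2 * phi * pi / 180))
  ang <- gen_boltzmann_angles(1e6, U, seed = 3)
  ts <- tst_rate(free_energy_profile(ang, 2))
  expect_equal(ts$barrier_kT, B, tolerance = 0.06)
})

test_that("lifetimes shorten with flip rate while the landscape is fixed", {
  cfg <- generator_config(mode_frequencies = 1220, n_steps = 2^16, seed = 9)
  ser <- gen_concentration_series(cfg, flip_rates = c(0.2, 0.8),
                                  n_dihedral_samples = 1e5)
  taus <- vapply(ser, function(e) {
    helicity_lifetime(e$data$theta, dt = cfg$dt)$tau_integral_ps
  }, numeric(1))
  expect_gt(taus[1], taus[2])
  ## free-energy profiles pairwise identical within counting noise
  p1 <- free_energy_profile(ser[[1]]$dihedral_samples, 5)
  p2 <- free_energy_profile(ser[[2]]$dihedral_samples, 5)
  ok <- !is.na(p1$F) & !is.na(p2$F) & p1$counts > 50 & p2$counts > 50
  z <- abs(p1$F[ok] - p2$F[ok]) / sqrt(1 / p1$counts[ok] + 1 / p2$counts[ok])
  expect_lt(max(z), 5)
})
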