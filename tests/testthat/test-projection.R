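test_that("frames at and along reference structures project exactly", {
  sys <- helical_system()
  refp <- sys$refs$x_ref_plus
  j <- which.min(abs(sys$modes_plus$frequencies - 1220))
  a <- 0.3
  disp <- matrix(sys$modes_plus$cart_disp[, j], ncol = 3, byrow = TRUE)
  fr <- refp + a * disp
  ## a third frame: same displacement under an arbitrary rigid transform
  R <- rot_z(37)
  fr_rot <- t(R %*% t(fr)) + matrix(c(5, -3, 2), nrow(fr), 3, byrow = TRUE)
  traj <- trajectory(array(c(refp, fr, fr_rot), dim = c(nrow(fr), 3, 3)),
                     dt = 1, masses = sys$masses, charges = sys$charges)
  mt <- project_onto_modes(traj, sys$refs, sys$modes_minus, sys$modes_plus,
                           fit_subset = "all", fit_weights = "mass")
  expect_equal(mt$helicity_used, c(1L, 1L, 1L))
  ## frame exactly at the reference: all q zero
  expect_lt(max(abs(mt$q[1, ])), 1e-10)
  ## displaced frame: q_j = a, every other mode < 1e-10
  expect_equal(mt$q[2, j], a, tolerance = 1e-10)
  expect_lt(max(abs(mt$q[2, -j])), 1e-10)
  ## rigid transform absorbed by the alignment
  expect_equal(mt$q[3, ], mt$q[2, ], tolerance = 1e-8)
  ## atom-count mismatch refused
  small <- trajectory(array(0, c(4, 3, 2)), 1, rep(1, 4), rep(0, 4))
  expect_error(project_onto_modes(small, sys$refs, sys$modes_minus,
                                  sys$modes_plus),
               "mismatch")
})

test_that("dipole decomposition is exact in the Eckart-consistent fit metric", {
  sys <- helical_system()
  refm <- sys$refs$x_ref_minus
  ## static molecule at the minus reference
  traj0 <- trajectory(array(c(refm, refm), dim = c(nrow(refm), 3, 2)),
                      dt = 1, masses = sys$masses, charges = sys$charges)
  d0 <- decompose_dipole(traj0, sys$refs, sys$modes_minus, sys$modes_plus)
  expect_equal(d0$helicity_used, c(-1L, -1L))
  expect_equal(d0$mu_total, d0$mu_rb, tolerance = 1e-12)
  expect_lt(max(abs(d0$mu_vib)), 1e-12)
  expect_lt(max(abs(d0$residual)), 1e-12)
  ## single-mode displacement: |mu_vib_k| = |mu_k| |q_k| frame by frame and
  ## machine-zero residual (point-charge dipole is linear; the mass-weighted
  ## all-atom fit leaves the frame unrotated)
  j <- which.min(abs(sys$modes_plus$frequencies - 1220))
  disp <- matrix(sys$modes_plus$cart_disp[, j], ncol = 3, byrow = TRUE)
  amps <- c(0.1, 0.5)
  frames <- lapply(amps, function(a) sys$refs$x_ref_plus + a * disp)
  traj <- trajectory(array(unlist(frames), dim = c(nrow(disp), 3, 2)),
                     dt = 1, masses = sys$masses, charges = sys$charges)
  dec <- decompose_dipole(traj, sys$refs, sys$modes_minus, sys$modes_plus,
                          fit_subset = "all", fit_weights = "mass")
  muk <- sqrt(sum(sys$modes_plus$transition_dipoles[j, ]^2))
  for (t in 1:2) {
    expect_equal(sqrt(sum(dec$mu_vib[t, , j]^2)), muk * abs(dec$q[t, j]),
                 tolerance = 1e-10)
  }
  expect_lt(max(abs(dec$residual)), 1e-12)
})

test_that("carbon-subset fitting leaves a residual that grows linearly", {
  ## the default (carbon, unit-weight) alignment is not the Eckart metric of
  ## the modes, so its optimal rotation responds at first order to a mode
  ## displacement; with an exactly linear point-charge dipole the residual
  ## is therefore linear in the amplitude, not quadratic
  sys <- helical_system()
  j <- which.min(abs(sys$modes_plus$frequencies - 1220))
  disp <- matrix(sys$modes_plus$cart_disp[, j], ncol = 3, byrow = TRUE)
  amps <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  res <- vapply(amps, function(a) {
    fr <- sys$refs$x_ref_plus + a * disp
    traj <- trajectory(array(c(fr, fr), dim = c(nrow(fr), 3, 2)), dt = 1,
                       masses = sys$masses, charges = sys$charges)
    dec <- decompose_dipole(traj, sys$refs, sys$modes_minus, sys$modes_plus)
    sqrt(sum(dec$residual[1, ]^2))
  }, numeric(1))
  expo <- unname(coef(stats::lm(log(res) ~ log(amps)))[2])
  expect_equal(expo, 1, tolerance = 0.15)
})

test_that("per-mode spectra close to the total for separated modes and flag degeneracy", {
  cfg <- generator_config(mode_frequencies = c(1100, 1300), mode_damping = 1,
                          flip_rate = 0.3, dipole_rotation_angle = 10,
                          n_steps = 2^16, seed = 5)
  d <- gen_telegraph_modes(cfg)
  ms <- mode_spectra(d, window = "hann", n_segments = 8)
  expect_lt(ms$closure_err, 0.01)
  ## single mode: decomposition exact
  cfg1 <- generator_config(mode_frequencies = 1220, n_steps = 2^14, seed = 5)
  d1 <- gen_telegraph_modes(cfg1)
  ms1 <- mode_spectra(d1, window = "hann", n_segments = 4)
  expect_equal(ms1$per_mode[[1]]$values, ms1$total$values, tolerance = 1e-10)
  ## two degenerate, fully correlated modes: cross-term bound flags it
  q1 <- d1$q[, 1]
  fake <- structure(list(mu_vib = array(rep(outer(q1, c(1, 0, 0)), 2),
                                        dim = c(length(q1), 3, 2)),
                         dt = cfg1$dt),
                    class = "dipole_decomposition")
  msf <- mode_spectra(fake, window = "hann", n_segments = 4)
  expect_gt(msf$cross_term, 0.05)
})

test_that("helicity-frozen spectra differ from full spectra only via dipole rotation", {
  ## zero flip rate: frozen and full identical within numerical noise
  cfg0 <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                           flip_rate = 0, dipole_rotation_angle = 180,
                           n_steps = 2^16, seed = 3)
  d0 <- gen_telegraph_modes(cfg0)
  ms0 <- mode_spectra(d0, window = "hann", n_segments = 8)
  fz0 <- helicity_frozen_spectrum(d0, d0$modes_minus, window = "hann",
                                  n_segments = 8)
  expect_equal(ms0$per_mode[[1]]$values, fz0[[1]]$values, tolerance = 1e-8)
  ## zero rotation angle: no difference at finite flip rate
  cfgr <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                           flip_rate = 0.5, dipole_rotation_angle = 0,
                           n_steps = 2^16, seed = 3)
  dr <- gen_telegraph_modes(cfgr)
  msr <- mode_spectra(dr, window = "hann", n_segments = 8)
  fzr <- helicity_frozen_spectrum(dr, dr$modes_minus, window = "hann",
                                  n_segments = 8)
  ## mu_minus = mu_plus: the full spectrum is the frozen spectrum exactly
  expect_equal(msr$per_mode[[1]]$values, fzr[[1]]$values, tolerance = 1e-8)
})

test_that("telegraph modulation broadens the full spectrum by 4k/(2 pi c)", {
  k <- 0.5  # ps^-1
  cfg <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                          flip_rate = k, dipole_rotation_angle = 180,
                          n_steps = 2^20, seed = 7)
  d <- gen_telegraph_modes(cfg)
  ms <- mode_spectra(d, window = "hann", n_segments = 32)
  fz <- helicity_frozen_spectrum(d, d$modes_minus, window = "hann",
                                 n_segments = 32)
  band <- c(1140, 1300)
  f_full <- fit_band(ms$per_mode[[1]], band)
  f_froz <- fit_band(fz[[1]], band)
  expected <- 4 * k * 1e-3 / (2 * pi * c_cm_fs)
  expect_equal(f_full$fwhm - f_froz$fwhm, expected, tolerance = 0.10)
  ## intensity is redistributed, not created: fitted band areas agree
  ## (single-trace estimate; the acceptance suite tightens this with
  ## molecule averaging)
  expect_equal(f_full$area / f_froz$area, 1, tolerance = 0.06)
})

test_that("full-spectrum width grows monotonically with flip rate", {
  rates <- c(0.1, 0.3, 1.0)
  fw <- vapply(rates, function(k) {
    cfg <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                            flip_rate = k, dipole_rotation_angle = 180,
                            n_steps = 2^18, seed = 11)
    d <- gen_telegraph_modes(cfg)
    ms <- mode_spectra(d, window = "hann", n_segments = 16)
    fit_band(ms$per_mode[[1]], c(1140, 1300))$fwhm
  }, numeric(1))
  expect_true(all(diff(fw) > 0))
})

test_that("event-aligned autocorrelation isolates the reversal decorrelation", {
  base <- function(angle, seed = 3) {
    cfg <- generator_config(mode_frequencies = 1220, mode_damping = 0.5,
                            flip_rate = 0.2, dipole_rotation_angle = angle,
                            n_steps = 2^18, seed = seed)
    gen_telegraph_modes(cfg)
  }
  win <- function(env, i0, i1) mean(env[i0:i1])
  i_ev <- round(200 / 2)
  ## 90 degrees: conditional envelope collapses right after the event
  d90 <- base(90)
  ea90 <- event_aligned_acf(d90$mu_vib[, , 1], 2, d90$events)
  expect_gt(ea90$n_events, 20)
  drop_cond <- win(ea90$envelope_conditional, i_ev + 10, i_ev + 60) /
    win(ea90$envelope_conditional, i_ev - 60, i_ev - 10)
  drop_unc <- win(ea90$envelope_unconditional, i_ev + 10, i_ev + 60) /
    win(ea90$envelope_unconditional, i_ev - 60, i_ev - 10)
  expect_lt(drop_cond, 0.5 * drop_unc)
  ## 180 degrees: the correlation reverses sign but the envelope survives
  d180 <- base(180)
  ea180 <- event_aligned_acf(d180$mu_vib[, , 1], 2, d180$events)
  after <- (i_ev + 10):(i_ev + 60)
  expect_lt(cor(ea180$conditional[after], ea180$unconditional[after]), -0.8)
  drop180 <- win(ea180$envelope_conditional, i_ev + 10, i_ev + 60) /
    win(ea180$envelope_conditional, i_ev - 60, i_ev - 10)
  expect_gt(drop180, 0.75)
  ## 0 degrees: conditional tracks unconditional
  d0 <- base(0)
  ea0 <- event_aligned_acf(d0$mu_vib[, , 1], 2, d0$events)
  expect_equal(win(ea0$envelope_conditional, i_ev + 10, i_ev + 60) /
                 win(ea0$envelope_conditional, i_ev - 60, i_ev - 10),
               win(ea0$envelope_unconditional, i_ev + 10, i_ev + 60) /
                 win(ea0$envelope_unconditional, i_ev - 60, i_ev - 10),
               tolerance = 0.15)
  ## no events: statistics warning, unconditional decay matches the damping
  cfgq <- generator_config(mode_frequencies = 1220, mode_damping = 1,
                           flip_rate = 0, n_steps = 2^18, seed = 5)
  dq <- gen_telegraph_modes(cfgq)
  expect_warning(
    eaq <- event_aligned_acf(dq$mu_vib[, , 1], 2, numeric(0), window = 4000),
    "statistics warning")
  env <- eaq$envelope_unconditional
  tt <- eaq$t
  sel <- tt > 200 & tt < 3000 & env > 0.05
  gamma_fit <- -2 * unname(coef(stats::lm(log(env[sel]) ~ tt[sel]))[2])
  expect_equal(gamma_fit, 1e-3, tolerance = 0.05)
})

test_that("projected spectra are invariant under a global rigid rotation", {
  sys <- helical_system()
  cfg <- generator_config(n_steps = 512, dt = 2, flip_rate = 0.5, seed = 42)
  g <- gen_mode_dynamics(cfg, sys)
  mt <- project_onto_modes(g$traj, g$refs, g$modes_minus, g$modes_plus,
                           fit_subset = "all", fit_weights = "mass")
  expect_lt(max(abs(mt$q[, g$mode_idx] - g$q)), 1e-10)
  expect_equal(mt$helicity_used, g$theta)
  cr <- g$traj$coords
  R <- rot_z(63)
  for (t in seq_len(dim(cr)[3])) cr[, , t] <- t(R %*% t(cr[, , t])) + 3
  traj2 <- trajectory(cr, dt = 2, masses = sys$masses, charges = sys$charges)
  mt2 <- project_onto_modes(traj2, g$refs, g$modes_minus, g$modes_plus,
                            fit_subset = "all", fit_weights = "mass")
  expect_equal(mt2$q, mt$q, tolerance = 1e-8)
})

test_that("masked frames are split into contiguous segments", {
  mt <- structure(list(q = matrix(rnorm(2000), 1000, 2),
                       helicity_used = rep(1L, 1000),
                       frame_mask = rep(TRUE, 1000), dt = 2,
                       frequencies = c(1100, 1200)),
                  class = "mode_trajectory")
  mask <- rep(TRUE, 1000)
  mask[301:310] <- FALSE     # short gauche excursion
  mask[700:1000] <- FALSE    # long gauche tail
  segs <- split_masked_segments(mt, mask, min_length = 128L)
  expect_length(segs, 2)
  expect_equal(nrow(segs[[1]]$q), 300)
  expect_equal(nrow(segs[[2]]$q), 389)
})
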