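#' Configuration for the synthetic generators
#'
#' Defaults encode the study conditions the pipeline is designed around: a
#' six-carbon helical perfluoroalkyl backbone with a 17 degree twist per
#' backbone dihedral (overall helicity dihedral near 35 degrees), C-F-like
#' mode frequencies in the 1000-1300 cm^-1 band, damping giving a few cm^-1
#' of intrinsic Lorentzian width, Poissonian helicity flips on the
#' picosecond scale, and a small (10 degree) rotation of the transition
#' dipoles upon helicity reversal.
#'
#' @param n_carbons backbone length (>= 4; shorter chains are planar and
#'   carry no helicity)
#' @param twist_per_dihedral helical twist per backbone dihedral, degrees
#' @param overall_twist nominal overall-helicity dihedral, degrees
#' @param mode_frequencies wavenumbers of the simulated modes, cm^-1
#' @param mode_damping per-mode damping rates, ps^-1 (recycled)
#' @param flip_rate per-direction helicity flip rate, ps^-1
#' @param dipole_rotation_angle angle between the plus- and minus-helicity
#'   transition dipoles, degrees
#' @param dt time step, fs
#' @param n_steps number of steps
#' @param temperature K
#' @param seed master seed; all child streams derive from it
#'   deterministically
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_carbons = 6, twist_per_dihedral = 17,
                             overall_twist = 35,
                             mode_frequencies = c(1135, 1220, 1236),
                             mode_damping = 1.0, flip_rate = 0.172,
                             dipole_rotation_angle = 10, dt = 2,
                             n_steps = 2^16, temperature = 300, seed = 1L) {
  if (n_carbons < 4) {
    stop("config error: chains with fewer than 4 carbons are planar and have ",
         "no helicity; n_carbons must be >= 4")
  }
  stopifnot(twist_per_dihedral > 0, all(mode_frequencies > 0),
            all(mode_damping > 0), flip_rate >= 0, dt > 0, n_steps >= 2,
            temperature > 0)
  structure(list(n_carbons = as.integer(n_carbons),
                 twist_per_dihedral = twist_per_dihedral,
                 overall_twist = overall_twist,
                 mode_frequencies = mode_frequencies,
                 mode_damping = rep_len(mode_damping, length(mode_frequencies)),
                 flip_rate = flip_rate,
                 dipole_rotation_angle = dipole_rotation_angle,
                 dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, seed = as.integer(seed)),
            class = "generator_config")
}

## NeRF atom placement: position D bonded to C with bond length r, angle
## D-C-B = theta and signed dihedral A-B-C-D = phi (degrees), consistent
## with dihedral_angle().
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Helical reference pair with spring-network Hessians
#'
#' Builds a helical carbon backbone (fixed bond length 1.54 A, fixed bond
#' angle, every backbone dihedral at +/-(180 - twist) degrees for the two
#' helicities) decorated with two pseudo-fluorine sites per carbon carrying
#' point charges (C +0.3 e, F -0.15 e; exactly net-neutral). The two
#' references are exact mirror images. For each helicity an analytic
#' harmonic Hessian is assembled from a pairwise distance-spring network
#' (bond, 1-3 angle-like, 1-4 dihedral-like and F-anchoring springs): at the
#' reference geometry every spring is at its rest length, so each spring
#' contributes the exact rank-1 block `k u u^T` and the Hessian is analytic,
#' not finite-differenced. Spring constants are chosen so the C-F-dominated
#' modes fall in the 1000-1300 cm^-1 band.
#'
#' Atom ordering: carbons `1..n_carbons` first, then fluorine pairs; the
#' overall-helicity dihedral is the C1-C2-C5-C6 carbon dihedral and the
#' default fit subset is the carbon atoms.
#'
#' In the twist convention used throughout (a twist is the deviation of a
#' dihedral from planar trans, `twist = 180 - |phi|`), interior backbone
#' dihedrals sit at `180 - twist_per_dihedral` while the two outermost
#' dihedrals are solved numerically so the overall helicity dihedral
#' honors `overall_twist` exactly — mirroring the relaxed chain ends of
#' optimized perfluoroalkyl geometries, whose end dihedrals deviate less
#' than the middle ones.
#'
#' @param config `generator_config`
#' @return list with `refs` ([reference_pair()]), `hessian_plus`,
#'   `hessian_minus` (amu/fs^2), `masses`, `charges`, `carbon_idx`, `config`
#' @export
gen_helical_references <- function(config) {
  nc <- config$n_carbons
  b_cc <- 1.54; b_cf <- 1.35
  theta_b <- 114.6      # backbone bond angle, deg
  build_backbone <- function(twist_outer) {
    phis <- rep(180 - config$twist_per_dihedral, nc - 3)
    phis[1] <- 180 - twist_outer
    phis[nc - 3] <- 180 - twist_outer
    C <- matrix(0, nc, 3)
    C[2, ] <- c(b_cc, 0, 0)
    C[3, ] <- C[2, ] + b_cc * c(-cos(theta_b * pi / 180),
                                sin(theta_b * pi / 180), 0)
    for (i in 4:nc) {
      C[i, ] <- place_atom(C[i - 3, ], C[i - 2, ], C[i - 1, ],
                           b_cc, theta_b, phis[i - 3])
    }
    C
  }
  twist_err <- function(tw) {
    180 - abs(dihedral_angle(build_backbone(tw), c(1, 2, 5, 6))) -
      config$overall_twist
  }
  tw_out <- tryCatch(
    stats::uniroot(twist_err, c(0.1, config$twist_per_dihedral + 20))$root,
    error = function(e) config$twist_per_dihedral)
  C <- build_backbone(tw_out)
  ## pseudo-fluorines via NeRF off the backbone
  Fx <- matrix(0, 2 * nc, 3)
  for (i in seq_len(nc)) {
    if (i == 1) {
      tri <- list(C[3, ], C[2, ], C[1, ]); base <- 0
    } else if (i == 2) {
      tri <- list(C[4, ], C[3, ], C[2, ]); base <- 0
    } else {
      tri <- list(C[i - 2, ], C[i - 1, ], C[i, ])
      base <- if (i < nc) {
        dihedral_angle(rbind(tri[[1]], tri[[2]], tri[[3]], C[i + 1, ]), 1:4)
      } else 0
    }
    Fx[2 * i - 1, ] <- place_atom(tri[[1]], tri[[2]], tri[[3]], b_cf,
                                  109.5, base + 120)
    Fx[2 * i, ] <- place_atom(tri[[1]], tri[[2]], tri[[3]], b_cf,
                              109.5, base - 120)
  }
  x_plus <- rbind(C, Fx)
  x_minus <- x_plus %*% diag(c(1, 1, -1))   # mirror conformer
  n <- nrow(x_plus)
  masses <- c(rep(12.011, nc), rep(18.9984032, 2 * nc))
  charges <- c(rep(0.30, nc), rep(-0.15, 2 * nc))

  ## spring network (pair indices and force constants, amu/fs^2)
  springs <- list()
  add <- function(i, j, k) springs[[length(springs) + 1L]] <<- c(i, j, k)
  for (i in seq_len(nc - 1)) add(i, i + 1, 0.45)          # C-C bonds
  for (i in seq_len(nc - 2)) add(i, i + 2, 0.08)          # backbone 1-3
  for (i in seq_len(nc - 3)) add(i, i + 3, 0.02)          # backbone 1-4
  for (i in seq_len(nc)) {
    f1 <- nc + 2 * i - 1; f2 <- nc + 2 * i
    add(i, f1, 0.42); add(i, f2, 0.42)                    # C-F bonds
    add(f1, f2, 0.06)                                     # F-F same carbon
    if (i > 1) { add(f1, i - 1, 0.05); add(f2, i - 1, 0.05) }
    if (i < nc) {
      add(f1, i + 1, 0.05); add(f2, i + 1, 0.05)
      ## adjacent-fluorine braces: without them the network retains two
      ## delocalized zero-frequency mechanisms
      add(f1, f1 + 2, 0.03); add(f2, f2 + 2, 0.03)
      add(f1, f2 + 2, 0.02)
    }
  }
  spring_hessian <- function(x) {
    H <- matrix(0, 3 * n, 3 * n)
    for (s in springs) {
      i <- s[1]; j <- s[2]; k <- s[3]
      u <- x[j, ] - x[i, ]; u <- u / sqrt(sum(u^2))
      B <- k * tcrossprod(u)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, ii] <- H[ii, ii] + B
      H[jj, jj] <- H[jj, jj] + B
      H[ii, jj] <- H[ii, jj] - B
      H[jj, ii] <- H[jj, ii] - B
    }
    H
  }
  refs <- reference_pair(x_minus, x_plus, fit_atom_subset = seq_len(nc),
                         helicity_dihedral = c(1, 2, 5, 6))
  list(refs = refs, hessian_plus = spring_hessian(x_plus),
       hessian_minus = spring_hessian(x_minus),
       masses = masses, charges = charges, carbon_idx = seq_len(nc),
       config = config)
}

#' Exact sampler for underdamped Langevin normal-mode dynamics
#'
#' Each normal coordinate evolves as a thermalized damped harmonic
#' oscillator, `q'' = -omega^2 q - gamma q' + noise`, sampled with the exact
#' Gaussian propagator of the linear SDE (no discretization error in either
#' the trajectory statistics or the stationary distribution; classical
#' equipartition `<q^2> omega^2 = kB T` holds in law). Stationary
#' initialization.
#'
#' @param freq_cm mode wavenumbers, cm^-1
#' @param damping_ps damping rates gamma, ps^-1 (recycled)
#' @param n_steps number of samples
#' @param dt time step, fs (at least 10 steps per period required)
#' @param temperature K
#' @param seed integer seed
#' @return `n_steps x K` matrix of mass-weighted normal coordinates
#' @export
sim_langevin_modes <- function(freq_cm, damping_ps, n_steps, dt,
                               temperature = 300, seed = 1L) {
  period_min <- 1 / (max(freq_cm) * .c_cm_fs)
  if (dt > period_min / 10) {
    stop("config error: dt = ", dt, " fs gives fewer than 10 steps per ",
         "period of the fastest mode (", signif(period_min, 4), " fs)")
  }
  damping_ps <- rep_len(damping_ps, length(freq_cm))
  kT <- .kB * temperature
  set.seed(seed)
  T <- n_steps
  q <- matrix(0, T, length(freq_cm))
  for (k in seq_along(freq_cm)) {
    w <- wavenumber_to_omega(freq_cm[k])
    g <- damping_ps[k] / 1000
    A <- matrix(c(0, -w^2, 1, -g), 2, 2)
    ev <- eigen(A)
    M <- Re(ev$vectors %*% diag(exp(ev$values * dt)) %*% solve(ev$vectors))
    Sinf <- diag(c(kT / w^2, kT))
    Q <- Sinf - M %*% Sinf %*% t(M)
    Q <- (Q + t(Q)) / 2
    L <- t(chol(Q))
    x1 <- c(sqrt(kT) / w * stats::rnorm(1), sqrt(kT) * stats::rnorm(1))
    W <- L %*% matrix(stats::rnorm(2 * (T - 1)), 2)
    q1 <- x1[1]
    q2 <- sum(M[1, ] * x1) + W[1, 1]
    ## q_{t+2} = tr(M) q_{t+1} - det(M) q_t + u_t with MA(1) innovations
    phi1 <- M[1, 1] + M[2, 2]
    phi2 <- -(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
    j <- seq_len(T - 2)
    u <- W[1, j + 1] + M[1, 2] * W[2, j] - M[2, 2] * W[1, j]
    q[, k] <- c(q1, q2,
                stats::filter(u, c(phi1, phi2), method = "recursive",
                              init = c(q2, q1)))
  }
  q
}

#' Telegraph helicity process
#'
#' Two-state Markov jump process with per-direction flip rate `k`; its
#' indicator autocorrelation is `exp(-2 k t)` and the lifetime `1/(2k)`.
#'
#' @param n_steps samples
#' @param dt fs
#' @param rate_ps per-direction flip rate, ps^-1
#' @param seed integer seed
#' @param theta0 initial state (+1/-1; random if `NULL`)
#' @return list with `theta` (length `n_steps`, -1/+1) and `flip_times` (fs)
#' @export
sim_telegraph <- function(n_steps, dt, rate_ps, seed = 1L, theta0 = NULL) {
  set.seed(seed)
  if (is.null(theta0)) theta0 <- sample(c(-1, 1), 1)
  t_end <- n_steps * dt
  if (rate_ps <= 0) {
    return(list(theta = rep(theta0, n_steps), flip_times = numeric(0)))
  }
  k_fs <- rate_ps / 1000
  n_exp <- ceiling(t_end * k_fs + 10 * sqrt(t_end * k_fs) + 10)
  wt <- stats::rexp(n_exp, k_fs)
  while (sum(wt) < t_end) wt <- c(wt, stats::rexp(n_exp, k_fs))
  ft <- cumsum(wt)
  ft <- ft[ft < t_end]
  tg <- (seq_len(n_steps) - 1) * dt
  nflip <- findInterval(tg, ft)
  list(theta = theta0 * (-1)^nflip, flip_times = ft)
}

#' Telegraph-modulated mode dynamics (dipole-level generator)
#'
#' The fast path of the synthetic model: Langevin normal coordinates
#' (exact propagator), a telegraph helicity process, and per-mode transition
#' dipoles that rotate by `dipole_rotation_angle` about the chain (z) axis
#' upon helicity reversal. Transition dipoles are placed perpendicular to
#' the chain axis so the rotation acts fully on them. The vibrational dipole
#' of mode k is `mu_k^(h(t)) q_k(t)`; no coordinates are built, which keeps
#' million-step runs cheap.
#'
#' Child seeds for the oscillator and telegraph streams are derived
#' deterministically from `config$seed`; passing `telegraph_stream` varies
#' only the flip process, which is how a concentration series shares its
#' thermodynamics across flip rates.
#'
#' @param config `generator_config`
#' @param telegraph_stream integer distinguishing the telegraph child stream
#'   (default 0)
#' @return `dipole_decomposition`-classed list (so [mode_spectra()] and
#'   [helicity_frozen_spectrum()] apply directly) with additional fields
#'   `events` (flip times, fs), `theta`, `mu_plus`, `mu_minus` (`K x 3`),
#'   and `modes_minus`/`modes_plus` (minimal transition-dipole carriers)
#' @export
gen_telegraph_modes <- function(config, telegraph_stream = 0L) {
  K <- length(config$mode_frequencies)
  q <- sim_langevin_modes(config$mode_frequencies, config$mode_damping,
                          config$n_steps, config$dt, config$temperature,
                          seed = child_seed(config$seed, 1L))
  tg <- sim_telegraph(config$n_steps, config$dt, config$flip_rate,
                      seed = child_seed(config$seed, 101L + telegraph_stream),
                      theta0 = 1)
  ## transition dipoles perpendicular to the chain (z) axis
  alpha <- 2 * pi * (seq_len(K) - 1) / max(K, 1)
  mu_plus <- cbind(cos(alpha), sin(alpha), 0)
  rot <- config$dipole_rotation_angle * pi / 180
  Rz <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1), 3, 3)
  mu_minus <- mu_plus %*% t(Rz)
  T <- config$n_steps
  hplus <- tg$theta > 0
  mu_vib <- array(0, dim = c(T, 3, K))
  for (k in seq_len(K)) {
    mk <- matrix(0, T, 3)
    mk[hplus, ] <- outer(q[hplus, k], mu_plus[k, ])
    mk[!hplus, ] <- outer(q[!hplus, k], mu_minus[k, ])
    mu_vib[, , k] <- mk
  }
  mu_total <- apply(mu_vib, c(1, 2), sum)
  structure(list(mu_total = mu_total, mu_rb = matrix(0, T, 3),
                 mu_vib = mu_vib, residual = matrix(0, T, 3), q = q,
                 helicity_used = tg$theta, dt = config$dt,
                 frequencies = config$mode_frequencies,
                 events = tg$flip_times, theta = tg$theta,
                 mu_plus = mu_plus, mu_minus = mu_minus,
                 modes_minus = list(transition_dipoles = mu_minus),
                 modes_plus = list(transition_dipoles = mu_plus),
                 config = config),
            class = "dipole_decomposition")
}

#' Full synthetic trajectory with helicity flips
#'
#' Drives the normal modes of a helical reference system (from
#' [gen_helical_references()]) with exact Langevin dynamics, flips the
#' helicity as a telegraph process (instantaneous swap of reference and
#' mode set), reconstructs Cartesian coordinates
#' `x(t) = x_ref^(h) + sum_k q_k cart_disp_k^(h)` and evaluates the
#' point-charge molecular dipole. Ground-truth flip events are returned.
#'
#' @param config `generator_config`; `mode_band` selects which Hessian modes
#'   are driven
#' @param system output of [gen_helical_references()] (built from `config`
#'   if omitted)
#' @param mode_band wavenumber window of driven modes, cm^-1
#' @param telegraph_stream child-stream index for the flip process
#' @return list with `traj` ([trajectory()]), `dipole` ([dipole_trace()]),
#'   `q`, `theta`, `events` (fs), `modes_minus`, `modes_plus`, `refs`,
#'   `mode_idx`
#' @export
gen_mode_dynamics <- function(config, system = NULL,
                              mode_band = c(1000, 1400),
                              telegraph_stream = 0L) {
  if (is.null(system)) system <- gen_helical_references(config)
  mp <- compute_normal_modes(system$hessian_plus, system$masses,
                             system$refs$x_ref_plus, system$charges,
                             helicity = +1L)
  mm <- compute_normal_modes(system$hessian_minus, system$masses,
                             system$refs$x_ref_minus, system$charges,
                             helicity = -1L)
  sel <- which(mp$frequencies >= mode_band[1] & mp$frequencies <= mode_band[2])
  if (!length(sel)) stop("config error: no modes in the requested band")
  freqs <- mp$frequencies[sel]
  q <- sim_langevin_modes(freqs, rep_len(config$mode_damping, length(sel)),
                          config$n_steps, config$dt, config$temperature,
                          seed = child_seed(config$seed, 1L))
  tg <- sim_telegraph(config$n_steps, config$dt, config$flip_rate,
                      seed = child_seed(config$seed, 101L + telegraph_stream),
                      theta0 = 1)
  n <- length(system$masses); T <- config$n_steps
  ref_p <- as.vector(t(system$refs$x_ref_plus))
  ref_m <- as.vector(t(system$refs$x_ref_minus))
  disp_p <- mp$cart_disp[, sel, drop = FALSE] %*% t(q)   # 3n x T
  disp_m <- mm$cart_disp[, sel, drop = FALSE] %*% t(q)
  hplus <- tg$theta > 0
  X <- matrix(0, 3 * n, T)
  X[, hplus] <- ref_p + disp_p[, hplus, drop = FALSE]
  X[, !hplus] <- ref_m + disp_m[, !hplus, drop = FALSE]
  coords <- aperm(array(X, dim = c(3, n, T)), c(2, 1, 3))
  traj <- trajectory(coords, dt = config$dt, masses = system$masses,
                     charges = system$charges)
  mu <- t(apply(coords, 3, function(fr) colSums(system$charges * fr)))
  dip <- dipole_trace(mu, config$dt, label = "molecule")
  list(traj = traj, dipole = dip, q = q, theta = tg$theta,
       events = tg$flip_times, modes_minus = mm, modes_plus = mp,
       refs = system$refs, mode_idx = sel)
}

#' Synthetic concentration series (flip rate mapped to mole fraction)
#'
#' One dataset per label, all sharing the oscillator dynamics (identical
#' potential, temperature and thermodynamics via a common random-number
#' stream) and differing only in the telegraph flip rate - the kinetic
#' mechanism by which a fluorous environment shortens the helicity
#' lifetime without touching the free-energy landscape. Each entry also
#' carries equilibrium dihedral-angle samples drawn from a fixed double-well
#' potential with minima at the two helicities, so free-energy profiles can
#' be compared across the series.
#'
#' @param config `generator_config` (its `flip_rate` is ignored)
#' @param flip_rates per-direction flip rates, ps^-1 (>= 2 values)
#' @param labels unique labels (e.g. mole fractions); defaults to the rates
#' @param n_dihedral_samples samples per label for the dihedral profile
#' @param dihedral_barrier_kT barrier of the shared dihedral double well
#' @return list of entries: `label`, `flip_rate`, `data`
#'   (from [gen_telegraph_modes()]), `dihedral_samples` (degrees)
#' @export
gen_concentration_series <- function(config, flip_rates, labels = flip_rates,
                                     n_dihedral_samples = 2e5,
                                     dihedral_barrier_kT = 4) {
  if (length(flip_rates) < 2) stop("config error: need >= 2 flip rates")
  if (anyDuplicated(labels)) stop("config error: duplicate labels")
  lapply(seq_along(flip_rates), function(i) {
    cfg <- config
    cfg$flip_rate <- flip_rates[i]
    dat <- gen_telegraph_modes(cfg, telegraph_stream = i)
    dih <- gen_boltzmann_dihedrals(
      n_dihedral_samples, barrier_kT = dihedral_barrier_kT,
      minima_deg = 180 - config$overall_twist,
      seed = child_seed(config$seed, 201L + i))
    list(label = labels[i], flip_rate = flip_rates[i], data = dat,
         dihedral_samples = dih)
  })
}

#' Sample dihedral angles from a double-well Boltzmann distribution
#'
#' Potential (in kB T) with minima at `+/- minima_deg` and a barrier of
#' `barrier_kT` between them through the nearer of 0/180 degrees:
#' `U(phi) = barrier * (cos(phi) - cos(m))^2 / (1 - |cos(m)|)^2`.
#' For minima near +/-145 degrees (a 35 degree helical twist) this gives a
#' `barrier_kT` crossing through the planar-trans configuration at 180
#' degrees and an effectively forbidden cis crossing at 0, the topology of
#' the overall-helicity dihedral free energy. Sampling is by inversion on a
#' fine grid with within-bin jitter.
#'
#' @param n number of samples
#' @param barrier_kT barrier height, kB T units
#' @param minima_deg position of the minima, degrees
#' @param seed integer seed
#' @param grid_deg grid resolution, degrees
#' @return numeric vector of angles in (-180, 180]
#' @export
gen_boltzmann_dihedrals <- function(n, barrier_kT = 4, minima_deg = 145,
                                    seed = 1L, grid_deg = 0.1) {
  set.seed(seed)
  phi <- seq(-180 + grid_deg / 2, 180 - grid_deg / 2, by = grid_deg)
  cm <- cos(minima_deg * pi / 180)
  U <- barrier_kT * (cos(phi * pi / 180) - cm)^2 / (1 - abs(cm))^2
  p <- exp(-U); p <- p / sum(p)
  idx <- sample.int(length(phi), n, replace = TRUE, prob = p)
  phi[idx] + stats::runif(n, -grid_deg / 2, grid_deg / 2)
}

#' Sample angles from an arbitrary Boltzmann potential
#'
#' @param n number of samples
#' @param potential function of angle (degrees) returning energy in kB T
#' @param seed integer seed
#' @param grid_deg grid resolution, degrees
#' @return numeric vector of angles in (-180, 180]
#' @export
gen_boltzmann_angles <- function(n, potential, seed = 1L, grid_deg = 0.05) {
  set.seed(seed)
  phi <- seq(-180 + grid_deg / 2, 180 - grid_deg / 2, by = grid_deg)
  p <- exp(-potential(phi)); p <- p / sum(p)
  idx <- sample.int(length(phi), n, replace = TRUE, prob = p)
  phi[idx] + stats::runif(n, -grid_deg / 2, grid_deg / 2)
}

#' Forward-modelled ATR spectrum from a Lorentzian-oscillator dielectric
#'
#' Builds `Im(eps)` as a sum of Lorentzian bands, its dispersive
#' Kramers-Kronig partner as the Hilbert conjugate, and mixes the two with a
#' global phase (the ATR distortion); Gaussian noise is added at the stated
#' signal-to-noise ratio. The ground-truth `Im(eps)` is returned for
#' round-trip tests.
#'
#' @param oscillators data.frame/matrix with columns `center` (cm^-1),
#'   `strength` (integrated intensity) and `width` (FWHM, cm^-1)
#' @param mixing_phase degrees (0 = pure absorptive; 90 = pure dispersive
#'   admixture, the nominal ATR value)
#' @param snr peak signal-to-noise ratio (`Inf` = noiseless)
#' @param nu wavenumber grid, cm^-1 (default 900-1500 at 0.5;
#'   keep band centers well inside the window so edge tails stay small)
#' @param seed integer seed for the noise stream
#' @return list with `spectrum` (ATR `experimental_spectrum`), `im_eps`
#'   (ground-truth `fspec_spectrum`), `dispersive` (its Hilbert conjugate)
#' @export
gen_atr_spectrum <- function(oscillators, mixing_phase = 90, snr = Inf,
                             nu = seq(900, 1500, by = 0.5), seed = 1L) {
  osc <- as.data.frame(oscillators)
  stopifnot(all(osc$center >= min(nu) & osc$center <= max(nu)))
  im <- numeric(length(nu))
  for (i in seq_len(nrow(osc))) {
    im <- im + lorentzian(nu, osc$center[i], osc$width[i],
                          area = osc$strength[i])
  }
  disp <- hilbert_transform(im, pad_frac = 0)
  phi <- mixing_phase * pi / 180
  tr <- cos(phi) * im + sin(phi) * disp
  if (is.finite(snr)) {
    set.seed(seed)
    tr <- tr + stats::rnorm(length(nu), sd = max(im) / snr)
  }
  list(spectrum = experimental_spectrum(nu, tr, acquisition = "ATR",
                                        resolution = stats::median(diff(nu)),
                                        metadata = list(synthetic = TRUE,
                                                        phase = mixing_phase,
                                                        snr = snr)),
       im_eps = spectrum_obj(nu, im, kind = "dielectric"),
       dispersive = spectrum_obj(nu, disp, kind = "dielectric"))
}
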