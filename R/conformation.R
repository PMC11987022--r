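#' Exact free-energy profile from a known potential
#'
#' Evaluates a potential (in kB T) on the standard bin-center grid and
#' returns it as a `free_energy_profile`, min-shifted to zero. Useful for
#' closed-form checks of barrier and rate estimators without sampling
#' noise.
#'
#' @param potential function of angle (degrees) returning energy in kB T
#' @param bin_width grid spacing, degrees
#' @return `free_energy_profile` (with `counts = NA`)
#' @export
free_energy_profile_from_potential <- function(potential, bin_width = 2) {
  breaks <- seq(-180, 180, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  F <- potential(centers)
  F <- F - min(F)
  structure(list(angle_grid = centers, F = F,
                 counts = rep(NA_integer_, length(centers)),
                 bin_width = bin_width, temperature = NULL),
            class = "free_energy_profile")
}

#' Dihedral free-energy profile
#'
#' Boltzmann inversion of a dihedral-angle histogram:
#' `F = -kB T ln p(phi)`, shifted so the minimum is zero. Profiles are
#' returned in units of kB T; with `temperature` given, a kJ/mol column is
#' added. Empty bins are flagged (`NA`), never silently interpolated.
#'
#' @param angles per-frame dihedral angles, degrees (signed or 0-360)
#' @param bin_width histogram bin width, degrees (default 2)
#' @param temperature optional absolute temperature, K, for the kJ/mol
#'   conversion
#' @return object of class `free_energy_profile` with `angle_grid` (bin
#'   centers, degrees, signed convention), `F` (kB T units, min 0), `counts`
#' @export
free_energy_profile <- function(angles, bin_width = 2, temperature = NULL) {
  if (!length(angles)) stop("input error: empty angle series")
  if (length(angles) < 1e4) {
    warning("fewer than 1e4 samples; free-energy profile will be noisy")
  }
  x <- dihedral_to_signed(angles)
  breaks <- seq(-180, 180, by = bin_width)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  centers <- breaks[-length(breaks)] + bin_width / 2
  p <- counts / sum(counts)
  F <- -log(p)
  F[counts == 0] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  out <- structure(list(angle_grid = centers, F = F, counts = counts,
                        bin_width = bin_width, temperature = temperature),
                   class = "free_energy_profile")
  if (!is.null(temperature)) {
    out$F_kJ_mol <- F * 8.31446261815324e-3 * temperature
  }
  out
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile: %d bins of %g deg, barrier %.2f kBT, %d empty bins>\n",
              length(x$angle_grid), x$bin_width, max(x$F, na.rm = TRUE),
              sum(is.na(x$F))))
  invisible(x)
}

#' Helicity indicator trace with debounced flip events
#'
#' The helicity indicator is the sign of the overall-helicity dihedral
#' (+1 right-handed, -1 left-handed); a frame with dihedral exactly 0 or
#' 180 degrees inherits the previous indicator. Sign changes that revert
#' within the debounce window are barrier recrossings, not flips, and are
#' suppressed: excursions shorter than `debounce` are absorbed into the
#' surrounding state.
#'
#' @param x per-frame overall-helicity dihedral angles in degrees, or a
#'   [trajectory()] (then `dihedral_indices` is required)
#' @param dt frame spacing, fs (taken from the trajectory if given)
#' @param debounce minimum dwell for a flip to count, fs (default 100)
#' @param dihedral_indices 4 atom indices (trajectory input only)
#' @return object of class `helicity_trace` with `theta` (debounced -1/+1
#'   per frame), `flip_times` (fs, strictly increasing), `dwell_times` (fs),
#'   `dt`, `debounce`
#' @export
helicity_trace <- function(x, dt = NULL, debounce = 100,
                           dihedral_indices = NULL) {
  if (inherits(x, "trajectory")) {
    stopifnot(!is.null(dihedral_indices))
    dt <- x$dt
    x <- vapply(seq_len(n_frames(x)),
                function(t) dihedral_angle(x$coords[, , t], dihedral_indices),
                numeric(1))
  }
  stopifnot(!is.null(dt), dt > 0)
  d <- dihedral_to_signed(x)
  raw <- sign(d)
  ## tie rule: 0 or 180 inherits the previous state
  for (t in seq_along(raw)) {
    if (raw[t] == 0 || abs(d[t]) == 180) raw[t] <- if (t > 1) raw[t - 1] else 1
  }
  nd <- max(1L, ceiling(debounce / dt))
  r <- rle(raw)
  theta <- raw
  s <- r$values[1]
  flip_frames <- integer(0)
  pos <- 1L
  for (i in seq_along(r$values)) {
    len <- r$lengths[i]; v <- r$values[i]
    if (v != s) {
      if (len >= nd) {          # accepted flip
        s <- v
        flip_frames <- c(flip_frames, pos)
      } else {                  # recrossing: absorb into current state
        theta[pos:(pos + len - 1L)] <- s
      }
    }
    pos <- pos + len
  }
  flip_times <- (flip_frames - 1L) * dt
  dwell <- diff(flip_times)
  structure(list(theta = theta, flip_times = flip_times,
                 dwell_times = dwell, dt = dt, debounce = debounce),
            class = "helicity_trace")
}

#' @export
print.helicity_trace <- function(x, ...) {
  cat(sprintf("<helicity_trace: %d frames, %d flips, debounce %g fs>\n",
              length(x$theta), length(x$flip_times), x$debounce))
  invisible(x)
}

#' Helicity lifetime from the indicator autocorrelation
#'
#' Computes the normalized autocorrelation `C_hel(t)` of the helicity
#' indicator and extracts the lifetime either by integrating `C_hel` up to
#' its first crossing below `threshold` (default, matching the integral
#' definition) or by a least-squares exponential fit. Both estimates are
#' always returned. For a telegraph process with per-direction flip rate k,
#' `C_hel(t) = exp(-2 k t)` and the lifetime is `1/(2k)`.
#'
#' @param trace `helicity_trace` (or a plain -1/+1 vector with `dt` given)
#' @param dt frame spacing, fs (taken from the trace if given)
#' @param method `"integral"` (default) or `"expfit"` selects which estimate
#'   is reported as `tau_ps`
#' @param threshold integration cut-off on the normalized ACF (default 0.01)
#' @param n_blocks blocks for the uncertainty estimate (default 8)
#' @return list with `tau_ps`, `tau_integral_ps`, `tau_expfit_ps`,
#'   `se_ps` (block standard error of the reported estimate), `lower_bound`
#'   (TRUE when the ACF never decorrelates below the threshold), `t_fs`,
#'   `C` (the normalized ACF)
#' @export
helicity_lifetime <- function(trace, dt = NULL,
                              method = c("integral", "expfit"),
                              threshold = 0.01, n_blocks = 8L) {
  method <- match.arg(method)
  if (inherits(trace, "helicity_trace")) {
    theta <- trace$theta; dt <- trace$dt
  } else {
    theta <- trace
    stopifnot(!is.null(dt))
  }
  est <- function(th) {
    lag_max <- min(length(th) - 1L, length(th) %/% 2L)
    C <- acf_fft(th, lag_max = lag_max)
    C <- C / C[1]
    t <- (0:lag_max) * dt
    cross <- which(C < threshold)[1]
    lb <- is.na(cross)
    iend <- if (lb) length(C) else cross
    tau_int <- trapz(t[1:iend], C[1:iend]) / 1000   # fs -> ps
    sel <- which(C[1:iend] > 0.05)
    tau_exp <- tryCatch({
      fit <- stats::lm(log(C[sel]) ~ 0 + t[sel])
      unname(-1 / stats::coef(fit)[1] / 1000)
    }, error = function(e) NA_real_)
    list(tau_int = tau_int, tau_exp = tau_exp, lb = lb, C = C, t = t)
  }
  full <- est(theta)
  ## block uncertainty
  bl <- floor(length(theta) / n_blocks)
  taus <- if (bl > 10) {
    vapply(seq_len(n_blocks), function(b) {
      e <- est(theta[((b - 1) * bl + 1):(b * bl)])
      if (method == "integral") e$tau_int else e$tau_exp
    }, numeric(1))
  } else NA_real_
  se <- if (all(is.na(taus))) NA_real_ else stats::sd(taus, na.rm = TRUE) / sqrt(n_blocks)
  if (full$lb) warning("ACF does not decorrelate within the trace; lifetime is a lower bound")
  list(tau_ps = if (method == "integral") full$tau_int else full$tau_exp,
       tau_integral_ps = full$tau_int, tau_expfit_ps = full$tau_exp,
       se_ps = se, lower_bound = full$lb, t_fs = full$t, C = full$C)
}

#' Classify frames as all-trans or gauche-containing
#'
#' A frame is all-trans iff every backbone dihedral lies within
#' `trans_window` degrees of 180 in absolute value (closed interval: the
#' window edge counts as trans). With the default window of 60 degrees this
#' keeps `|phi| in [120, 180]`, comfortably containing the trans minima near
#' +/-163/197 degrees while excluding gauche states near 60/300 degrees.
#'
#' @param backbone_dihedrals `T x D` matrix of per-frame backbone dihedrals,
#'   degrees
#' @param trans_window half-width of the trans window about 180 degrees
#'   (default 60, must lie in (0, 180))
#' @return character vector per frame: `"all-trans"` or `"gauche-containing"`
#' @export
classify_conformers <- function(backbone_dihedrals, trans_window = 60) {
  stopifnot(trans_window > 0, trans_window < 180)
  d <- abs(dihedral_to_signed(as.matrix(backbone_dihedrals)))
  ok <- rowSums(d < 180 - trans_window) == 0
  ifelse(ok, "all-trans", "gauche-containing")
}

#' Transition-state-theory rate from a free-energy profile
#'
#' `k_TST = nu_attempt * exp(-dF / kBT)` with the barrier taken as the
#' highest point separating the global minimum from the nearest other local
#' minimum. In `"auto"` mode the attempt frequency is estimated from the
#' harmonic curvature at the global minimum,
#' `nu_attempt = sqrt(F''(min)) / (2 pi)` with the profile in kB T and the
#' angle in radians (unit effective inertia; returned rates are then in
#' ps^-1 up to that convention and meaningful in ratios).
#'
#' Candidate minima are filtered by topographic prominence (default 1 kB T)
#' so that counting-noise dips near the barrier top are not mistaken for
#' wells.
#'
#' @param profile `free_energy_profile`
#' @param attempt_frequency attempt frequency in ps^-1, or `"auto"`
#' @param min_prominence minimum depth (kB T) for a local minimum to count
#'   as a well
#' @return list with `rate` (ps^-1), `barrier_kT`, `attempt_ps1`,
#'   `minimum_deg`, `barrier_deg`
#' @export
tst_rate <- function(profile, attempt_frequency = "auto",
                     min_prominence = 1) {
  F <- profile$F
  phi <- profile$angle_grid
  ok <- !is.na(F)
  Fv <- F[ok]; pv <- phi[ok]
  n <- length(Fv)
  if (diff(range(Fv)) < 0.5) stop("analysis error: no barrier found (flat profile)")
  ## local minima on the periodic profile
  lo <- which(Fv <= c(Fv[n], Fv[-n]) & Fv <= c(Fv[-1], Fv[1]))
  gmin <- lo[which.min(Fv[lo])]
  others <- setdiff(lo, gmin)
  ## saddle toward the global minimum along either periodic path; a well
  ## must be separated from the global minimum by a prominent ridge
  path_max <- function(m) {
    idx1 <- if (m > gmin) gmin:m else m:gmin
    idx2 <- if (m > gmin) c(m:n, 1:gmin) else c(gmin:n, 1:m)
    min(max(Fv[idx1]), max(Fv[idx2]))
  }
  saddles <- vapply(others, path_max, numeric(1))
  prom <- saddles - Fv[others]
  keep <- prom >= min_prominence & saddles - Fv[gmin] >= min_prominence
  if (!any(keep)) stop("analysis error: no second minimum found")
  others <- others[keep]; saddles <- saddles[keep]
  best <- which.min(saddles)
  barrier <- saddles[best] - Fv[gmin]
  m <- others[best]
  idx1 <- if (m > gmin) gmin:m else m:gmin
  idx2 <- if (m > gmin) c(m:n, 1:gmin) else c(gmin:n, 1:m)
  btop <- if (max(Fv[idx1]) <= max(Fv[idx2])) {
    idx1[which.max(Fv[idx1])]
  } else idx2[which.max(Fv[idx2])]
  if (identical(attempt_frequency, "auto")) {
    ## quadratic fit of 5 bins around the minimum, curvature per rad^2
    sel <- ((gmin - 3):(gmin + 1)) %% n + 1L
    x <- (pv[sel] - pv[gmin]) * pi / 180
    ## handle wrap
    x <- ifelse(x > pi, x - 2 * pi, ifelse(x < -pi, x + 2 * pi, x))
    cf <- stats::coef(stats::lm(Fv[sel] ~ x + I(x^2)))
    curv <- 2 * cf[3]
    if (!is.finite(curv) || curv <= 0) stop("analysis error: bad curvature at minimum")
    nu_att <- unname(sqrt(curv) / (2 * pi))
  } else {
    nu_att <- attempt_frequency
  }
  list(rate = unname(nu_att * exp(-barrier)), barrier_kT = barrier,
       attempt_ps1 = as.numeric(nu_att), minimum_deg = pv[gmin],
       barrier_deg = pv[btop])
}
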