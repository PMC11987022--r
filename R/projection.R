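#' Project a trajectory onto dual-helicity normal modes
#'
#' Per frame, the molecule is assigned a helicity from the sign of the
#' overall-helicity dihedral, rigidly fitted to the reference structure of
#' matching helicity (carbon-subset fit by default), and the mass-weighted
#' displacement from that reference is projected onto the orthonormal mode
#' vectors: `q_k = eta_k^(h) . sqrt(m) (x_fit - x_ref^(h))`.
#'
#' The default alignment (carbon subset, unit weights) follows the standard
#' trajectory-analysis practice for these chains; with
#' `fit_subset = "all"` and `fit_weights = "mass"` the fit metric matches
#' the Eckart projection of the modes, in which case a frame displaced
#' purely along one mode is recovered exactly (the mass-weighted
#' cross-covariance is symmetric, so the optimal rotation is the identity).
#'
#' @param traj [trajectory()]
#' @param refs [reference_pair()]
#' @param modes_minus,modes_plus `normal_modes` for the two helicities
#' @param fit_subset atom indices used in the rigid fit, or `"all"`;
#'   default: `refs$fit_atom_subset` (the carbon atoms)
#' @param fit_weights `"unit"` (default), `"mass"`, or a numeric vector of
#'   per-subset-atom weights
#' @return object of class `mode_trajectory` with fields `q` (`T x K` normal
#'   coordinates), `helicity_used` (per frame -1/+1), `frame_mask`
#'   (per-frame logical, all `TRUE` initially), `dt`, `frequencies`
#' @export
project_onto_modes <- function(traj, refs, modes_minus, modes_plus,
                               fit_subset = NULL, fit_weights = "unit") {
  n <- dim(traj$coords)[1]
  K <- ncol(modes_plus$eta)
  if (nrow(modes_plus$eta) != 3 * n || nrow(modes_minus$eta) != 3 * n) {
    stop("input error: mode/atom count mismatch")
  }
  if (is.null(fit_subset)) fit_subset <- refs$fit_atom_subset
  if (identical(fit_subset, "all")) fit_subset <- seq_len(n)
  w <- if (identical(fit_weights, "unit")) rep(1, length(fit_subset))
       else if (identical(fit_weights, "mass")) traj$masses[fit_subset]
       else fit_weights
  T <- n_frames(traj)
  sm3 <- rep(sqrt(traj$masses), each = 3)
  q <- matrix(0, T, K)
  hel <- integer(T)
  h_prev <- 1L
  for (t in seq_len(T)) {
    fr <- traj$coords[, , t]
    d <- dihedral_angle(fr, refs$helicity_dihedral)
    h <- if (d == 0 || abs(d) == 180) h_prev else sign(d)
    h_prev <- h
    hel[t] <- h
    ref <- if (h > 0) refs$x_ref_plus else refs$x_ref_minus
    modes <- if (h > 0) modes_plus else modes_minus
    fit <- rigid_fit(fr, ref, subset = fit_subset, weights = w)
    dx <- as.vector(t(fit$x_fit - ref)) * sm3
    q[t, ] <- as.numeric(crossprod(modes$eta, dx))
  }
  structure(list(q = q, helicity_used = hel, frame_mask = rep(TRUE, T),
                 dt = traj$dt, frequencies = modes_plus$frequencies),
            class = "mode_trajectory")
}

#' @export
print.mode_trajectory <- function(x, ...) {
  cat(sprintf("<mode_trajectory: %d frames x %d modes, dt = %g fs>\n",
              nrow(x$q), ncol(x$q), x$dt))
  invisible(x)
}

#' Decompose a molecular dipole into rigid-body and per-mode terms
#'
#' The decomposition is carried out in the body-fixed (fitted) frame, where
#' the rigid-body term is simply the reference dipole of the frame's
#' helicity and each vibrational term is `mu_k^(h) q_k(t)`. The residual
#' (anharmonic/nonlinear remainder) is stored explicitly so
#' `mu_total = mu_rb + sum_k mu_vib_k + residual` holds exactly.
#'
#' @inheritParams project_onto_modes
#' @return object of class `dipole_decomposition` with `mu_total`, `mu_rb`,
#'   `residual` (`T x 3` each), `mu_vib` (array `T x 3 x K`), `q`
#'   (`T x K`), `helicity_used`, `dt`
#' @export
decompose_dipole <- function(traj, refs, modes_minus, modes_plus,
                             fit_subset = NULL, fit_weights = "unit") {
  mt <- project_onto_modes(traj, refs, modes_minus, modes_plus,
                           fit_subset, fit_weights)
  n <- dim(traj$coords)[1]
  if (is.null(fit_subset)) fit_subset <- refs$fit_atom_subset
  if (identical(fit_subset, "all")) fit_subset <- seq_len(n)
  w <- if (identical(fit_weights, "unit")) rep(1, length(fit_subset))
       else if (identical(fit_weights, "mass")) traj$masses[fit_subset]
       else fit_weights
  T <- nrow(mt$q); K <- ncol(mt$q)
  ch <- traj$charges
  mu_ref <- list(`-1` = colSums(ch * refs$x_ref_minus),
                 `1` = colSums(ch * refs$x_ref_plus))
  mu_total <- matrix(0, T, 3)
  mu_rb <- matrix(0, T, 3)
  mu_vib <- array(0, dim = c(T, 3, K))
  for (t in seq_len(T)) {
    h <- mt$helicity_used[t]
    ref <- if (h > 0) refs$x_ref_plus else refs$x_ref_minus
    modes <- if (h > 0) modes_plus else modes_minus
    fit <- rigid_fit(traj$coords[, , t], ref, subset = fit_subset,
                     weights = w)
    mu_total[t, ] <- colSums(ch * fit$x_fit)
    mu_rb[t, ] <- mu_ref[[as.character(h)]]
    mu_vib[t, , ] <- t(modes$transition_dipoles * mt$q[t, ])
  }
  residual <- mu_total - mu_rb - apply(mu_vib, c(1, 2), sum)
  structure(list(mu_total = mu_total, mu_rb = mu_rb, mu_vib = mu_vib,
                 residual = residual, q = mt$q,
                 helicity_used = mt$helicity_used, dt = traj$dt,
                 frequencies = mt$frequencies),
            class = "dipole_decomposition")
}

#' Per-mode vibrational dipole spectra
#'
#' Power spectra of the time derivative of each mode's vibrational dipole
#' `mu_k^vib(t)`, together with the spectrum of the total vibrational dipole
#' `sum_k mu_k^vib`. Because different normal modes are only approximately
#' orthogonal, the relative cross-term (integrated |total - sum of modes|)
#' is reported alongside rather than assumed to vanish.
#'
#' @param decomp `dipole_decomposition`
#' @param ... passed to [power_spectrum()]
#' @return list with `per_mode` (list of `fspec_spectrum`), `total`
#'   (`fspec_spectrum` of the summed vibrational dipole), `cross_term`
#'   (relative integral of `|total - sum of per-mode|`, a conservative
#'   bound that flags correlated/degenerate modes), `closure_err` (signed
#'   integrated-intensity closure error) and `nu`
#' @export
mode_spectra <- function(decomp, ...) {
  K <- dim(decomp$mu_vib)[3]
  dt <- decomp$dt
  per_mode <- vector("list", K)
  for (k in seq_len(K)) {
    dmu <- dipole_derivative(dipole_trace(decomp$mu_vib[, , k], dt))
    per_mode[[k]] <- power_spectrum(dmu, ...)
  }
  tot_series <- apply(decomp$mu_vib, c(1, 2), sum)
  dtot <- dipole_derivative(dipole_trace(tot_series, dt))
  total <- power_spectrum(dtot, ...)
  sum_modes <- Reduce(`+`, lapply(per_mode, function(s) s$values))
  itot <- trapz(total$nu, total$values)
  cross_term <- trapz(total$nu, abs(total$values - sum_modes)) / itot
  closure_err <- abs(itot - trapz(total$nu, sum_modes)) / itot
  list(nu = total$nu, per_mode = per_mode, total = total,
       cross_term = cross_term, closure_err = closure_err)
}

#' Helicity-frozen per-mode spectra
#'
#' The hypothetical spectrum a mode would have if the transition dipole did
#' not change upon helicity reversal (`mu_k^- - mu_k^+ = 0`): the normal
#' coordinate velocity power spectrum scaled by `|mu_k^-|^2`. Compared with
#' the full per-mode spectrum, the difference in line width isolates the
#' broadening contributed by helicity reversal.
#'
#' @param mode_traj `mode_trajectory` (or `dipole_decomposition`)
#' @param modes `normal_modes` supplying the reference transition dipoles
#'   (by convention the minus-helicity set)
#' @param ... passed to [power_spectrum()]
#' @return list of `fspec_spectrum`, one per mode
#' @export
helicity_frozen_spectrum <- function(mode_traj, modes, ...) {
  q <- mode_traj$q
  dt <- mode_traj$dt
  K <- ncol(q)
  mu2 <- rowSums(modes$transition_dipoles^2)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    qd <- dipole_derivative(dipole_trace(q[, k], dt))
    s <- power_spectrum(qd, ...)
    out[[k]] <- spectrum_obj(s$nu, mu2[k] * s$values, kind = "power",
                             metadata = c(s$metadata, list(frozen = TRUE)))
  }
  out
}

#' Event-aligned conditional dipole autocorrelation
#'
#' Averages the dipole autocorrelation over subtrajectory windows positioned
#' so that each helicity-reversal event sits at a fixed offset inside the
#' window, and compares with the unconditional autocorrelation over the
#' whole trace. Envelopes are extracted as analytic-signal magnitudes.
#'
#' @param mu_vib `T x 3` vibrational dipole series of one mode
#' @param dt sampling interval, fs
#' @param events event times, fs (from the start of the series)
#' @param offset position of the event inside each window, fs (default 200)
#' @param window window length, fs (default 2000)
#' @param min_events below this many usable events a statistics warning is
#'   issued (default 20)
#' @return list with `t` (lag grid, fs), `conditional`, `unconditional`
#'   (normalized ACFs; `conditional` is `NULL` when no events fit),
#'   `envelope_conditional`, `envelope_unconditional`, `n_events`
#' @export
event_aligned_acf <- function(mu_vib, dt, events, offset = 200,
                              window = 2000, min_events = 20L) {
  mu_vib <- as.matrix(mu_vib)
  T <- nrow(mu_vib)
  L <- round(window / dt)
  o <- round(offset / dt)
  lag <- seq_len(L) - 1L
  ev_frames <- round(events / dt) + 1L
  starts <- ev_frames - o
  starts <- starts[starts >= 1 & starts + L - 1 <= T]
  n_ev <- length(starts)
  if (n_ev < min_events) {
    warning("statistics warning: only ", n_ev,
            " usable events for conditional averaging")
  }
  uncond <- acf_fft_vec(mu_vib, lag_max = L - 1L)
  uncond <- uncond / uncond[1]
  cond <- NULL; env_c <- NULL
  if (n_ev >= 1) {
    acc <- numeric(L)
    for (s in starts) {
      seg <- mu_vib[s + lag, , drop = FALSE]
      acc <- acc + as.numeric(seg %*% seg[1, ])
    }
    cond <- acc / acc[1]
    env_c <- signal_envelope(cond)
  }
  list(t = lag * dt, conditional = cond, unconditional = uncond,
       envelope_conditional = env_c,
       envelope_unconditional = signal_envelope(uncond),
       n_events = n_ev)
}

#' Mask gauche frames and split into contiguous trans segments
#'
#' Frames failing the mask are dropped and the remaining frames are returned
#' as a list of contiguous segments of at least `min_length` frames, ready
#' for segment-wise spectral estimation (zero-filling masked frames would
#' distort line shapes).
#'
#' @param mode_traj `mode_trajectory`
#' @param mask per-frame logical (`TRUE` = keep), e.g. all-trans frames
#' @param min_length minimum usable segment length in frames (default 512)
#' @return list of `mode_trajectory` objects, one per retained segment
#' @export
split_masked_segments <- function(mode_traj, mask, min_length = 512L) {
  stopifnot(length(mask) == nrow(mode_traj$q))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_length)
  lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    structure(list(q = mode_traj$q[idx, , drop = FALSE],
                   helicity_used = mode_traj$helicity_used[idx],
                   frame_mask = rep(TRUE, length(idx)),
                   dt = mode_traj$dt, frequencies = mode_traj$frequencies),
              class = "mode_trajectory")
  })
}
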