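#' Dipole time series
#'
#' @param values `T x 3` matrix of dipole vectors (e Angstrom), or a numeric
#'   vector for a scalar series
#' @param dt sampling interval, fs
#' @param label `"total"`, a molecule id, or a species name
#' @return object of class `dipole_trace`
#' @export
dipole_trace <- function(values, dt, label = "total") {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("a dipole trace needs at least 2 samples")
  if (!all(is.finite(values))) stop("dipole trace contains non-finite values")
  stopifnot(dt > 0)
  structure(list(values = values, dt = dt, label = label),
            class = "dipole_trace")
}

#' Thermodynamic state of the simulation cell
#'
#' @param volume box volume, Angstrom^3 (> 0)
#' @param temperature absolute temperature, K (> 0)
#' @return object of class `thermo_state`
#' @export
thermo_state <- function(volume, temperature) {
  stopifnot(volume > 0, temperature > 0)
  structure(list(volume = volume, temperature = temperature),
            class = "thermo_state")
}

## Core Welch estimator on a T x k matrix (components summed).
## Convention: v~(omega) = dt * sum_t v_t exp(-i omega t); S = |v~|^2 / t_max,
## averaged over (50% overlapping) segments, one-sided (negative frequencies
## folded). With this normalization,
##   sum(S) * dnu * c_cm_fs = <|v|^2>   (Parseval, rectangle window),
## where dnu is the grid spacing in cm^-1.
welch_psd <- function(x, dt, window = c("hann", "none"), n_segments = 1L,
                      overlap = 0.5, detrend = TRUE) {
  window <- match.arg(window)
  x <- as.matrix(x)
  T <- nrow(x)
  if (T < 16) stop("input error: series too short (need >= 16 samples)")
  L <- floor(T / (1 + (n_segments - 1) * (1 - overlap)))
  if (L < 16) stop("input error: segment length < 16; reduce n_segments")
  L <- smooth_fft_size(L)   # keep the FFT size 5-smooth (mixed-radix speed)
  step <- if (n_segments > 1) floor((T - L) / (n_segments - 1)) else 0L
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  } else rep(1, L)
  w <- w / sqrt(mean(w^2))          # unbiased for white noise
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in seq_len(n_segments)) {
    i0 <- (s - 1L) * step
    for (j in seq_len(ncol(x))) {
      seg <- x[i0 + seq_len(L), j]
      if (detrend) seg <- seg - mean(seg)
      ft <- stats::fft(seg * w)[seq_len(nf)] * dt
      acc <- acc + Mod(ft)^2
    }
  }
  S <- acc / (n_segments * L * dt)
  ## fold negative frequencies (one-sided)
  fold <- rep(2, nf); fold[1] <- 1
  if (L %% 2 == 0) fold[nf] <- 1
  S <- S * fold
  nu <- (seq_len(nf) - 1) / (L * dt) / .c_cm_fs
  list(nu = nu, S = S, L = L, window = window, n_segments = n_segments)
}

#' Power spectrum of a (vector) time series
#'
#' Welch-averaged one-sided power spectral density with the Fourier
#' convention `v~(omega) = integral v(t) exp(-i omega t) dt` and
#' normalization by the segment length `t_max`; vector components are
#' summed. The mean is removed per segment before transforming so DC offsets
#' do not leak into low-frequency bins.
#'
#' @param trace `dipole_trace`, or a numeric vector/matrix with `dt` given
#' @param dt sampling interval in fs (ignored when `trace` is a
#'   `dipole_trace`)
#' @param window `"hann"` (default) or `"none"` (rectangle; use this when
#'   comparing against analytic identities)
#' @param n_segments number of Welch segments (50% overlap)
#' @param detrend remove the per-segment mean before transforming
#' @return `fspec_spectrum` of kind `"power"`; the grid is in cm^-1
#' @export
power_spectrum <- function(trace, dt = NULL, window = c("hann", "none"),
                           n_segments = 1L, detrend = TRUE) {
  window <- match.arg(window)
  if (inherits(trace, "dipole_trace")) {
    x <- trace$values; dt <- trace$dt
  } else {
    if (is.null(dt)) stop("dt required for raw series")
    x <- as.matrix(trace)
  }
  p <- welch_psd(x, dt, window = window, n_segments = n_segments,
                 detrend = detrend)
  spectrum_obj(p$nu[-1], p$S[-1], kind = "power",
               metadata = list(window = p$window, n_segments = p$n_segments,
                               segment_length = p$L, dt = dt,
                               one_sided = TRUE))
}

#' Time derivative of a dipole trace
#'
#' Central finite differences; one-sided differences at the endpoints. The
#' spectral identity `S_dvdv(omega) ~ omega^2 S_vv(omega)` holds well below
#' the Nyquist frequency and is used as a cross-check in the tests, not as
#' the implementation.
#'
#' @param trace `dipole_trace` with at least 3 samples
#' @return `dipole_trace` of the derivative (units per fs)
#' @export
dipole_derivative <- function(trace) {
  x <- trace$values; dt <- trace$dt
  T <- nrow(x)
  if (T < 3) stop("input error: need >= 3 samples for derivatives")
  d <- (x[c(2:T, T), , drop = FALSE] - x[c(1, 1:(T - 1)), , drop = FALSE]) /
    (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[T, ] <- (x[T, ] - x[T - 1, ]) / dt
  dipole_trace(d, dt, label = paste0("d/dt ", trace$label))
}

#' Dielectric susceptibility from total-dipole fluctuations
#'
#' Green-Kubo linear-response susceptibility with the dipole autocorrelation
#' evaluated in the frequency domain (Wiener-Khinchin). The dissipative part
#' is `chi''(omega) = omega S_MM(omega) / (2 * 3 V eps0 kB T)`; the reactive
#' part is reconstructed from it by a Kramers-Kronig (Hilbert) transform.
#' The energy absorption is reported alongside as `omega * chi''`. Only
#' proportionality is physically asserted downstream, so an overall `scale`
#' knob is exposed.
#'
#' @param trace total-system `dipole_trace`
#' @param state `thermo_state` (volume, temperature)
#' @param scale overall multiplicative constant (default 1)
#' @param ... passed to [power_spectrum()] (`window`, `n_segments`)
#' @return `fspec_spectrum` of kind `"susceptibility"` with complex values;
#'   `metadata$absorption` holds `omega * chi''` on the same grid
#' @export
susceptibility <- function(trace, state, scale = 1, ...) {
  if (!inherits(state, "thermo_state")) {
    stop("input error: missing volume/temperature (thermo_state)")
  }
  S <- power_spectrum(trace, ...)
  omega <- wavenumber_to_omega(S$nu)
  pref <- scale / (2 * 3 * state$volume * .eps0 * .kB * state$temperature)
  chi2 <- pref * omega * S$values
  chi1 <- -hilbert_transform(chi2)   # KK partner of the dissipative part
  spectrum_obj(S$nu, complex(real = chi1, imaginary = chi2),
               kind = "susceptibility",
               metadata = c(S$metadata,
                            list(absorption = omega * chi2,
                                 volume = state$volume,
                                 temperature = state$temperature,
                                 scale = scale)))
}

#' Per-species self/cross decomposition of the absorption spectrum
#'
#' Decomposes the power spectrum of the summed dipole derivative into
#' per-species self terms and pairwise cross terms. All spectra are computed
#' with identical segmentation so the identity `total = sum(self) +
#' sum(cross)` holds to numerical precision.
#'
#' @param traces list of per-molecule `dipole_trace` objects
#' @param species character vector of species labels, one per trace
#' @param ... passed to [power_spectrum()]
#' @return list with `total` (`fspec_spectrum`), `self` (named list per
#'   species), `cross` (named list per unordered species pair) and `nu`
#' @export
species_decompose <- function(traces, species, ...) {
  stopifnot(length(traces) >= 1, length(species) == length(traces))
  lens <- vapply(traces, function(tr) nrow(tr$values), 1L)
  if (length(unique(lens)) != 1) stop("input error: traces not aligned in time")
  dts <- vapply(traces, function(tr) tr$dt, 1)
  if (length(unique(dts)) != 1) stop("input error: traces have different dt")
  dt <- dts[1]
  sp <- unique(species)
  ## species-summed derivative series
  deriv <- lapply(traces, function(tr) dipole_derivative(tr)$values)
  sp_sum <- lapply(sp, function(s) Reduce(`+`, deriv[species == s]))
  names(sp_sum) <- sp
  total_series <- Reduce(`+`, sp_sum)
  total <- power_spectrum(total_series, dt = dt, ...)
  self <- lapply(sp_sum, function(x) power_spectrum(x, dt = dt, ...))
  cross <- list()
  if (length(sp) > 1) {
    for (i in seq_len(length(sp) - 1)) {
      for (j in (i + 1):length(sp)) {
        ## cross term via polarization identity: S_{a+b} - S_a - S_b.
        ## Cross spectra may legitimately be negative, so they carry the
        ## neutral "dielectric" kind tag rather than "power".
        sab <- power_spectrum(sp_sum[[i]] + sp_sum[[j]], dt = dt, ...)
        cross[[paste(sp[i], sp[j], sep = ":")]] <-
          spectrum_obj(sab$nu, sab$values - self[[i]]$values - self[[j]]$values,
                       kind = "dielectric", metadata = sab$metadata)
      }
    }
  }
  list(nu = total$nu, total = total, self = self, cross = cross)
}
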