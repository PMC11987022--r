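#' Area-normalized Lorentzian line shape
#'
#' `lorentzian(x, center, fwhm)` integrates to 1 over the real line; the peak
#' height is `2 / (pi * fwhm)`. Multiplying by `area` scales the integral.
#'
#' @param x evaluation grid
#' @param center peak position
#' @param fwhm full width at half maximum (> 0)
#' @param area integrated intensity
#' @return numeric vector of the same length as `x`
#' @export
lorentzian <- function(x, center, fwhm, area = 1) {
  stopifnot(fwhm > 0)
  hw <- fwhm / 2
  area * (hw / pi) / ((x - center)^2 + hw^2)
}

#' Discrete Hilbert transform
#'
#' FFT-based Hilbert transform with the convention H(cos) = sin, so that
#' `x + 1i * hilbert_transform(x)` is the analytic signal. The input is
#' mirror-padded to suppress wrap-around artifacts at the edges.
#'
#' @param x real series
#' @param pad_frac fraction of the series length mirrored onto each end
#' @return real series of the same length: the Hilbert conjugate of `x`
#' @export
hilbert_transform <- function(x, pad_frac = 0.5) {
  n0 <- length(x)
  np <- max(8L, ceiling(n0 * pad_frac))
  np <- min(np, n0 - 1L)
  xp <- c(rev(x[seq_len(np) + 1L]), x, rev(x[n0 - seq_len(np)]))
  n <- length(xp)
  X <- stats::fft(xp)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  Im(z)[np + seq_len(n0)]
}

#' Analytic-signal envelope
#'
#' @param x real oscillatory series
#' @return instantaneous amplitude `|x + i H(x)|`
#' @export
signal_envelope <- function(x) {
  sqrt(x^2 + hilbert_transform(x)^2)
}

## Fast autocorrelation via zero-padded FFT.
## Returns C_j = (1/(T-j)) sum_t x_t x_{t+j} for j = 0..lag_max (unbiased).
acf_fft <- function(x, lag_max = length(x) - 1L, demean = FALSE) {
  n <- length(x)
  if (demean) x <- x - mean(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  lags <- 0:lag_max
  s[lags + 1L] / (n - lags)
}

## Autocorrelation of a T x k matrix summed over columns (e.g. vector dipole).
acf_fft_vec <- function(x, lag_max = nrow(x) - 1L, demean = FALSE) {
  out <- numeric(lag_max + 1L)
  for (j in seq_len(ncol(x))) {
    out <- out + acf_fft(x[, j], lag_max = lag_max, demean = demean)
  }
  out
}

## Trapezoidal integral.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

## Linear-interpolated full width at half maximum of a single peak.
## Used as a fit-free cross-check of the Lorentzian fitter.
fwhm_interp <- function(x, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(i0, 2L)) {
    if (y[i - 1] <= half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
      break
    }
  }
  for (i in seq(i0, length(y) - 1L)) {
    if (y[i + 1] <= half) {
      right <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
      break
    }
  }
  right - left
}

## Deterministic child-seed derivation from a master seed (kept below 2^31).
child_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 7919 + stream * 104729) %% 2147483629)
}

## Largest integer <= n whose prime factors are all in {2, 3, 5}; R's
## mixed-radix FFT is only fast for smooth sizes.
smooth_fft_size <- function(n) {
  is_smooth <- function(m) {
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  m <- as.integer(n)
  while (m > 16L && !is_smooth(m)) m <- m - 1L
  m
}
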