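#' Experimental absorbance spectrum
#'
#' @param nu wavenumber grid, cm^-1, monotone increasing
#' @param absorbance measured values
#' @param acquisition `"transmission"` or `"ATR"`
#' @param resolution spectral resolution, cm^-1 (> 0; 2 cm^-1 is typical for
#'   a benchtop FTIR)
#' @param metadata named list (compound label, solvent, mole fraction, ...)
#' @return object of class `experimental_spectrum`
#' @export
experimental_spectrum <- function(nu, absorbance,
                                  acquisition = c("transmission", "ATR"),
                                  resolution = 2, metadata = list()) {
  acquisition <- match.arg(acquisition)
  stopifnot(length(nu) == length(absorbance), resolution > 0)
  if (any(diff(nu) <= 0)) stop("wavenumber grid must be monotone increasing")
  structure(list(nu = as.numeric(nu), absorbance = as.numeric(absorbance),
                 acquisition = acquisition, resolution = resolution,
                 metadata = metadata),
            class = "experimental_spectrum")
}

#' @export
print.experimental_spectrum <- function(x, ...) {
  cat(sprintf("<experimental_spectrum: %s, %d points, %.0f-%.0f cm^-1, res %g cm^-1>\n",
              x$acquisition, length(x$nu), min(x$nu), max(x$nu), x$resolution))
  invisible(x)
}

#' Read a JCAMP-DX spectrum (simple XYDATA form)
#'
#' Supports the uncompressed `##XYDATA=(X++(Y..Y))` and `(XY..XY)` forms
#' with `XFACTOR`/`YFACTOR` scaling; sufficient for plain exported
#' absorbance spectra.
#'
#' @param path JCAMP-DX file
#' @param acquisition acquisition tag to attach
#' @return `experimental_spectrum`
#' @export
read_jcamp <- function(path, acquisition = "transmission") {
  lines <- readLines(path)
  get_field <- function(key, default = NA) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xf <- get_field("XFACTOR", 1); yf <- get_field("YFACTOR", 1)
  res <- get_field("RESOLUTION", 2)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("format error: no XYDATA block")
  end <- grep("^##END", lines)
  end <- end[end > start][1]
  body <- lines[(start + 1):(end - 1)]
  xs <- c(); ys <- c()
  if (grepl("XY..XY", lines[start], fixed = TRUE)) {
    for (b in body) {
      pr <- strsplit(trimws(b), "[;,[:space:]]+")[[1]]
      v <- as.numeric(pr)
      xs <- c(xs, v[seq(1, length(v), 2)]); ys <- c(ys, v[seq(2, length(v), 2)])
    }
  } else {
    firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
    npt <- get_field("NPOINTS")
    for (b in body) {
      v <- as.numeric(strsplit(trimws(b), "[[:space:]]+")[[1]])
      ys <- c(ys, v[-1])
    }
    xs <- seq(firstx, lastx, length.out = npt) / xf
  }
  ord <- order(xs * xf)
  experimental_spectrum(xs[ord] * xf, ys[ord] * yf,
                        acquisition = acquisition, resolution = res)
}

#' Kramers-Kronig separation of an ATR spectrum
#'
#' ATR absorbance mixes the transmission-like component (proportional to
#' Im(eps)) with a dispersive, reflection-like component (its Hilbert
#' conjugate). Because the two are a Kramers-Kronig pair, a single global
#' phase rotation of the analytic signal recovers the absorptive part:
#' `Im(eps) = m cos(phi) - H(m) sin(phi)` with the default ATR phase
#' `phi = 90` degrees. The dispersive residue is returned alongside for
#' inspection. `phase_offset = "fit"` chooses the phase minimizing the
#' negative lobes of the recovered absorptive component.
#'
#' The constant (DC) component of the absorptive spectrum is not encoded in
#' a purely dispersive trace and cannot be recovered by the phase rotation;
#' with `anchor_edges = TRUE` (default) the recovered component is
#' re-anchored so the band-free window edges sit at zero, the spectroscopic
#' baseline convention.
#'
#' @param spec `experimental_spectrum` with `acquisition = "ATR"`;
#'   non-uniform grids are resampled
#' @param phase_offset global phase in degrees (default 90), or `"fit"`
#' @param anchor_edges re-anchor the recovered baseline using the outer
#'   `edge_frac` of the grid on each side
#' @param edge_frac fraction of points per edge used for anchoring
#' @return `fspec_spectrum` of kind `"dielectric"` holding the recovered
#'   transmission-like component; `metadata$residual` holds the
#'   reflection-like component and `metadata$phase` the phase used
#' @export
kk_separate <- function(spec, phase_offset = 90, anchor_edges = TRUE,
                        edge_frac = 0.02) {
  if (spec$acquisition != "ATR") {
    warning("not an ATR spectrum; returning input unchanged")
    return(spectrum_obj(spec$nu, spec$absorbance, kind = "dielectric",
                        metadata = list(phase = 0, passthrough = TRUE)))
  }
  nu <- spec$nu; m <- spec$absorbance
  dn <- diff(nu)
  if (max(dn) - min(dn) > 1e-6 * mean(dn)) {
    grid <- seq(min(nu), max(nu), length.out = length(nu))
    m <- stats::approx(nu, m, xout = grid)$y
    nu <- grid
  }
  ## periodic (unpadded) Hilbert operator: the phase rotation is then
  ## exactly unitary on the band, and only the DC component is lost
  Hm <- hilbert_transform(m, pad_frac = 0)
  recover <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    m * cos(phi) - Hm * sin(phi)
  }
  if (identical(phase_offset, "fit")) {
    obj <- function(phi) { u <- recover(phi); sum(pmin(u - mean(u), 0)^2) }
    phase_offset <- stats::optimize(obj, c(-180, 180))$minimum
  }
  u <- recover(phase_offset)
  if (anchor_edges) {
    ne <- max(2L, ceiling(edge_frac * length(u)))
    u <- u - mean(u[c(seq_len(ne), length(u) - seq_len(ne) + 1L)])
  }
  phi <- phase_offset * pi / 180
  v <- m * sin(phi) + Hm * cos(phi)
  spectrum_obj(nu, u, kind = "dielectric",
               metadata = list(phase = phase_offset, residual = v))
}

## Second-derivative-Lorentzian wavelet, peaked positive at the origin:
## psi_gamma(x) = -(d^2/dx^2) [ (gamma/pi) / (x^2 + gamma^2) ]
sdl_wavelet <- function(x, gamma) {
  (2 * gamma / pi) * (gamma^2 - 3 * x^2) / (x^2 + gamma^2)^3
}

## CWT coefficients of `y` on grid spacing `dx` at one scale.
cwt_coeffs <- function(y, dx, gamma) {
  half <- ceiling(10 * gamma / dx)
  k <- sdl_wavelet((-half:half) * dx, gamma) * dx
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  out <- stats::filter(ypad, k, method = "convolution", sides = 2)
  as.numeric(out[half + seq_len(n)])
}

#' Wavelet-based peak detection
#'
#' Continuous wavelet transform with a second-derivative Lorentzian
#' analyzing function on a ladder of scale parameters gamma (default 3-6
#' cm^-1). Peak candidates are coefficient maxima forming ridge lines that
#' persist across at least `min_scales` scales and exceed a per-scale noise
#' threshold of `snr_mult` times the median absolute deviation of that
#' scale's coefficients. Ridges are seeded at the coarsest scale (best
#' coefficient-to-noise ratio for broad bands) and tracked toward the
#' finest; each reported center is the coefficient-weighted mean of the
#' quadratically refined ridge positions.
#'
#' @param spec `experimental_spectrum` or `fspec_spectrum`
#' @param gamma_range scale range in cm^-1 (within `[1, 20]`; grid spacing
#'   must be at most `gamma_min / 2`)
#' @param n_scales size of the gamma ladder (default 7)
#' @param min_scales ridge persistence requirement (default 3)
#' @param snr_mult noise threshold multiplier (default 5)
#' @return data.frame with `center` (cm^-1), `n_scales` (ridge length),
#'   `coef` (finest-scale coefficient) and `unresolved` (TRUE for members of
#'   pairs closer than `2 * gamma_min`); zero rows for a flat spectrum
#' @export
detect_peaks <- function(spec, gamma_range = c(3, 6), n_scales = 7L,
                         min_scales = 3L, snr_mult = 5) {
  stopifnot(gamma_range[1] >= 1, gamma_range[2] <= 20,
            gamma_range[1] < gamma_range[2])
  nu <- spec$nu
  y <- if (inherits(spec, "experimental_spectrum")) spec$absorbance else Re(spec$values)
  dx <- stats::median(diff(nu))
  if (dx > gamma_range[1] / 2) {
    stop("grid spacing ", signif(dx, 3), " exceeds gamma_min/2")
  }
  gammas <- seq(gamma_range[1], gamma_range[2], length.out = n_scales)
  C <- vapply(gammas, function(g) cwt_coeffs(y, dx, g), numeric(length(y)))
  locmax <- function(v) which(v > c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf))
  ## seed ridges at the coarsest scale, where broad weak bands have the
  ## best coefficient-to-noise ratio, then track down to the finest scale
  thr <- snr_mult * stats::mad(C[, n_scales])
  cand <- locmax(C[, n_scales])
  cand <- cand[C[cand, n_scales] > thr]
  if (!length(cand)) {
    return(data.frame(center = numeric(0), n_scales = integer(0),
                      coef = numeric(0), unresolved = logical(0)))
  }
  ## sub-bin refinement: quadratic fit of the coefficient row over a
  ## +/- gamma window (a 3-point parabola is noise-dominated for bands much
  ## broader than the wavelet)
  refine <- function(pos, s) {
    w <- max(3L, round(gammas[s] / dx))
    idx <- max(1, pos - w):min(length(nu), pos + w)
    cf <- tryCatch(stats::coef(stats::lm(C[idx, s] ~ nu[idx] + I(nu[idx]^2))),
                   error = function(e) NULL)
    if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) return(nu[pos])
    ctr <- -cf[2] / (2 * cf[3])
    if (abs(ctr - nu[pos]) > gammas[s]) nu[pos] else ctr
  }
  res <- lapply(cand, function(i) {
    pos <- i; nlink <- 1L
    rp <- refine(i, n_scales); rw <- C[i, n_scales]
    for (s in rev(seq_len(n_scales - 1L))) {
      mx <- locmax(C[, s])
      mx <- mx[C[mx, s] > snr_mult * stats::mad(C[, s])]
      if (!length(mx)) break
      j <- mx[which.min(abs(nu[mx] - nu[pos]))]
      if (abs(nu[j] - nu[pos]) <= gammas[s + 1L]) {
        nlink <- nlink + 1L; pos <- j
        rp <- c(rp, refine(j, s)); rw <- c(rw, C[j, s])
      } else break
    }
    ## center: coefficient-weighted mean of the refined ridge positions
    c(center = sum(rp * rw) / sum(rw), n_scales = nlink,
      coef = C[pos, n_scales - nlink + 1L])
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- out[out$n_scales >= min_scales, , drop = FALSE]
  out <- out[!duplicated(round(out$center / dx)), , drop = FALSE]
  out <- out[order(out$center), , drop = FALSE]
  out$unresolved <- FALSE
  if (nrow(out) > 1) {
    gap <- diff(out$center)
    close_pair <- gap < 2 * gamma_range[1]
    out$unresolved <- c(close_pair, FALSE) | c(FALSE, close_pair)
  }
  rownames(out) <- NULL
  out
}

#' Constrained Lorentzian band deconvolution
#'
#' Least-squares fit of a sum of Lorentzian bands with the peak centers
#' clamped exactly at the supplied positions; intensities (areas) and
#' bandwidths are the free parameters. An optional linear baseline can be
#' floated. Bands whose fitted area falls below `degenerate_tol` times the
#' largest band are flagged degenerate.
#'
#' @param spec `experimental_spectrum` or `fspec_spectrum`
#' @param centers fixed peak centers, cm^-1 (must lie within the grid)
#' @param baseline fit an additive linear baseline (default FALSE)
#' @param fwhm_start initial bandwidth guess, cm^-1 (default 10)
#' @param degenerate_tol relative area below which a band is flagged
#' @return a `peak_table`: data.frame with columns `center`, `fwhm`,
#'   `fwhm_se`, `area`, `area_se`, `height`, `assignment` (NA until
#'   [assign_bands()]), `degenerate`; attributes `residual_rms` and
#'   `normalization_reference`
#' @export
fit_lorentzians <- function(spec, centers, baseline = FALSE,
                            fwhm_start = 10, degenerate_tol = 1e-6) {
  nu <- spec$nu
  y <- if (inherits(spec, "experimental_spectrum")) spec$absorbance else Re(spec$values)
  stopifnot(all(centers >= min(nu) & centers <= max(nu)))
  nb <- length(centers)
  dx <- stats::median(diff(nu))
  model <- function(p) {
    v <- numeric(length(nu))
    for (i in seq_len(nb)) {
      v <- v + lorentzian(nu, centers[i], p[nb + i], area = p[i])
    }
    if (baseline) v <- v + p[2 * nb + 1] + p[2 * nb + 2] * (nu - mean(nu))
    v
  }
  h0 <- vapply(centers, function(c0) max(y[abs(nu - c0) < 2 * fwhm_start], 0),
               numeric(1))
  p0 <- c(pmax(h0 * pi * fwhm_start / 2, 1e-8), rep(fwhm_start, nb))
  lower <- c(rep(0, nb), rep(max(dx, 1e-3), nb))
  upper <- c(rep(Inf, nb), rep(diff(range(nu)), nb))
  if (baseline) {
    p0 <- c(p0, 0, 0); lower <- c(lower, -Inf, -Inf); upper <- c(upper, Inf, Inf)
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || fit$info == 9) {
    stop("fit did not converge (info = ", fit$info, "); last residual RMS = ",
         signif(sqrt(mean(fit$fvec^2)), 4))
  }
  p <- fit$par
  se <- tryCatch(sqrt(diag(2 * mean(fit$fvec^2) *
                             solve(fit$hessian))), error = function(e) rep(NA_real_, length(p)))
  areas <- p[seq_len(nb)]; fwhms <- p[nb + seq_len(nb)]
  degen <- areas < degenerate_tol * max(areas, 1e-300) | areas < 1e-12
  tab <- data.frame(center = centers, fwhm = fwhms,
                    fwhm_se = se[nb + seq_len(nb)], area = areas,
                    area_se = se[seq_len(nb)],
                    height = areas * 2 / (pi * fwhms),
                    assignment = NA_character_, degenerate = degen)
  attr(tab, "residual_rms") <- sqrt(mean(fit$fvec^2))
  attr(tab, "normalization_reference") <- NA_character_
  class(tab) <- c("peak_table", "data.frame")
  tab
}

#' Assign bands by nearest nominal center
#'
#' Matches fitted band centers to a lookup table of nominal band positions
#' within a tolerance; unmatched bands are labeled `"other"`. The default
#' table covers the C-F stretching region band assignments.
#'
#' @param table `peak_table`
#' @param lookup named numeric vector `c(label = nominal_center, ...)`
#' @param tol matching tolerance, cm^-1 (default 10)
#' @return the `peak_table` with the `assignment` column filled
#' @export
assign_bands <- function(table,
                         lookup = c("nu_a_OP(CF3)" = 1236,
                                    "nu_a_IP(CF3)" = 1220,
                                    "nu_s(CF2)" = 1135,
                                    "nu_s(CF3)" = 1353,
                                    "rho_IP(CH3)" = 1020),
                         tol = 10) {
  for (i in seq_len(nrow(table))) {
    d <- abs(lookup - table$center[i])
    j <- which.min(d)
    table$assignment[i] <- if (d[j] <= tol) names(lookup)[j] else "other"
  }
  table
}

#' Normalize band areas to a reference band
#'
#' @param table `peak_table` with assignments
#' @param reference assignment label of the normalization band (e.g.
#'   `"nu_s(CF2)"`)
#' @return `peak_table` with `norm_area` and `height_ratio` columns; the
#'   reference is recorded in the `normalization_reference` attribute
#' @export
normalize_bands <- function(table, reference) {
  i <- which(table$assignment == reference)
  if (length(i) != 1) stop("normalization error: reference band '",
                           reference, "' not present exactly once")
  if (!(table$area[i] > 0)) stop("normalization error: reference band area is zero")
  table$norm_area <- table$area / table$area[i]
  table$height_ratio <- table$height / table$height[i]
  attr(table, "normalization_reference") <- reference
  table
}

#' Band trends across a labeled spectrum series
#'
#' Collects per-band normalized areas, FWHMs and height ratios across a
#' series of peak tables labeled by mole fraction or chain length, and fits
#' a least-squares line per band when at least 3 labeled points are
#' available (otherwise the series is returned and the fit is omitted with
#' a notice).
#'
#' @param tables list of `peak_table` objects (normalized)
#' @param labels numeric labels, one per table (mole fraction or chain
#'   length N)
#' @param label_name name for the label column (default `"label"`)
#' @return list with `series` (long data.frame: label, assignment, center,
#'   fwhm, area, norm_area, height_ratio) and `fits` (per band: slope,
#'   intercept, r_squared for `fwhm ~ label` and `norm_area ~ label`), the
#'   latter `NULL` with a message when fewer than 3 points
#' @export
trend_analysis <- function(tables, labels, label_name = "label") {
  stopifnot(length(tables) == length(labels))
  rows <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    data.frame(label = labels[i], assignment = tb$assignment,
               center = tb$center, fwhm = tb$fwhm, area = tb$area,
               norm_area = if ("norm_area" %in% names(tb)) tb$norm_area else NA,
               height_ratio = if ("height_ratio" %in% names(tb)) tb$height_ratio else NA)
  })
  series <- do.call(rbind, rows)
  names(series)[1] <- label_name
  fits <- NULL
  if (length(tables) >= 3) {
    fits <- do.call(rbind, lapply(split(series, series$assignment), function(d) {
      if (nrow(d) < 3) return(NULL)
      f1 <- stats::lm(fwhm ~ d[[label_name]], data = d)
      f2 <- stats::lm(norm_area ~ d[[label_name]], data = d)
      ## constant series fit perfectly; the summary warning is expected
      s1 <- suppressWarnings(summary(f1))
      s2 <- suppressWarnings(summary(f2))
      data.frame(assignment = d$assignment[1],
                 fwhm_slope = stats::coef(f1)[2],
                 fwhm_intercept = stats::coef(f1)[1],
                 fwhm_r2 = s1$r.squared,
                 area_slope = stats::coef(f2)[2],
                 area_r2 = s2$r.squared)
    }))
    if (!is.null(fits)) rownames(fits) <- NULL
  } else {
    message("fewer than 3 labeled tables; linear fits omitted")
  }
  list(series = series, fits = fits)
}
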