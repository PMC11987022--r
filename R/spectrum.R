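#' Spectrum container
#'
#' A light container for spectra on a wavenumber grid. `kind` records what the
#' values are: a power spectral density, a (complex) dielectric
#' susceptibility, an absorbance, or a dielectric function component.
#'
#' @param nu wavenumber grid in cm^-1, strictly increasing
#' @param values real or complex values on the grid
#' @param kind one of `"power"`, `"susceptibility"`, `"absorbance"`,
#'   `"dielectric"`
#' @param metadata named list (window, segment count, normalization
#'   reference, ...)
#' @return object of class `fspec_spectrum`
#' @export
spectrum_obj <- function(nu, values,
                         kind = c("power", "susceptibility", "absorbance",
                                  "dielectric"),
                         metadata = list()) {
  kind <- match.arg(kind)
  nu <- as.numeric(nu)
  if (length(nu) != length(values)) {
    stop("`nu` and `values` must have the same length")
  }
  if (any(diff(nu) <= 0)) stop("wavenumber grid must be strictly increasing")
  if (kind == "power" && is.numeric(values)) {
    tol <- 1e-10 * max(abs(values), 1e-300)
    if (any(values < -tol)) stop("power spectrum has negative values")
    values <- pmax(values, 0)
  }
  structure(list(nu = nu, values = values, kind = kind, metadata = metadata),
            class = "fspec_spectrum")
}

#' @export
print.fspec_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f cm^-1>\n",
              x$kind, length(x$nu), min(x$nu), max(x$nu)))
  invisible(x)
}

#' @export
as.data.frame.fspec_spectrum <- function(x, ...) {
  if (is.complex(x$values)) {
    data.frame(nu_cm1 = x$nu, value = Re(x$values), imag = Im(x$values))
  } else {
    data.frame(nu_cm1 = x$nu, value = x$values)
  }
}

#' Integrated intensity of a spectrum
#'
#' Trapezoidal integral over the wavenumber grid, optionally restricted to a
#' band. For one-sided power spectra, multiplying by the speed of light in
#' cm/fs converts the integral back to the mean-square signal (Parseval).
#'
#' @param spec `fspec_spectrum`
#' @param band optional `c(lo, hi)` wavenumber window in cm^-1
#' @return numeric integral
#' @export
integrate_spectrum <- function(spec, band = NULL) {
  nu <- spec$nu
  v <- if (is.complex(spec$values)) Re(spec$values) else spec$values
  if (!is.null(band)) {
    sel <- nu >= band[1] & nu <= band[2]
    nu <- nu[sel]; v <- v[sel]
  }
  trapz(nu, v)
}

#' Write a spectrum to CSV
#'
#' Two columns (`nu_cm1`, `value`) for real spectra, three (`..., imag`) for
#' complex ones.
#'
#' @param spec `fspec_spectrum`
#' @param path output file
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' Read a two/three-column spectrum CSV
#'
#' @param path CSV with columns `nu_cm1`, `value` and optionally `imag`
#' @param kind spectrum kind tag
#' @return `fspec_spectrum`
#' @export
read_spectrum_csv <- function(path, kind = "absorbance") {
  d <- utils::read.csv(path)
  v <- if ("imag" %in% names(d)) complex(real = d$value, imaginary = d$imag) else d$value
  spectrum_obj(d$nu_cm1, v, kind = kind)
}
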