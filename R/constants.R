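## Internal unit system: Angstrom, femtosecond, amu, elementary charge.
## Energies are then in amu A^2/fs^2; conversion constants below are the only
## place where SI values enter.

## speed of light in cm/fs
.c_cm_fs <- 2.99792458e-5

## Boltzmann constant in amu A^2 fs^-2 K^-1
.kB <- 1.380649e-23 / 1.66053906660e-17

## vacuum permittivity in e^2 fs^2 amu^-1 A^-3
## (equivalently 1/(4 pi eps0) = 0.13894 amu A^3 fs^-2 e^-2)
.eps0 <- 1 / (4 * pi * 0.138935458)

#' Convert angular frequency to wavenumber
#'
#' @param omega angular frequency in rad/fs
#' @return wavenumber in cm^-1
#' @keywords internal
omega_to_wavenumber <- function(omega) omega / (2 * pi * .c_cm_fs)

#' Convert wavenumber to angular frequency
#'
#' @param nu wavenumber in cm^-1
#' @return angular frequency in rad/fs
#' @keywords internal
wavenumber_to_omega <- function(nu) nu * 2 * pi * .c_cm_fs
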