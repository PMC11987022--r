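#' Normal-mode analysis of a supplied Hessian
#'
#' Diagonalizes the mass-weighted Hessian after projecting out rigid
#' translations and rotations (Eckart conditions), and attaches point-charge
#' transition dipoles. The Hessian is taken as input (from any engine, or
#' from the synthetic spring-network generator); no force field is evaluated
#' here.
#'
#' Conventions: Cartesian coordinates are flattened atom-major
#' (`x1 y1 z1 x2 ...`). Mode vectors `eta` are orthonormal in mass-weighted
#' space; the Cartesian displacement per unit normal coordinate is
#' `cart_disp[i] = eta[i] / sqrt(m_i)`, and the transition dipole of mode k
#' is `mu_k = sum_i charge_i * cart_disp_i^(k)` (e per sqrt(amu) Angstrom
#' of mass-weighted normal coordinate). With the Hessian in amu/fs^2
#' (energy in amu Angstrom^2/fs^2 per Angstrom^2), eigenvalues are squared
#' angular frequencies in rad^2/fs^2 and are reported as wavenumbers
#' `nu = sqrt(lambda)/(2 pi c)` in cm^-1. Negative eigenvalues among retained
#' modes are flagged as imaginary frequencies (stored with negative sign)
#' with a warning.
#'
#' @param hessian symmetric `3n x 3n` second-derivative matrix (amu/fs^2)
#' @param masses per-atom masses, amu
#' @param reference `n x 3` reference coordinates (Angstrom), used for the
#'   Eckart rotational projection
#' @param charges per-atom point charges (e)
#' @param helicity -1 or +1 tag carried along for dual-helicity bookkeeping
#' @param sym_tol relative tolerance on Hessian asymmetry
#' @return object of class `normal_modes` with fields `frequencies` (cm^-1,
#'   ascending), `eta` (`3n x K` orthonormal mass-weighted mode vectors),
#'   `cart_disp` (`3n x K` Cartesian displacements), `transition_dipoles`
#'   (`K x 3`), `imaginary` (logical flags), `helicity`, `n_removed`,
#'   `masses`, `charges`, `reference`
#' @export
compute_normal_modes <- function(hessian, masses, reference, charges,
                                 helicity = 1L, sym_tol = 1e-8) {
  n <- length(masses)
  stopifnot(all(masses > 0), nrow(hessian) == 3 * n, ncol(hessian) == 3 * n,
            nrow(reference) == n, length(charges) == n)
  asym <- max(abs(hessian - t(hessian)))
  if (asym > sym_tol * max(abs(hessian), 1)) {
    stop("input error: Hessian asymmetry ", signif(asym, 3), " beyond tolerance")
  }
  H <- (hessian + t(hessian)) / 2
  m3 <- rep(masses, each = 3)
  Hmw <- H / sqrt(outer(m3, m3))

  ## rigid-body space in mass-weighted coordinates
  com <- colSums(reference * masses) / sum(masses)
  X <- sweep(reference, 2, com)
  rig <- matrix(0, 3 * n, 6)
  sm <- sqrt(masses)
  for (a in 1:3) {            # translations
    v <- matrix(0, n, 3); v[, a] <- sm
    rig[, a] <- as.vector(t(v))
  }
  ax <- diag(3)
  for (a in 1:3) {            # rotations: sqrt(m) (e_a x (x - com))
    v <- t(apply(X, 1, function(d) cross3(ax[a, ], d))) * sm
    rig[, 3 + a] <- as.vector(t(v))
  }
  qr_rig <- qr(rig)
  n_removed <- qr_rig$rank   # 6 nonlinear, 5 linear
  Qr <- qr.Q(qr_rig)[, seq_len(n_removed), drop = FALSE]

  P <- diag(3 * n) - Qr %*% t(Qr)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  eg <- eigen(Hp, symmetric = TRUE)

  ## drop the n_removed eigenvectors living in the rigid space
  overlap <- colSums((t(Qr) %*% eg$vectors)^2)
  drop_idx <- order(overlap, decreasing = TRUE)[seq_len(n_removed)]
  keep <- setdiff(seq_len(3 * n), drop_idx)
  lam <- eg$values[keep]
  vec <- eg$vectors[, keep, drop = FALSE]
  ord <- order(sign(lam) * sqrt(abs(lam)))
  lam <- lam[ord]; vec <- vec[, ord, drop = FALSE]

  imaginary <- lam < -1e-12
  if (any(imaginary)) {
    warning(sum(imaginary), " imaginary frequencies among retained modes")
  }
  freq <- sign(lam) * omega_to_wavenumber(sqrt(abs(lam)))
  cart <- vec / sqrt(m3)
  tdip <- t(vapply(seq_len(ncol(cart)), function(k) {
    d <- matrix(cart[, k], ncol = 3, byrow = TRUE)
    colSums(charges * d)
  }, numeric(3)))

  structure(list(frequencies = freq, eta = vec, cart_disp = cart,
                 transition_dipoles = tdip, imaginary = imaginary,
                 helicity = as.integer(sign(helicity)), n_removed = n_removed,
                 masses = as.numeric(masses), charges = as.numeric(charges),
                 reference = reference),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes: %d modes (%d rigid removed), helicity %+d, %s-%s cm^-1>\n",
              length(x$frequencies), x$n_removed, x$helicity,
              signif(min(x$frequencies), 4), signif(max(x$frequencies), 4)))
  invisible(x)
}

#' Broaden a stick spectrum with Lorentzian line shapes
#'
#' Each stick becomes a unit-area Lorentzian scaled by its intensity, so the
#' integrated spectrum equals the summed intensities (grid-resolution
#' limited).
#'
#' @param frequencies stick positions, cm^-1
#' @param intensities stick intensities (same length)
#' @param fwhm Lorentzian full width at half maximum, cm^-1 (> 0); the
#'   default 5 cm^-1 is the conventional display width for static
#'   normal-mode spectra
#' @param grid optional wavenumber grid; the default covers all sticks
#'   +/- 10 fwhm at fwhm/20 spacing
#' @return `fspec_spectrum` of kind `"absorbance"`
#' @export
broaden_sticks <- function(frequencies, intensities, fwhm = 5, grid = NULL) {
  if (!length(frequencies)) stop("empty stick list")
  stopifnot(length(frequencies) == length(intensities), fwhm > 0)
  if (is.null(grid)) {
    grid <- seq(min(frequencies) - 10 * fwhm, max(frequencies) + 10 * fwhm,
                by = fwhm / 20)
  }
  v <- numeric(length(grid))
  for (i in seq_along(frequencies)) {
    v <- v + lorentzian(grid, frequencies[i], fwhm, area = intensities[i])
  }
  spectrum_obj(grid, v, kind = "absorbance",
               metadata = list(fwhm = fwhm, n_sticks = length(frequencies)))
}

#' Write a normal-mode set to plain-text files
#'
#' Serializes frequencies, transition dipoles and flags to a CSV, and the
#' mass-weighted mode vectors to a whitespace-delimited dense matrix file.
#'
#' @param modes `normal_modes`
#' @param prefix output path prefix; writes `<prefix>_modes.csv` and
#'   `<prefix>_eta.txt`
#' @export
write_normal_modes <- function(modes, prefix) {
  info <- data.frame(frequency_cm1 = modes$frequencies,
                     mu_x = modes$transition_dipoles[, 1],
                     mu_y = modes$transition_dipoles[, 2],
                     mu_z = modes$transition_dipoles[, 3],
                     imaginary = modes$imaginary,
                     helicity = modes$helicity)
  utils::write.csv(info, paste0(prefix, "_modes.csv"), row.names = FALSE)
  utils::write.table(modes$eta, paste0(prefix, "_eta.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a dense Hessian from a whitespace-delimited text file
#'
#' @param path text file with `3n` rows of `3n` numbers (amu/fs^2)
#' @return numeric matrix
#' @export
read_hessian <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
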