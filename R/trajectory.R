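#' Trajectory container
#'
#' Time series of atomic coordinates with fixed topology. Internal units are
#' Angstrom, femtosecond, amu and elementary charge throughout the package;
#' GRO files (nm) are converted on read.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or a list
#'   of `n_atoms x 3` matrices
#' @param dt time step between frames in fs (> 0)
#' @param masses per-atom masses in amu (> 0)
#' @param charges per-atom point charges in units of the elementary charge
#' @param atom_labels optional character vector (element + index)
#' @param molecule_ids integer vector grouping atoms into molecules
#'   (default: all atoms in molecule 1)
#' @param box optional 3-vector of box lengths in Angstrom
#' @return object of class `trajectory`
#' @export
trajectory <- function(coords, dt, masses, charges,
                       atom_labels = NULL, molecule_ids = NULL, box = NULL) {
  if (is.list(coords)) {
    dims <- vapply(coords, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3)) {
      stop("inconsistent coordinate dimensions across frames")
    }
    coords <- array(unlist(coords), dim = c(dims[1, 1], 3, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  n <- dim(coords)[1]; nt <- dim(coords)[3]
  if (nt < 2) stop("a trajectory needs at least 2 frames")
  if (!(is.numeric(dt) && length(dt) == 1 && dt > 0)) stop("dt must be a positive scalar (fs)")
  if (length(masses) != n || any(masses <= 0)) stop("masses must be positive, one per atom")
  if (length(charges) != n) stop("charges must have one entry per atom")
  if (is.null(molecule_ids)) molecule_ids <- rep(1L, n)
  if (length(molecule_ids) != n || anyNA(molecule_ids)) {
    stop("every atom must belong to exactly one molecule")
  }
  if (is.null(atom_labels)) atom_labels <- paste0("X", seq_len(n))
  structure(list(coords = coords, dt = dt, masses = as.numeric(masses),
                 charges = as.numeric(charges), atom_labels = atom_labels,
                 molecule_ids = as.integer(molecule_ids), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d atoms, %d frames, dt = %g fs>\n",
              dim(x$coords)[1], dim(x$coords)[3], x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj `trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an `n x 3` matrix
#' @param traj `trajectory`
#' @param i frame index
#' @return `n_atoms x 3` coordinate matrix
#' @export
get_frame <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a topology table
#'
#' Topology supplies per-atom masses, charges and molecule ids. Accepted
#' formats: CSV with columns `atom_index, element, mass, charge, molecule_id`,
#' or a JSON object with those arrays.
#'
#' @param path file path (.csv or .json)
#' @return data.frame with the topology columns, ordered by `atom_index`
#' @export
read_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  top <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  need <- c("atom_index", "element", "mass", "charge", "molecule_id")
  miss <- setdiff(need, names(top))
  if (length(miss)) stop("topology error: missing columns ", paste(miss, collapse = ", "))
  top[order(top$atom_index), , drop = FALSE]
}

#' Read a multi-frame XYZ or GRO trajectory
#'
#' XYZ files are assumed to be in Angstrom; GRO files are in nm and converted
#' to Angstrom on read. The topology (a file path or an inline data.frame as
#' produced by [read_topology()]) supplies masses, charges and molecule ids.
#'
#' @param path coordinate file (`.xyz` or `.gro`)
#' @param topology topology file path or data.frame
#' @param dt time step between frames in fs
#' @return [trajectory()]
#' @export
read_trajectory <- function(path, topology, dt) {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    xyz = parse_xyz(path),
    gro = parse_gro(path),
    stop("format error: unsupported trajectory format '", ext, "'"))
  top <- if (is.character(topology)) read_topology(topology) else topology
  n <- dim(parsed$coords)[1]
  if (nrow(top) != n) {
    stop("topology error: ", nrow(top), " topology rows for ", n, " atoms")
  }
  if (anyNA(top$mass) || anyNA(top$charge)) {
    stop("topology error: missing masses/charges")
  }
  trajectory(parsed$coords, dt = dt, masses = top$mass, charges = top$charge,
             atom_labels = paste0(top$element, top$atom_index),
             molecule_ids = top$molecule_id, box = parsed$box)
}

## Multi-frame XYZ parser. Element symbols from the file are kept but the
## topology remains authoritative for masses and charges.
parse_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); i <- 1L; n0 <- NA_integer_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("format error: expected atom count at line ", i)
    if (is.na(n0)) n0 <- n
    if (n != n0) stop("format error: inconsistent atom count across frames (",
                      n, " vs ", n0, ")")
    if (i + 1L + n > length(lines)) stop("format error: truncated frame")
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    bad <- vapply(parts, length, 1L) < 4L
    if (any(bad)) stop("format error: malformed atom line")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("format error: non-numeric coordinates")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("format error: no frames found")
  list(coords = array(unlist(frames), dim = c(n0, 3, length(frames))), box = NULL)
}

## Multi-frame GRO parser (fixed-width positions, nm -> Angstrom).
parse_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; n0 <- NA_integer_; box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("format error: expected atom count at line ", i + 1L)
    if (is.na(n0)) n0 <- n
    if (n != n0) stop("format error: inconsistent atom count across frames")
    rows <- lines[(i + 2L):(i + 1L + n)]
    xyz <- t(vapply(rows, function(r) {
      c(as.numeric(substr(r, 21, 28)), as.numeric(substr(r, 29, 36)),
        as.numeric(substr(r, 37, 44)))
    }, numeric(3), USE.NAMES = FALSE))
    if (anyNA(xyz)) stop("format error: malformed GRO coordinate field")
    frames[[length(frames) + 1L]] <- xyz * 10  # nm -> Angstrom
    boxline <- strsplit(trimws(lines[i + 2L + n]), "[[:space:]]+")[[1]]
    box <- as.numeric(boxline[1:3]) * 10
    i <- i + 3L + n
  }
  if (!length(frames)) stop("format error: no frames found")
  list(coords = array(unlist(frames), dim = c(n0, 3, length(frames))), box = box)
}

#' Rigid-body superposition onto a reference structure
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) mean-square distance between a subset of atoms of `frame` and
#' `reference` (Kabsch algorithm via SVD). Reflections are excluded even when
#' a reflection would give a lower residual: the mirror conformer is
#' represented by its own reference structure, and an improper fit would
#' silently swap helicity.
#'
#' @param frame `n x 3` coordinates to fit
#' @param reference `n x 3` target coordinates
#' @param subset atom indices used in the fit (default: all); at least 3
#'   non-collinear atoms
#' @param weights per-subset-atom weights (default: unit weights; pass masses
#'   for a mass-weighted fit)
#' @return list of class `fit_result` with `rotation` (proper 3x3 matrix),
#'   `translation` (3-vector), `rmsd` (Angstrom, over the fit subset) and
#'   `x_fit` (all atoms, fitted coordinates); `x_fit = rotation %*% x +
#'   translation` maps the frame into the reference frame
#' @export
rigid_fit <- function(frame, reference, subset = NULL, weights = NULL) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  stopifnot(ncol(frame) == 3, all(dim(frame) == dim(reference)))
  if (is.null(subset)) subset <- seq_len(nrow(frame))
  if (length(subset) < 3) stop("geometry error: fit subset needs >= 3 atoms")
  if (is.null(weights)) weights <- rep(1, length(subset))
  stopifnot(length(weights) == length(subset), all(weights > 0))
  w <- weights / sum(weights)
  P <- frame[subset, , drop = FALSE]
  Q <- reference[subset, , drop = FALSE]
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  ## collinearity check: centered subset must span a plane
  sv <- svd(Pc * sqrt(w))$d
  if (sv[2] < 1e-8 * max(1, sv[1])) {
    stop("geometry error: fit subset is (near-)collinear")
  }
  C <- crossprod(Qc * w, Pc)            # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- cq - as.numeric(R %*% cp)
  x_fit <- t(R %*% t(frame)) + matrix(translation, nrow(frame), 3, byrow = TRUE)
  dev <- x_fit[subset, , drop = FALSE] - Q
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 x_fit = x_fit),
            class = "fit_result")
}

#' Signed dihedral angle
#'
#' IUPAC sign convention: looking along the central bond, a clockwise
#' rotation of the far bond relative to the near bond is positive. The value
#' is in (-180, 180] degrees.
#'
#' @param coords `n x 3` coordinate matrix
#' @param indices 4 distinct atom indices
#' @return signed angle in degrees
#' @export
dihedral_angle <- function(coords, indices) {
  stopifnot(length(indices) == 4)
  if (anyDuplicated(indices)) stop("geometry error: dihedral atoms must be distinct")
  p <- coords[indices, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  if (min(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2))) < 1e-10) {
    stop("geometry error: coincident consecutive atoms in dihedral")
  }
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert signed dihedrals to the 0-360 degree convention
#' @param x signed angles in degrees
#' @return angles in [0, 360)
#' @export
dihedral_to_0360 <- function(x) x %% 360

#' Convert 0-360 degree dihedrals to the signed (-180, 180] convention
#' @param x angles in degrees
#' @return signed angles in (-180, 180]
#' @export
dihedral_to_signed <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Reference-structure pair for the two helicities
#'
#' The two references must be mirror conformers: the overall-helicity
#' dihedral has opposite sign in the two structures.
#'
#' @param x_ref_minus,x_ref_plus `n x 3` geometry-optimized coordinates
#'   (Angstrom) of the left- and right-handed helix
#' @param fit_atom_subset indices used for the rigid fit (default supplied by
#'   the caller; typically the carbon atoms)
#' @param helicity_dihedral 4 atom indices defining the overall-helicity
#'   dihedral
#' @return object of class `reference_pair`
#' @export
reference_pair <- function(x_ref_minus, x_ref_plus, fit_atom_subset,
                           helicity_dihedral) {
  stopifnot(all(dim(x_ref_minus) == dim(x_ref_plus)), length(fit_atom_subset) >= 1)
  dm <- dihedral_angle(x_ref_minus, helicity_dihedral)
  dp <- dihedral_angle(x_ref_plus, helicity_dihedral)
  if (sign(dm) * sign(dp) >= 0) {
    stop("reference structures must have opposite helicity-dihedral signs")
  }
  if (dp < 0) {  # store so that "plus" has positive helicity dihedral
    tmp <- x_ref_minus; x_ref_minus <- x_ref_plus; x_ref_plus <- tmp
  }
  structure(list(x_ref_minus = x_ref_minus, x_ref_plus = x_ref_plus,
                 fit_atom_subset = fit_atom_subset,
                 helicity_dihedral = helicity_dihedral),
            class = "reference_pair")
}
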