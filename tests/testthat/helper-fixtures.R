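## Shared fixtures, all built in code.

c_cm_fs <- 2.99792458e-5
kB_int <- 1.380649e-23 / 1.66053906660e-17

## pairwise-distance-spring Hessian block assembly (independent of the
## package's internal assembler; used to build analytic test systems)
spring_pair_hessian <- function(x, pairs) {
  n <- nrow(x)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]; k <- pairs[r, 3]
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

## two unit masses on a unit spring along x, embedded in 3D
two_body_system <- function(k = 1, m = c(1, 1)) {
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  list(x = x, masses = m,
       hessian = spring_pair_hessian(x, matrix(c(1, 2, k), 1)))
}

## symmetric linear triatomic m-M-m with two springs k
triatomic_system <- function(k = 0.5, m = 1, M = 16) {
  x <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(2.4, 0, 0))
  list(x = x, masses = c(m, M, m), k = k, m = m, M = M,
       hessian = spring_pair_hessian(x, rbind(c(1, 2, k), c(2, 3, k))))
}

## cached helical reference system + normal modes (built once per run)
helical_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config()
      sys <- gen_helical_references(cfg)
      mp <- compute_normal_modes(sys$hessian_plus, sys$masses,
                                 sys$refs$x_ref_plus, sys$charges, +1)
      mm <- compute_normal_modes(sys$hessian_minus, sys$masses,
                                 sys$refs$x_ref_minus, sys$charges, -1)
      cache <<- c(sys, list(modes_plus = mp, modes_minus = mm, config = cfg))
    }
    cache
  }
})

## standard 4-band fixture at the C-F band positions; equal peak heights so
## a single signal-to-noise ratio applies to every band
four_band_oscillators <- function() {
  osc <- data.frame(center = c(1045, 1069, 1218, 1276),
                    width = c(10, 15, 20, 25))
  osc$strength <- osc$width / 15
  osc
}

## rotation matrix about z
rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

## brute-force rigid-fit oracle: coarse search over rotations (axis-angle
## grid) refined by Nelder-Mead on the rotation vector
brute_force_fit_rmsd <- function(frame, reference, subset) {
  P <- frame[subset, , drop = FALSE]
  Q <- reference[subset, , drop = FALSE]
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rotvec_to_R <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    R <- rotvec_to_R(v)
    mean(rowSums((Pc %*% t(R) - Qc)^2))
  }
  best <- c(0, 0, 0); bestv <- obj(best)
  for (ax in list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,0,1),
                  c(0,1,1), c(1,1,1))) {
    for (th in seq(0, pi, length.out = 25)) {
      v <- ax / sqrt(sum(ax^2)) * th
      f <- obj(v)
      if (f < bestv) { best <- v; bestv <- f }
      f <- obj(-v)
      if (f < bestv) { best <- -v; bestv <- f }
    }
  }
  o <- stats::optim(best, obj, control = list(reltol = 1e-16, maxit = 5000))
  sqrt(o$value)
}

## write a small multi-frame XYZ + topology CSV into a temp dir
write_xyz_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  xyz <- file.path(dir, "tiny.xyz")
  writeLines(c("3", "frame 1",
               "C 0.0 0.0 0.0", "F 1.0 0.0 0.0", "F -1.0 0.2 0.0",
               "3", "frame 2",
               "C 0.1 0.0 0.0", "F 1.1 0.0 0.0", "F -0.9 0.2 0.0"), xyz)
  topo <- file.path(dir, "tiny_topology.csv")
  utils::write.csv(data.frame(atom_index = 1:3, element = c("C", "F", "F"),
                              mass = c(12.011, 18.998, 18.998),
                              charge = c(0.3, -0.15, -0.15),
                              molecule_id = 1L),
                   topo, row.names = FALSE)
  list(xyz = xyz, topo = topo)
}
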