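# Shared fixtures: tiny hand-made structures and ensemble assembly.

KB <- 0.0019872041

# assemble a trajectory_ensemble from lists of duplex frames (one list per
# run), bypassing the generator
ensemble_from_frames <- function(frames_per_run, burn_in = 0) {
  topo <- frames_per_run[[1]][[1]]
  runs <- lapply(frames_per_run, function(frames) {
    arr <- array(NA_real_, c(nrow(topo$atoms), 3, length(frames)))
    for (f in seq_along(frames)) {
      arr[, , f] <- as.matrix(frames[[f]]$atoms[, c("x", "y", "z")])
    }
    arr
  })
  structure(list(topology = topo, runs = runs, ground_truth = NULL,
                 burn_in = burn_in, config = NULL),
            class = "trajectory_ensemble")
}

# minimal "duplex" with hand-placed atoms (for boundary-geometry tests)
toy_duplex <- function(atoms) {
  atoms$mass <- duplexflip:::ATOMIC_MASS[atoms$element]
  structure(list(atoms = atoms, sequence = NA, pairing = NA,
                 n_pairs = max(atoms$pair)), class = "duplex")
}

# rotation matrix about a unit axis (independent of package internals)
rot_mat <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  t <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# brute-force rigid-superposition oracle: numerical optimization over an
# axis-angle parameterization (independent of the Kabsch path)
brute_force_superpose <- function(ref, obs) {
  objective <- function(p) {
    ang <- sqrt(sum(p[1:3]^2))
    R <- if (ang < 1e-12) diag(3) else rot_mat(p[1:3] / ang, ang * 180 / pi)
    moved <- ref %*% t(R)
    moved <- sweep(moved, 2, colMeans(obs) - colMeans(moved), "+")
    sum((obs - moved)^2)
  }
  best <- NULL
  for (start in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3), c(2, 2, 1))) {
    o <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  sqrt(best$value / nrow(ref))
}

# independent four-point dihedral (plane-normal construction, converted to
# the package's [0, 360) convention)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosv))) * 180 / pi
  if (sum(pracma_cross(n1, n2) * b2) < 0) ang <- -ang
  ang %% 360
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
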