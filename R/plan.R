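# Precomputed per-nucleotide indexing for fast frame construction and
# measurement.  A "plan" caches, for a fixed topology, the template
# coordinate matrices, the atom-row indices of every nucleotide, the ring
# rows used for frame fitting and the rows feeding the lambda/flip
# observables, so per-frame work reduces to small matrix products.

#' @noRd
duplex_plan <- function(topology, flip_spec = NULL) {
  a <- topology$atoms
  n <- topology$n_pairs
  nucs <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    for (s in c("I", "II")) {
      base <- if (s == "I") topology$sequence[i] else topology$pairing[i]
      rows <- which(a$strand == s & a$pair == i)
      tpl <- base_geometry(base)
      tpl <- tpl[match(a$atom[rows], tpl$atom), , drop = FALSE]
      local <- as.matrix(tpl[, c("x", "y", "z")])
      if (s == "II") local <- local %*% FLIP_MAT
      ring <- ring_atom_names(base)
      ring_rows <- rows[match(ring, a$atom[rows])]
      ring_ref <- {
        full <- base_geometry(base)
        as.matrix(full[match(ring, full$atom), c("x", "y", "z")])
      }
      nucs[[(i - 1) * 2 + (s == "II") + 1]] <- list(
        base = base, strand = s, pair = i, rows = rows, local = local,
        ring_rows = ring_rows, ring_ref = ring_ref,
        c1 = rows[match("C1'", a$atom[rows])],
        glyc = rows[match(GLYCOSIDIC_N[[base]], a$atom[rows])])
    }
  }
  plan <- list(n_pairs = n, nucs = nucs, n_atoms = nrow(a), mass = a$mass)
  if (!is.null(flip_spec)) {
    sel <- flip_group_rows(topology, flip_spec)
    plan$flip <- list(spec = flip_spec, groups = sel,
                      w = lapply(sel, function(s) a$mass[s] / sum(a$mass[s])))
  }
  plan
}

#' @noRd
flip_group_rows <- function(topology, spec) {
  lapply(flip_groups(topology, spec), which)
}

#' @noRd
#' Coordinates of a frame from a helical state (matrix-only build path;
#' mirrors build_duplex exactly).
frame_coords <- function(plan, state) {
  out <- matrix(NA_real_, plan$n_atoms, 3)
  pair_frame <- list(R = diag(3), o = c(0, 0, 0))
  for (i in seq_len(plan$n_pairs)) {
    if (i > 1) {
      pair_frame <- cehs_compose(pair_frame, state$step[i - 1, 1:3],
                                 state$step[i - 1, 4:6])$frame
    }
    sp <- cehs_split(pair_frame, state$pair[i, 1:3], state$pair[i, 4:6])
    nI <- plan$nucs[[(i - 1) * 2 + 1]]
    nII <- plan$nucs[[(i - 1) * 2 + 2]]
    out[nI$rows, ] <- sweep(nI$local %*% t(sp$frame_j$R), 2, sp$frame_j$o, "+")
    out[nII$rows, ] <- sweep(nII$local %*% t(sp$frame_i$R), 2, sp$frame_i$o, "+")
  }
  out
}

#' @noRd
#' Inverse: helical state, lambda angles and (optionally) the flip angle
#' from a coordinate matrix.
measure_frame <- function(plan, coords) {
  n <- plan$n_pairs
  pair <- matrix(NA_real_, n, 6, dimnames = list(NULL, PAIR_PARAMS))
  lambda <- matrix(NA_real_, n, 2)
  mids <- vector("list", n)
  for (i in seq_len(n)) {
    nI <- plan$nucs[[(i - 1) * 2 + 1]]
    nII <- plan$nucs[[(i - 1) * 2 + 2]]
    fI <- kabsch(nI$ring_ref, coords[nI$ring_rows, , drop = FALSE])
    fII <- kabsch(nII$ring_ref, coords[nII$ring_rows, , drop = FALSE])
    dec <- cehs_decompose(list(R = fII$R %*% FLIP_MAT, o = fII$t),
                          list(R = fI$R, o = fI$t))
    pair[i, ] <- c(dec$trans, dec$rot)
    mids[[i]] <- list(R = dec$mid$R, o = (fI$t + fII$t) / 2)
    c1i <- coords[nI$c1, ]; c1ii <- coords[nII$c1, ]
    lambda[i, ] <- c(vec_angle(coords[nI$glyc, ] - c1i, c1ii - c1i),
                     vec_angle(coords[nII$glyc, ] - c1ii, c1i - c1ii))
  }
  step <- matrix(NA_real_, max(n - 1, 0), 6, dimnames = list(NULL, STEP_PARAMS))
  for (i in seq_len(max(n - 1, 0))) {
    dec <- cehs_decompose(mids[[i]], mids[[i + 1]])
    step[i, ] <- c(dec$trans, dec$rot)
  }
  out <- list(pair = pair, step = step, lambda = lambda, mids = mids)
  if (!is.null(plan$flip)) {
    coms <- lapply(seq_len(4), function(g) {
      w <- plan$flip$w[[g]]
      as.numeric(w %*% coords[plan$flip$groups[[g]], , drop = FALSE])
    })
    out$flip <- dihedral4(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
  }
  out
}

#' @noRd
#' Rotate the flipping nucleotide in a coordinate matrix so the measured
#' flip angle equals `target` (fast analogue of set_flip_angle).
set_flip_coords <- function(plan, coords, target) {
  g <- plan$flip$groups
  w <- plan$flip$w
  com <- function(k) as.numeric(w[[k]] %*% coords[g[[k]], , drop = FALSE])
  com1 <- com(1); com2 <- com(2); com3 <- com(3); com4 <- com(4)
  cur <- dihedral4(com1, com2, com3, com4)
  delta <- (target - cur) %% 360
  axis <- com3 - com2
  spec <- plan$flip$spec
  nuc_rows <- NULL
  for (nc in plan$nucs) {
    if (nc$strand == spec$strand && nc$pair == spec$pair) nuc_rows <- nc$rows
  }
  apply_rot <- function(ang) {
    R <- rot_axis(axis, ang)
    xyz <- sweep(coords[nuc_rows, , drop = FALSE], 2, com2)
    out <- coords
    out[nuc_rows, ] <- sweep(xyz %*% t(R), 2, com2, "+")
    out
  }
  out <- apply_rot(delta)
  com1b <- as.numeric(w[[1]] %*% out[g[[1]], , drop = FALSE])
  if (abs(((dihedral4(com1b, com2, com3, com4) - target + 180) %% 360) - 180) > 1e-6) {
    out <- apply_rot(-delta)
  }
  out
}
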