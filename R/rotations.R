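# Rigid-body math shared by the builder and the measurement code.
#
# All user-facing angles are degrees; internal trigonometry is radians.
# Rotation matrices act on column vectors (global = R %*% local + origin).

DEG <- pi / 180

rot_z <- function(deg) {
  t <- deg * DEG
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  t <- deg * DEG
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

rot_axis <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  t <- deg * DEG
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# strand-II frame flip about its x-axis: (x, -y, -z)
FLIP_MAT <- diag(c(1, -1, -1))

#' @noRd
#' Decompose the relative rotation/translation between two frames into the
#' six mid-frame ("CEHS-style") helical coordinates.
#'
#' Frames are lists(R = 3x3, o = length-3).  The relative rotation
#' t(Ri) %*% Rj is factored as Rz(w/2 - phi) Ry(gamma) Rz(w/2 + phi); the
#' twist-like coordinate is w, the tilt-like and roll-like coordinates are
#' gamma*sin(phi) and gamma*cos(phi), and the translations are the
#' displacement o_j - o_i expressed in the mid-frame.  Exact inverse of
#' cehs_compose()/cehs_split().
cehs_decompose <- function(frame_i, frame_j) {
  A <- crossprod(frame_i$R, frame_j$R)
  szz <- sqrt(A[1, 3]^2 + A[2, 3]^2)
  if (A[3, 3] < 0) {
    stop("frames are not near-parallel (z.z' < 0): antiparallel pairing violation")
  }
  if (szz < 1e-12) {
    gamma <- 0
    a <- atan2(A[2, 1], A[1, 1]) / 2
    b <- a
  } else {
    gamma <- atan2(szz, A[3, 3])
    a <- atan2(A[2, 3], A[1, 3])
    b <- atan2(A[3, 2], -A[3, 1])
  }
  w <- a + b
  phi <- (b - a) / 2
  if (w > pi) {
    w <- w - 2 * pi
    phi <- phi + pi
  } else if (w <= -pi) {
    w <- w + 2 * pi
    phi <- phi + pi
  }
  Rm <- frame_i$R %*% rot_z((w / 2 - phi) / DEG) %*%
    rot_y((gamma / 2) / DEG) %*% rot_z(phi / DEG)
  d <- as.numeric(crossprod(Rm, frame_j$o - frame_i$o))
  list(
    trans = d,
    rot = c(gamma * sin(phi), gamma * cos(phi), w) / DEG,
    mid = list(R = Rm, o = (frame_i$o + frame_j$o) / 2)
  )
}

#' @noRd
#' Advance a frame by six helical coordinates: returns frame j such that
#' cehs_decompose(frame_i, frame_j) recovers the inputs, plus the mid-frame
#' used for the translation.
cehs_compose <- function(frame_i, trans, rot) {
  tilt <- rot[1] * DEG; roll <- rot[2] * DEG; w <- rot[3] * DEG
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  a <- w / 2 - phi
  b <- w / 2 + phi
  Rm <- frame_i$R %*% rot_z(a / DEG) %*% rot_y((gamma / 2) / DEG) %*% rot_z(phi / DEG)
  Rj <- frame_i$R %*% rot_z(a / DEG) %*% rot_y(gamma / DEG) %*% rot_z(b / DEG)
  oj <- frame_i$o + as.numeric(Rm %*% trans)
  list(frame = list(R = Rj, o = oj), mid = list(R = Rm, o = frame_i$o + as.numeric(Rm %*% (trans / 2))))
}

#' @noRd
#' Split a mid-frame into the two constituent frames given the six
#' coordinates (inverse of the mid-frame construction in cehs_decompose).
cehs_split <- function(mid, trans, rot) {
  tilt <- rot[1] * DEG; roll <- rot[2] * DEG; w <- rot[3] * DEG
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  a <- w / 2 - phi
  b <- w / 2 + phi
  Ri <- mid$R %*% rot_z(-phi / DEG) %*% rot_y((-gamma / 2) / DEG) %*% rot_z(-a / DEG)
  Rj <- mid$R %*% rot_z(-phi / DEG) %*% rot_y((gamma / 2) / DEG) %*% rot_z(b / DEG)
  hd <- as.numeric(mid$R %*% (trans / 2))
  list(
    frame_i = list(R = Ri, o = mid$o - hd),
    frame_j = list(R = Rj, o = mid$o + hd)
  )
}

#' @noRd
#' Least-squares rigid superposition (Kabsch).  Returns R, t minimizing
#' ||obs - (R %*% t(ref) + t)||; no scaling, det(R) = +1.
kabsch <- function(ref, obs) {
  cr <- colMeans(ref)
  co <- colMeans(obs)
  H <- crossprod(sweep(obs, 2, co), sweep(ref, 2, cr))  # sum obs_i ref_i^T
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = unname(co - as.numeric(R %*% cr)))
}

#' @noRd
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-10 || nv < 1e-10) stop("zero-length vector in angle computation")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) / DEG
}

#' @noRd
#' Dihedral of four points, degrees in [0, 360).  Errors on (near-)collinear
#' centres rather than returning an arbitrary value.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) {
    stop("degenerate dihedral: three of the four centres are collinear")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  # sign convention: the canonical flipped-in state of a B-form duplex
  # reports a small positive angle that grows toward 180 as the base
  # rotates out through the major groove
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  ang %% 360
}
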