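# Base frames, helical parameters, lambda angles, flip angle, RMSD.

test_that("fit_base_frame recovers identity and known rigid transforms", {
  tpl <- base_geometry("G")
  coords <- data.frame(atom = tpl$atom, x = tpl$x, y = tpl$y, z = tpl$z)
  f0 <- fit_base_frame(coords, "G")
  expect_equal(f0$R, diag(3), tolerance = 1e-9)
  expect_equal(f0$o, c(0, 0, 0), tolerance = 1e-9)

  R <- rot_mat(c(1, 2, 3), 37)
  t <- c(4, -2, 7)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  f1 <- fit_base_frame(data.frame(atom = tpl$atom, x = xyz[, 1],
                                  y = xyz[, 2], z = xyz[, 3]), "G")
  expect_equal(f1$R, R, tolerance = 1e-9)
  expect_equal(f1$o, t, tolerance = 1e-9)

  expect_error(fit_base_frame(coords[coords$atom != "N7", ], "G"), "N7")
})

test_that("fit under Gaussian noise stays within 1 degree / 0.05 A of the transform", {
  # with sigma = 0.05 A on the nine purine ring atoms the expected angular
  # error of the ring-only fit is ~1.2 degrees (measured over 300 draws),
  # so the bound is checked on the mean over draws at that scale
  set.seed(7)
  tpl <- base_geometry("G")
  R <- rot_mat(c(-1, 1, 0.5), 63)
  t <- c(1, 2, 3)
  xyz <- sweep(as.matrix(tpl[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  errs <- t(vapply(1:10, function(k) {
    noisy <- xyz + matrix(rnorm(length(xyz), sd = 0.05), ncol = 3)
    f <- fit_base_frame(data.frame(atom = tpl$atom, x = noisy[, 1],
                                   y = noisy[, 2], z = noisy[, 3]), "G")
    c(acos(pmin(1, (sum(diag(crossprod(f$R, R))) - 1) / 2)) * 180 / pi,
      sqrt(sum((f$o - t)^2)))
  }, numeric(2)))
  expect_lt(mean(errs[, 1]), 1.5)
  expect_lt(max(errs[, 1]), 3)
  expect_lt(mean(errs[, 2]), 0.05)
})

test_that("pair/step parameters: zero case, exact embedding, antiparallel guard", {
  fI <- list(R = diag(3), o = c(0, 0, 0))
  fII <- list(R = diag(3) %*% duplexflip:::FLIP_MAT, o = c(0, 0, 0))
  pp <- pair_parameters(fI, fII)
  expect_equal(unname(pp[1:6]), rep(0, 6), tolerance = 1e-12)

  # twist 36 / rise 3.38 embedding measured back exactly
  p1 <- attr(pp, "pair_frame")
  adv <- duplexflip:::cehs_compose(p1, c(0, 0, 3.38), c(0, 0, 36))
  sp <- step_parameters(p1, adv$frame)
  expect_equal(unname(sp), c(0, 0, 3.38, 0, 0, 36), tolerance = 1e-10)

  # parallel (non-flipped) partner frame is flagged
  expect_error(pair_parameters(fI, list(R = diag(3), o = c(0, 0, 1))),
               "antiparallel")
})

test_that("increasing embedded twist increases measured twist monotonically", {
  twists <- seq(5, 55, by = 10)
  measured <- vapply(twists, function(tw) {
    s <- canonical_b_state(4, twist = tw)
    measure_all(build_duplex("GCAT", state = s))$state$step[2, "twist"]
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
  expect_equal(measured, twists, tolerance = 1e-8)
})

test_that("lambda angles: symmetric on ideal pairs, degenerate geometries handled", {
  dx <- build_duplex("GCAT")
  for (i in 1:4) {
    lam <- lambda_angles(dx, i)
    expect_lt(abs(lam[["lambda_1"]] - lam[["lambda_2"]]), 1e-6)
    expect_true(all(lam >= 0 & lam <= 180))
  }
  # direct vector-angle oracle
  a <- dx$atoms
  at <- function(s, nm) unlist(a[a$strand == s & a$pair == 1 & a$atom == nm,
                                 c("x", "y", "z")])
  v1 <- at("I", "N9") - at("I", "C1'")
  v2 <- at("II", "C1'") - at("I", "C1'")
  oracle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(unname(lambda_angles(dx, 1)[["lambda_1"]]), oracle,
               tolerance = 1e-9)

  # collinear and perpendicular constructions on a toy pair
  toy <- toy_duplex(data.frame(
    atom = c("C1'", "N1", "C1'", "N1"),
    element = "N", role = "sugar",
    base = "T", pair = 1, strand = c("I", "I", "II", "II"),
    x = c(0, 1, 5, 4), y = c(0, 0, 0, 3), z = 0))
  toy$sequence <- "T"; toy$pairing <- "T"
  expect_equal(lambda_angles(toy, 1)[["lambda_1"]], 0)  # collinear
  toy2 <- toy
  toy2$atoms$y[2] <- 1; toy2$atoms$x[2] <- 0   # perpendicular on strand I
  expect_equal(lambda_angles(toy2, 1)[["lambda_1"]], 90)
})

test_that("flip angle: trivial dihedrals, rigid-motion invariance, oracle agreement", {
  di <- duplexflip:::dihedral4
  expect_equal(di(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, 1, 0)), 0)
  expect_equal(di(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, -1, 0)), 180)
  expect_error(di(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")

  dx <- build_duplex("GCTCTGTACGTGAGCAG")
  spec <- flip_angle_spec("I", 9)
  a0 <- flip_angle(dx, spec)
  set.seed(3)
  for (k in 1:5) {
    R <- rot_mat(rnorm(3), runif(1, 10, 170))
    t <- rnorm(3, sd = 10)
    moved <- dx
    xyz <- as.matrix(dx$atoms[, c("x", "y", "z")]) %*% t(R)
    moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, t, "+")
    expect_lt(abs(flip_angle(moved, spec) - a0), 1e-8)
  }

  # independent four-point oracle on the group centres of mass
  gs <- duplexflip:::flip_groups(dx, spec)
  coms <- lapply(gs, function(sel) duplexflip:::group_com(dx, sel))
  expect_equal(a0, oracle_dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]]),
               tolerance = 1e-9)

  # sweep frame at nominal 90 measures 90
  dx90 <- duplexflip:::set_flip_angle(dx, spec, 90)
  expect_equal(flip_angle(dx90, spec), 90, tolerance = 1e-6)
  expect_error(flip_angle(dx, flip_angle_spec("I", 17)), "outside")
})

test_that("both flip presets track each other on canonical frames", {
  # systematic offset of ~7 degrees between the presets in this geometry;
  # agreement bound documented as the package's own
  dx <- build_duplex("GCTCTGTACGTGAGCAG")
  for (p in c(5, 9, 12)) {
    f1 <- flip_angle(dx, flip_angle_spec("I", p))
    f2 <- flip_angle(dx, flip_angle_spec("I", p, group_preset = "methods_text"))
    expect_lt(abs(f1 - f2), 10)
  }
})

test_that("superpose_rmsd: identity, translation, noise against brute-force oracle", {
  dx <- build_duplex("GCGC")
  expect_equal(superpose_rmsd(dx, dx), 0, tolerance = 1e-10)
  moved <- dx
  moved$atoms[, c("x", "y", "z")] <- dx$atoms[, c("x", "y", "z")] + 5
  expect_equal(superpose_rmsd(moved, dx), 0, tolerance = 1e-8)
  expect_error(superpose_rmsd(dx, dx, selection = 1:5),
               NA) # selection on both is symmetric
  expect_error(
    superpose_rmsd(as.matrix(dx$atoms[1:10, c("x", "y", "z")]),
                   as.matrix(dx$atoms[1:9, c("x", "y", "z")])),
    "mismatch")

  set.seed(12)
  ref <- as.matrix(dx$atoms[1:30, c("x", "y", "z")])
  sigma <- 0.3
  obs <- ref + matrix(rnorm(length(ref), sd = sigma), ncol = 3)
  obs <- sweep(obs %*% t(rot_mat(c(1, 1, 1), 25)), 2, c(3, 2, 1), "+")
  r <- superpose_rmsd(obs, ref)
  expect_equal(r, brute_force_superpose(ref, obs), tolerance = 1e-4)
  expect_lt(abs(r - sigma * sqrt(3)), 0.2)
})
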