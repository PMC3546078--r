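# Hydrogen bonds, occupancy, SASA and flip profiles.

test_that("hydrogen-bond criteria have inclusive boundaries", {
  # donor N at the origin with its H at (1, 0, 0); acceptor placed freely
  frame_with_acceptor <- function(acc) {
    toy_duplex(data.frame(
      atom = c("N1", "H1", "O2"), element = c("N", "H", "O"),
      role = c("ring", "hpolar", "base"), base = c("G", "G", "C"),
      pair = c(1, 1, 2), strand = "I",
      x = c(0, 1, acc[1]), y = c(0, 0, acc[2]), z = 0))
  }
  crit <- hbond_criteria()
  # d = 2.8, angle 180: bond.  d = 3.2, angle 180: no bond
  expect_equal(nrow(detect_hbonds(frame_with_acceptor(c(2.8, 0)), crit)), 1)
  expect_equal(nrow(detect_hbonds(frame_with_acceptor(c(3.2, 0)), crit)), 0)

  # exact boundary: acceptor at 135 degrees seen from H, solved so the
  # donor-acceptor distance is exactly 3.0 -> bond (both inclusive)
  h <- c(1, 0)
  dir135 <- c(cos(pi / 4), sin(pi / 4))
  r <- uniroot(function(r) sqrt(sum((h + r * dir135)^2)) - 3.0, c(0.1, 5),
               tol = 1e-12)$root
  acc <- h + r * dir135
  hb <- detect_hbonds(frame_with_acceptor(acc), crit)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  expect_equal(hb$angle, 135, tolerance = 1e-9)
  # slightly longer distance or slightly sharper angle -> no bond
  expect_equal(nrow(detect_hbonds(frame_with_acceptor(acc * (3.001 / 3)), crit)), 0)
  # angle 134 at comfortable distance -> no bond
  sharp <- h + 1.8 * c(cos(46 * pi / 180), sin(46 * pi / 180))
  expect_equal(nrow(detect_hbonds(frame_with_acceptor(sharp), crit)), 0)
})

test_that("hydrogen-bond detection is invariant under rigid motion and finds the WC sets", {
  dx <- build_duplex("GCTCTGTACGTGAGCAG")
  hb0 <- detect_hbonds(dx, pairs = 8:10)
  key <- function(h) sort(paste(h$donor_pair, h$donor_atom, h$acceptor_atom))
  moved <- dx
  xyz <- as.matrix(dx$atoms[, c("x", "y", "z")]) %*% t(rot_mat(c(2, 1, 1), 77))
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(-4, 9, 2), "+")
  expect_identical(key(detect_hbonds(moved, pairs = 8:10)), key(hb0))

  # canonical small-fluctuation ensemble: exactly 3 bonds for C:G and 2 for
  # T:A in >= 99% of frames
  cfg <- generator_config(n_runs = 2, n_frames = 60, seed = 17,
                          fluctuation_sd = fluctuation_state(17, 0.2))
  ens <- generate_trajectory(cfg)
  count_ok <- c(cg = 0, ta = 0, n = 0)
  for (r in 1:2) for (f in 1:60) {
    fr <- get_frame(ens, r, f)
    cg <- detect_hbonds(fr, pairs = 9)   # C:G pair
    ta <- detect_hbonds(fr, pairs = 8)   # A:T pair
    intra <- function(h, p) sum(h$donor_pair == p & h$acceptor_pair == p)
    count_ok["cg"] <- count_ok["cg"] + (intra(cg, 9) == 3)
    count_ok["ta"] <- count_ok["ta"] + (intra(ta, 8) == 2)
    count_ok["n"] <- count_ok["n"] + 1
  }
  expect_gte(count_ok[["cg"]] / count_ok[["n"]], 0.99)
  expect_gte(count_ok[["ta"]] / count_ok[["n"]], 0.99)
})

test_that("occupancy: single-run and across-run arithmetic", {
  # one run, bond present in 4 of 10 frames: 40 %, no SE
  base <- build_duplex("GC")
  # pair 1 of "GC" is G (strand I) : C (strand II)
  broken <- base
  broken$atoms$x[broken$atoms$atom == "N3" & broken$atoms$strand == "II" &
                   broken$atoms$pair == 1] <- 50
  frames <- c(rep(list(base), 4), rep(list(broken), 6))
  ens1 <- ensemble_from_frames(list(frames))
  occ1 <- hbond_occupancy(ens1, donor = list(strand = "I", pair = 1, atom = "N1"),
                          acceptor = list(strand = "II", pair = 1, atom = "N3"))
  expect_equal(occ1$occupancy, 40)
  expect_true(is.na(occ1$se))

  # three runs at 30/40/50 % -> 40 +- SE({30,40,50})
  mk <- function(k) c(rep(list(base), k), rep(list(broken), 10 - k))
  ens3 <- ensemble_from_frames(list(mk(3), mk(4), mk(5)))
  occ3 <- hbond_occupancy(ens3, donor = list(strand = "I", pair = 1, atom = "N1"),
                          acceptor = list(strand = "II", pair = 1, atom = "N3"))
  expect_equal(occ3$occupancy, 40)
  expect_equal(occ3$se, sd(c(30, 40, 50)) / sqrt(3))

  # a bond present in every frame is exactly 100 %
  occ_full <- hbond_occupancy(ensemble_from_frames(list(rep(list(base), 5))),
                              donor = list(strand = "II", pair = 1, atom = "N4"),
                              acceptor = list(strand = "I", pair = 1, atom = "O6"))
  expect_equal(occ_full$occupancy, 100)
})

test_that("SASA matches closed forms for isolated and overlapping spheres", {
  cfg <- sasa_config()
  iso <- toy_duplex(data.frame(atom = "C1", element = "C", role = "base",
                               base = "G", pair = 1, strand = "I",
                               x = 0, y = 0, z = 0))
  r <- vdw_radii()[["C"]] + 1.4
  expect_lt(abs(sasa(iso, cfg) - 4 * pi * r^2) / (4 * pi * r^2), 0.01)

  two_at <- function(d) toy_duplex(data.frame(
    atom = c("C1", "C2"), element = "C", role = "base", base = "G",
    pair = 1:2, strand = "I", x = c(0, d), y = 0, z = 0))
  # far apart: both isolated
  far <- sasa(two_at(2 * r + 0.1), cfg)
  expect_equal(unname(far), rep(4 * pi * r^2, 2), tolerance = 1e-2 * r^2)
  # overlapping: spherical-cap closed form, equal radii
  d <- 1.5 * r
  cap_area <- 2 * pi * r * (r - d / 2)           # removed cap per sphere
  expected <- 4 * pi * r^2 - cap_area
  near <- sasa(two_at(d), cfg)
  expect_lt(max(abs(near - expected)) / expected, 0.02)
  # union is not larger than isolated sum
  expect_lt(sum(near), 2 * 4 * pi * r^2)
  expect_error(sasa(toy_duplex(data.frame(atom = "X", element = "Xx",
                                          role = "base", base = "G", pair = 1,
                                          strand = "I", x = 0, y = 0, z = 0))),
               "Xx")
})

test_that("profile_vs_flip recovers flat, identity and step-function profiles", {
  cfg <- generator_config(n_runs = 2, flip_sweep = c(20, 160, 36), seed = 9,
                          fluctuation_sd = fluctuation_state(17, 0))
  ens <- generate_trajectory(cfg)
  fsp <- cfg$flip_spec

  flat <- profile_vs_flip(ens, function(fr) 7.5, fsp)
  expect_true(all(flat$mean == 7.5))

  ident <- profile_vs_flip(ens, function(fr) flip_angle(fr, fsp), fsp)
  expect_true(all(abs(ident$mean - ident$center) <= 1))

  stepq <- profile_vs_flip(ens, function(fr) {
    as.numeric(flip_angle(fr, fsp) >= 70)
  }, fsp)
  below <- stepq$center < 69
  above <- stepq$center > 71
  expect_true(all(stepq$mean[below] == 0))
  expect_true(all(stepq$mean[above] == 1))
})
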