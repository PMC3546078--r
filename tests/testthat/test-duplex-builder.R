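# Builder and synthetic-trajectory generator.

test_that("canonical 17-mer has B-DNA dimensions and a zero-twist ladder is straight", {
  dx <- build_duplex("GCTCTGTACGTGAGCAG")
  expect_equal(nrow(unique(dx$atoms[, c("strand", "pair")])), 34)
  dims <- helix_dimensions(dx)
  expect_lt(abs(dims[["length"]] - 60) / 60, 0.10)
  expect_lt(abs(dims[["width"]] - 20) / 20, 0.15)

  # untwisted ladder: rise only -> all base normals parallel
  st <- canonical_b_state(6, twist = 0, rise = 3.38)
  ladder <- build_duplex("GCATGC", state = st)
  frames <- duplexflip:::duplex_base_frames(ladder)
  normals <- t(vapply(c(frames$I, frames$II),
                      function(f) f$R[, 3], numeric(3)))
  ref <- normals[1, ]
  expect_true(all(abs(abs(normals %*% ref) - 1) < 1e-9))
})

test_that("measure_all(build_duplex(s)) recovers s to <= 1e-6 over random B states", {
  set.seed(421)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    seqs <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    s <- random_b_state(n)
    m <- measure_all(build_duplex(seqs, state = s))
    expect_lt(max(abs(m$state$pair - s$pair)), 1e-6)
    expect_lt(max(abs(m$state$step - s$step)), 1e-6)
  }
})

test_that("builder rejects bad input with informative errors", {
  expect_error(build_duplex("GCXT"), "position 3")
  expect_error(build_duplex(""), "non-empty")
  expect_error(build_duplex("GCGC", state = canonical_b_state(5)),
               "dimension mismatch")
  expect_error(build_duplex("GCGC", pairing = "CGC"), "length")
})

test_that("two-state path: degenerate probabilities and stationary fraction", {
  spec0 <- two_state_spec(9, p_close_to_open = 0, p_open_to_close = 0.3)
  p0 <- sample_two_state_path(spec0, 500, seed = 1)
  expect_true(all(p0$labels == 0L))

  spec_alt <- two_state_spec(9, p_close_to_open = 1, p_open_to_close = 1)
  pa <- sample_two_state_path(spec_alt, 400, seed = 2)
  expect_true(all(abs(diff(pa$labels)) == 1L))

  expect_error(two_state_spec(9, p_close_to_open = 1.2), "\\[0, 1\\]")

  # f = p_co / (p_co + p_oc); SE corrected for chain autocorrelation
  spec <- two_state_spec(9, p_close_to_open = 0.02, p_open_to_close = 0.08)
  n <- 50000
  path <- sample_two_state_path(spec, n, seed = 99)
  f <- 0.2
  rho <- 1 - 0.02 - 0.08
  se <- sqrt(f * (1 - f) / n * (1 + rho) / (1 - rho))
  expect_lt(abs(mean(path$labels) - f), 3 * se)

  # values follow the state-conditional means
  expect_lt(abs(mean(path$values[path$labels == 1]) - 45), 1)
  expect_lt(abs(mean(path$values[path$labels == 0]) - (-1)), 1)
})

test_that("generator is seed-deterministic and honours zero fluctuations", {
  zero_sd <- fluctuation_state(5, scale = 0)
  cfg <- generator_config(sequence = "GCGAT", n_runs = 2, n_frames = 4,
                          fluctuation_sd = zero_sd, target_pair = 3, seed = 11)
  e1 <- generate_trajectory(cfg)
  e2 <- generate_trajectory(cfg)
  expect_identical(e1$runs, e2$runs)

  # sd = 0, no two-state: every frame equals the mean-state build
  ref <- as.matrix(build_duplex("GCGAT")$atoms[, c("x", "y", "z")])
  for (f in 1:4) {
    expect_equal(e1$runs[[1]][, , f], ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("generator records ground truth that measurement reproduces", {
  ts <- two_state_spec(target_pair = 5)
  cfg <- generator_config(sequence = "GCATCGATC", n_runs = 1, n_frames = 12,
                          two_state = ts, target_pair = 5, seed = 8,
                          fluctuation_sd = fluctuation_state(9, 0.2))
  ens <- generate_trajectory(cfg)
  meas <- measure_all(ens)
  op <- observable_series(meas, "opening", 5, drop_burn_in = FALSE)[[1]]
  expect_equal(op, unname(ens$ground_truth[[1]]$pair[5, "opening", ]),
               tolerance = 1e-9)
  expect_true(all(ens$ground_truth[[1]]$labels %in% 0:1))
})

test_that("flip sweep produces a monotone increasing flip-angle series", {
  cfg <- generator_config(n_runs = 1, flip_sweep = c(10, 180, 30), seed = 5,
                          fluctuation_sd = fluctuation_state(17, 0))
  ens <- generate_trajectory(cfg)
  ang <- vapply(1:30, function(f) flip_angle(get_frame(ens, 1, f),
                                             cfg$flip_spec), numeric(1))
  expect_true(all(diff(ang) > 0))
  expect_equal(ang[1], 10, tolerance = 1e-6)
  expect_equal(ang[30], 180, tolerance = 1e-6)
})

test_that("burn-in frames are flagged and excluded downstream", {
  cfg <- generator_config(sequence = "GCGCG", n_runs = 1, n_frames = 10,
                          burn_in_frames = 4, target_pair = 3, seed = 2,
                          fluctuation_sd = fluctuation_state(5, 0.2))
  ens <- generate_trajectory(cfg)
  meas <- measure_all(ens)
  expect_equal(sort(unique(meas$frame[meas$burn_in])), 1:4)
  ser <- observable_series(meas, "twist", 2)
  expect_length(ser[[1]], 6)
  expect_error(generator_config(n_frames = 5, burn_in_frames = 5),
               "burn_in")
})
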