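# Adaptive-biasing-force sampler on the reduced flip model.

test_that("potential specs: presets are self-consistent, bad derivative rejected", {
  dw <- double_well_potential()
  xs <- seq(10, 180, by = 0.5)
  u <- dw$U(xs)
  expect_true(all(is.finite(u)))
  # two local minima near 42 and 67, about 1 kcal/mol barrier
  loc_min <- xs[which(diff(sign(diff(u))) == 2) + 1]
  expect_length(loc_min, 2)
  expect_lt(abs(loc_min[1] - 42), 1.5)
  expect_lt(abs(loc_min[2] - 67), 1.5)
  mid <- xs[xs > loc_min[1] & xs < loc_min[2]]
  barrier <- max(dw$U(mid)) - dw$U(loc_min[1])
  expect_lt(abs(barrier - 1), 0.35)
  # rising outer wall
  expect_gt(dw$U(178) - dw$U(67), 3)

  h <- harmonic_potential(k = 0.004, center = 90)
  expect_equal(h$U(100) - h$U(90), 0.004 / 2 * 100, tolerance = 1e-9)
  expect_error(abf_config(range = c(10, 180), bin_width = 3), "whole bins")
})

test_that("sample conservation, determinism and the flat landscape", {
  pot <- flat_potential()
  cfg <- abf_config(n_steps = 1e6, n_min = 500)
  st1 <- run_abf(pot, cfg, langevin_config(seed = 4, save_stride = 10))
  st2 <- run_abf(pot, cfg, langevin_config(seed = 4, save_stride = 10))
  expect_identical(st1$theta, st2$theta)
  expect_equal(sum(st1$count), 1e6)
  # occupancy of the correlated walk is only loosely uniform; no bin may
  # be empty or systematically favoured
  expect_true(all(st1$count > 0))
  expect_lt(max(st1$count) / min(st1$count), 3)
  p <- pmf_from_forces(st1)
  expect_lt(diff(range(p$dG)), 0.12)
})

test_that("harmonic potential: accrued mean force is linear with slope -k", {
  k <- 0.002
  pot <- harmonic_potential(k = k, center = 95)
  st <- run_abf(pot, abf_config(n_steps = 8e5, n_min = 2000),
                langevin_config(seed = 21, save_stride = 100))
  sampled <- st$count > 200
  fbar <- (st$force_sum / st$count)[sampled]
  ctr <- st$centers[sampled]
  fit <- lm(fbar ~ ctr)
  expect_lt(abs(coef(fit)[2] - (-k)) / k, 0.05)
})

test_that("n_min = Inf reduces to plain Langevin whose histogram matches U", {
  pot <- harmonic_potential(k = 0.002, center = 95)
  st <- run_abf(pot, abf_config(n_steps = 6e5, n_min = Inf),
                langevin_config(seed = 31, save_stride = 1))
  expect_equal(sum(st$bias_active), 0)
  p <- pmf_from_series(st$theta, histogram_spec(bin_width = 2))
  kT <- KB * 300
  inside <- abs(p$center - 95) < 2 * sqrt(kT / 0.002)
  ref <- pot$U(p$center[inside]) - min(pot$U(p$center[inside]))
  dev <- p$dG[inside] - ref
  expect_lt(max(abs(dev - mean(dev))), 0.25)
})

test_that("ABF reconstructs the double well and boosts barrier crossings", {
  pot <- double_well_potential()
  states <- lapply(1:3, function(s) {
    run_abf(pot, abf_config(n_steps = 1.2e6),
            langevin_config(seed = 100 + s, save_stride = 50))
  })
  avg <- average_abf_runs(states)
  xs <- seq(10, 180, by = 0.5)
  uref <- pot$U(xs) - min(pot$U(xs))
  # reconstructed minima within 2 bins (4 degrees) of the analytic ones
  u <- avg$dG
  loc_min_ref <- xs[which(diff(sign(diff(uref))) == 2) + 1]
  in_well <- function(prof, lo, hi) {
    sub <- prof[prof$center > lo & prof$center < hi, ]
    sub$center[which.min(sub$dG)]
  }
  expect_lt(abs(in_well(avg, 20, 55) - loc_min_ref[1]), 4)
  expect_lt(abs(in_well(avg, 55, 85) - loc_min_ref[2]), 4)
  # barrier within 0.2 kcal/mol
  bar_ref <- max(pot$U(xs[xs > loc_min_ref[1] & xs < loc_min_ref[2]])) -
    pot$U(loc_min_ref[1])
  sub <- avg[avg$center > 40 & avg$center < 70, ]
  bar <- max(sub$dG[sub$center > in_well(avg, 20, 55) &
                      sub$center < in_well(avg, 55, 85)]) -
    min(sub$dG)
  expect_lt(abs(bar - bar_ref), 0.2)

  # the inner barrier (~1.7 kT) is crossed freely even without bias; the
  # 10x sampling gain shows up at the outer wall (>4 kT), which the
  # unbiased walk rarely passes
  crossings <- function(theta, thr) sum(abs(diff(theta > thr)))
  unbiased <- run_abf(pot, abf_config(n_steps = 1.2e6, n_min = Inf),
                      langevin_config(seed = 101, save_stride = 50))
  expect_gte(crossings(states[[1]]$theta, 140),
             10 * max(1, crossings(unbiased$theta, 140)))

  # outer-wall region visited only under bias at equal steps
  expect_gt(max(states[[1]]$theta), max(unbiased$theta))
})

test_that("averaging ABF runs: identical seeds give zero SE, single run none", {
  pot <- harmonic_potential(k = 0.004, center = 60, range = c(10, 110))
  cfg <- abf_config(range = c(10, 110), n_steps = 4e5, n_min = 1000)
  s1 <- run_abf(pot, cfg, langevin_config(seed = 7, save_stride = 100))
  s2 <- run_abf(pot, cfg, langevin_config(seed = 7, save_stride = 100))
  avg <- average_abf_runs(list(s1, s2))
  expect_true(all(avg$se == 0))
  single <- pmf_from_forces(s1)
  expect_false("se" %in% names(single))
  expect_error(pmf_from_forces(
    run_abf(pot, abf_config(range = c(10, 110), n_steps = 100, n_min = 10),
            langevin_config(seed = 1))), "unsampled")
})
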