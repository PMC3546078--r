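# Adaptive-biasing-force estimator on a reduced 1-D model of the flip
# coordinate.
#
# The coordinate is discretized into windows; samples of the instantaneous
# force along the coordinate are accrued per window, and once a window has
# collected n_min samples the negative running mean force is applied as the
# bias (ramped linearly from zero to full between 0 and n_min samples).
# Dynamics are overdamped Langevin with reflecting boundaries.

#' Closed-form potential for the reduced flip model
#'
#' Potentials are sums of a quadratic term, a quartic wall and Gaussian
#' wells, which covers the presets and keeps the force evaluable in
#' compiled code: `U(x) = q2 (x - q0)^2 + q4 ((x - q0)/qw)^4 +
#' sum_i A_i exp(-(x - m_i)^2 / (2 s_i^2))` (kcal/mol, x in degrees).
#' The analytic derivative is cross-checked against a finite difference at
#' construction.
#'
#' @param range Coordinate range `c(lo, hi)`, degrees.
#' @param q0,q2,q4,qw Polynomial terms (centre, quadratic coefficient,
#'   quartic amplitude and width).
#' @param gaussians Data frame with columns `A`, `m`, `s` (well depth < 0,
#'   centre, width).
#' @return An object of class `potential_spec` with function components
#'   `U` and `dU`.
#' @export
potential_spec <- function(range, q0 = 0, q2 = 0, q4 = 0, qw = 1,
                           gaussians = data.frame(A = numeric(),
                                                  m = numeric(),
                                                  s = numeric())) {
  U <- function(x) {
    out <- q2 * (x - q0)^2 + q4 * ((x - q0) / qw)^4
    for (i in seq_len(nrow(gaussians))) {
      out <- out + gaussians$A[i] *
        exp(-(x - gaussians$m[i])^2 / (2 * gaussians$s[i]^2))
    }
    out
  }
  dU <- function(x) {
    out <- 2 * q2 * (x - q0) + 4 * q4 * (x - q0)^3 / qw^4
    for (i in seq_len(nrow(gaussians))) {
      z <- (x - gaussians$m[i]) / gaussians$s[i]
      out <- out - gaussians$A[i] * z / gaussians$s[i] * exp(-z^2 / 2)
    }
    out
  }
  xs <- seq(range[1], range[2], length.out = 201)
  h <- 1e-5
  fd <- (U(xs + h) - U(xs - h)) / (2 * h)
  if (max(abs(fd - dU(xs))) > 1e-4) {
    stop("analytic derivative inconsistent with finite difference")
  }
  if (!all(is.finite(U(xs)))) stop("potential not finite on range")
  structure(list(range = range, q0 = q0, q2 = q2, q4 = q4, qw = qw,
                 gaussians = gaussians, U = U, dU = dU),
            class = "potential_spec")
}

#' Harmonic preset
#' @param k Force constant, kcal/mol/deg^2.
#' @param center Minimum position, degrees.
#' @param range Coordinate range.
#' @return A [potential_spec()].
#' @export
harmonic_potential <- function(k = 0.002, center = 95, range = c(10, 180)) {
  potential_spec(range, q0 = center, q2 = k / 2)  # U = k/2 (x - c)^2
}

#' Flat preset
#' @param range Coordinate range.
#' @return A [potential_spec()].
#' @export
flat_potential <- function(range = c(10, 180)) {
  potential_spec(range)
}

#' Double-well preset emulating the wobble-pair flip profile
#'
#' Two Gaussian wells placed so the local minima sit near 42 and 67
#' degrees separated by a barrier of about 1 kcal/mol (the second minimum
#' about 0.3 kcal/mol above the first), plus a quartic rise toward 180
#' degrees of a few kcal/mol.
#'
#' @param range Coordinate range.
#' @return A [potential_spec()].
#' @export
double_well_potential <- function(range = c(10, 180)) {
  potential_spec(range, q0 = 55, q4 = 1, qw = 81.6,
                 gaussians = data.frame(A = c(-2.2, -1.9),
                                        m = c(42, 67),
                                        s = c(8, 8)))
}

#' ABF discretization and threshold configuration
#'
#' @param range Reaction-coordinate window, degrees (default 10 to 180).
#' @param bin_width Window width, degrees (default 2; range must divide
#'   into whole bins).
#' @param n_min Samples collected in a window before the bias reaches
#'   full strength (default 2000; `Inf` disables biasing).
#' @param n_steps Total Langevin steps.
#' @return An object of class `abf_config`.
#' @export
abf_config <- function(range = c(10, 180), bin_width = 2, n_min = 2000,
                       n_steps = 1e6) {
  n_bins <- (range[2] - range[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("range must divide into whole bins")
  }
  if (n_min < 1) stop("n_min must be >= 1")
  structure(list(range = range, bin_width = bin_width, n_min = n_min,
                 n_steps = as.integer(n_steps)), class = "abf_config")
}

#' Langevin integrator configuration for the reduced model
#'
#' @param timestep Integration step, reduced time units (default 0.5,
#'   giving a root-mean-square free-diffusion step of ~0.8 degrees --
#'   small against the 2-degree bins yet large enough to traverse the
#'   10-180 degree window in well under a million steps).
#' @param friction Friction coefficient (> 0); the diffusion constant is
#'   `kB T / friction` in deg^2 per time unit.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @param save_stride Store every `save_stride`-th coordinate in the
#'   returned trajectory.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(timestep = 0.5, friction = 1,
                            temperature = 300, seed = 1, save_stride = 1L) {
  if (timestep <= 0 || friction <= 0) stop("timestep and friction must be > 0")
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, seed = seed,
                 save_stride = as.integer(save_stride)),
            class = "langevin_config")
}

#' Run the adaptive-biasing-force sampler
#'
#' Overdamped Langevin dynamics on a closed-form potential with per-bin
#' accrual of the instantaneous force and an adaptively applied
#' mean-force bias (linear ramp up to `n_min` samples), reflecting
#' boundaries, and an R-seed-deterministic trajectory.
#'
#' @param potential A [potential_spec()].
#' @param config An [abf_config()].
#' @param langevin A [langevin_config()].
#' @param x0 Starting coordinate; default the lower third of the range.
#' @return An `abf_state`: list with per-bin `force_sum`, `count`,
#'   `bias_active`, bin `centers`, the (possibly thinned) `theta`
#'   trajectory and the configurations.
#' @export
run_abf <- function(potential, config, langevin,
                    x0 = config$range[1] + diff(config$range) / 3) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(config, "abf_config"),
            inherits(langevin, "langevin_config"))
  set.seed(langevin$seed)
  kT <- KB_KCAL * langevin$temperature
  res <- abf_core(x0, config$n_steps, config$range[1], config$range[2],
                  config$bin_width, config$n_min, langevin$timestep,
                  langevin$friction, kT,
                  potential$q0, potential$q2, potential$q4, potential$qw,
                  potential$gaussians$A, potential$gaussians$m,
                  potential$gaussians$s, langevin$save_stride)
  centers <- seq(config$range[1] + config$bin_width / 2,
                 config$range[2] - config$bin_width / 2,
                 by = config$bin_width)
  structure(list(force_sum = res$force_sum, count = res$count,
                 bias_active = res$count >= config$n_min,
                 centers = centers, theta = res$theta,
                 x_final = res$x_final,
                 config = config, langevin = langevin,
                 potential = potential), class = "abf_state")
}

#' @export
print.abf_state <- function(x, ...) {
  cat("<abf_state>", length(x$centers), "bins,",
      format(sum(x$count), big.mark = ","), "samples,",
      sum(x$bias_active), "bins at full bias\n")
  invisible(x)
}

#' Reconstruct the free-energy profile from accrued mean forces
#'
#' `dG(theta) = -integral of the mean force`, trapezoid rule over bin
#' centres, anchored at its minimum.
#'
#' @param state An `abf_state` from [run_abf()].
#' @return A `pmf_profile` with columns `center`, `dG`.
#' @export
pmf_from_forces <- function(state) {
  empty <- which(state$count == 0)
  if (length(empty)) {
    stop("unsampled bin(s) at centre(s): ",
         paste(state$centers[empty], collapse = ", "))
  }
  fbar <- state$force_sum / state$count
  w <- state$config$bin_width
  dG <- c(0, cumsum(-(utils::head(fbar, -1) + utils::tail(fbar, -1)) / 2 * w))
  dG <- dG - min(dG)
  spec <- histogram_spec(bin_width = w,
                         temperature = state$langevin$temperature)
  new_pmf_profile(data.frame(center = state$centers, dG = dG),
                  spec, reference_index = which.min(dG))
}

#' Average ABF free-energy profiles over independent runs
#'
#' @param states List of `abf_state` objects (e.g. runs with different
#'   seeds).
#' @param conf Confidence level (default 0.99).
#' @return A `pmf_profile` with per-bin mean, SE and confidence interval
#'   ([average_profiles()] semantics).
#' @export
average_abf_runs <- function(states, conf = 0.99) {
  average_profiles(lapply(states, pmf_from_forces), conf = conf)
}
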