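# The twelve helical parameters as a typed container.

PAIR_PARAMS <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening")
STEP_PARAMS <- c("shift", "slide", "rise", "tilt", "roll", "twist")

#' Helical-parameter state of a duplex
#'
#' Bundles the six base-pair parameters (shear, stretch, stagger in
#' Angstrom; buckle, propeller, opening in degrees) for each of `n` pairs
#' with the six base-step parameters (shift, slide, rise in Angstrom; tilt,
#' roll, twist in degrees) for each of the `n - 1` steps.
#'
#' @param pair Numeric matrix `n x 6` (columns in the order shear, stretch,
#'   stagger, buckle, propeller, opening) or a data frame coercible to one.
#' @param step Numeric matrix `(n - 1) x 6` (shift, slide, rise, tilt,
#'   roll, twist).
#' @return An object of class `helical_state`.
#' @export
helical_state <- function(pair, step) {
  pair <- as.matrix(pair)
  step <- as.matrix(step)
  if (ncol(pair) != 6 || ncol(step) != 6) {
    stop("pair and step must have six columns")
  }
  if (nrow(step) != nrow(pair) - 1) {
    stop("dimension mismatch: need n pairs and n - 1 steps, got ",
         nrow(pair), " and ", nrow(step))
  }
  if (!all(is.finite(pair)) || !all(is.finite(step))) {
    stop("helical parameters must be finite")
  }
  colnames(pair) <- PAIR_PARAMS
  colnames(step) <- STEP_PARAMS
  structure(list(pair = pair, step = step), class = "helical_state")
}

#' @export
print.helical_state <- function(x, ...) {
  cat("<helical_state>", nrow(x$pair), "pairs,", nrow(x$step), "steps\n")
  cat("pair parameter means:", paste(sprintf("%s=%.2f", PAIR_PARAMS,
                                             colMeans(x$pair)), collapse = " "), "\n")
  cat("step parameter means:", paste(sprintf("%s=%.2f", STEP_PARAMS,
                                             colMeans(x$step)), collapse = " "), "\n")
  invisible(x)
}

#' Canonical B-form helical state
#'
#' All parameters zero except twist (36 degrees) and rise (3.38 Angstrom):
#' the idealized straight B-DNA used as the construction default.
#'
#' @param n_pairs Number of base pairs.
#' @param twist,rise Step twist (degrees) and rise (Angstrom).
#' @return A [helical_state].
#' @export
canonical_b_state <- function(n_pairs, twist = 36, rise = 3.38) {
  pair <- matrix(0, n_pairs, 6)
  step <- matrix(0, max(n_pairs - 1, 0), 6)
  if (n_pairs > 1) {
    step[, 3] <- rise
    step[, 6] <- twist
  }
  helical_state(pair, step)
}

#' Random helical state within B-DNA-like ranges
#'
#' Draws every parameter uniformly from a range typical of relaxed B-DNA
#' fluctuations; used for property tests of the build/measure round trip.
#' Translations vary by a few tenths of an Angstrom (rise around 3.38),
#' angles by several degrees (twist in 20-50).
#'
#' @param n_pairs Number of base pairs.
#' @return A [helical_state].
#' @export
random_b_state <- function(n_pairs) {
  runifm <- function(n, lo, hi) {
    m <- matrix(stats::runif(n * 6), n, 6)
    sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
  }
  pair <- runifm(n_pairs, lo = c(-1.5, -0.8, -1.0, -15, -15, -10),
                 hi = c(1.5, 0.8, 1.0, 15, 15, 10))
  step <- runifm(max(n_pairs - 1, 0),
                 lo = c(-1.5, -1.5, 2.8, -8, -10, 20),
                 hi = c(1.5, 1.5, 4.0, 8, 10, 50))
  helical_state(pair, step)
}

#' @noRd
#' Gaussian perturbation of a mean state (used by the generator)
draw_state <- function(mean_state, sd_state) {
  pair <- mean_state$pair +
    matrix(stats::rnorm(length(mean_state$pair)), nrow(mean_state$pair)) * sd_state$pair
  step <- mean_state$step
  if (length(step)) {
    step <- step + matrix(stats::rnorm(length(step)), nrow(step)) * sd_state$step
  }
  helical_state(pair, step)
}
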