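# Synthetic trajectory generator: the statistical stand-in for the MD runs.
#
# Frames are drawn by perturbing a mean helical state with independent
# Gaussian fluctuations; one designated pair can follow a hidden two-state
# (closed/open) Markov chain, emulating wobble-pair opening dynamics; and a
# deterministic sweep of the flip coordinate emulates the biased runs.

#' Two-state (closed/open) switching specification
#'
#' A hidden two-state Markov chain attached to one helical parameter of
#' one pair.  Defaults emulate wobble-pair opening: the closed state at an
#' opening angle of -1 degrees (Watson-Crick-like) and the open state at
#' 45 degrees, with a stationary open fraction
#' `p_close_to_open / (p_close_to_open + p_open_to_close)`.
#'
#' @param target_pair Pair index carrying the two-state parameter.
#' @param parameter Helical parameter targeted (default `"opening"`).
#' @param closed_mean,open_mean State means (degrees for angles).
#' @param closed_sd,open_sd Within-state standard deviations.  The
#'   defaults (3 degrees) keep the two basins cleanly separated and the
#'   open basin inside the validity domain of the rigid-nucleotide
#'   forward model (opening angles beyond roughly 53 degrees would force
#'   steric overlap of the rigidly attached backbones).
#' @param p_close_to_open,p_open_to_close Per-frame transition
#'   probabilities, each in [0, 1].
#' @return An object of class `two_state_spec`.
#' @export
two_state_spec <- function(target_pair, parameter = "opening",
                           closed_mean = -1, open_mean = 45,
                           closed_sd = 3, open_sd = 3,
                           p_close_to_open = 0.02, p_open_to_close = 0.08) {
  p <- c(p_close_to_open, p_open_to_close)
  if (any(p < 0) || any(p > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  if (!parameter %in% c(PAIR_PARAMS, STEP_PARAMS)) {
    stop("unknown helical parameter: ", parameter)
  }
  structure(list(target_pair = target_pair, parameter = parameter,
                 closed_mean = closed_mean, open_mean = open_mean,
                 closed_sd = closed_sd, open_sd = open_sd,
                 p_close_to_open = p_close_to_open,
                 p_open_to_close = p_open_to_close),
            class = "two_state_spec")
}

#' @noRd
stationary_open_fraction <- function(spec) {
  s <- spec$p_close_to_open + spec$p_open_to_close
  if (s == 0) return(0)
  spec$p_close_to_open / s
}

#' Sample a realization of the two-state chain
#'
#' Draws a Markov-chain path of hidden closed/open labels (initial state
#' from the stationary distribution) and per-frame parameter values from
#' the state-conditional Gaussians.
#'
#' @param spec A [two_state_spec()].
#' @param n Number of frames (>= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (as inside [generate_trajectory()]).
#' @return List with `labels` (integer vector, 0 = closed, 1 = open) and
#'   `values` (numeric vector).
#' @export
sample_two_state_path <- function(spec, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  f <- stationary_open_fraction(spec)
  labels <- integer(n)
  u <- stats::runif(n)
  labels[1] <- as.integer(u[1] < f)
  for (i in seq_len(n - 1)) {
    labels[i + 1] <- if (labels[i] == 0L) {
      as.integer(u[i + 1] < spec$p_close_to_open)
    } else {
      as.integer(u[i + 1] >= spec$p_open_to_close)
    }
  }
  mu <- ifelse(labels == 1L, spec$open_mean, spec$closed_mean)
  sd <- ifelse(labels == 1L, spec$open_sd, spec$closed_sd)
  list(labels = labels, values = stats::rnorm(n, mu, sd))
}

#' Default per-parameter fluctuation standard deviations
#'
#' Moderate Gaussian fluctuation widths typical of room-temperature B-DNA
#' (a few tenths of an Angstrom for translations, a few degrees for
#' angles), expressed as a [helical_state]-shaped object so each parameter
#' of each pair/step can be overridden.
#'
#' @param n_pairs Number of base pairs.
#' @param scale Overall multiplier (e.g. `0.2` for the "small
#'   fluctuations" regime used in hydrogen-bond tests).
#' @return A [helical_state] whose entries are standard deviations.
#' @export
fluctuation_state <- function(n_pairs, scale = 1) {
  pair_sd <- c(0.15, 0.08, 0.20, 4, 5, 3)
  step_sd <- c(0.30, 0.30, 0.15, 2.5, 4, 4)
  helical_state(
    matrix(pair_sd, n_pairs, 6, byrow = TRUE) * scale,
    matrix(step_sd, max(n_pairs - 1, 0), 6, byrow = TRUE) * scale
  )
}

#' Configuration of the synthetic trajectory generator
#'
#' @param sequence Strand I sequence (default: the 17-mer
#'   d(GCTCTGTACGTGAGCAG) studied in the analyses this package supports).
#' @param pairing Strand II bases by pair; default Watson-Crick.
#' @param mean_state Mean [helical_state]; default canonical B form.
#' @param fluctuation_sd [helical_state]-shaped standard deviations (all
#'   >= 0); default [fluctuation_state()].
#' @param two_state Optional [two_state_spec()].
#' @param flip_sweep Optional numeric `c(start, end, n_frames)` in
#'   degrees: replaces stochastic frames by a deterministic sweep of the
#'   flip coordinate (the biased-run stand-in).
#' @param flip_spec [flip_angle_spec()] used by `flip_sweep`; default
#'   targets strand I of `target_pair`.
#' @param target_pair Pair index of the site of interest (default 9, the
#'   centre of the default 17-mer).
#' @param n_runs,n_frames Independent runs and frames per run.
#' @param burn_in_frames Leading frames flagged for exclusion from
#'   analyses (default 0; `n_frames > burn_in_frames` required).
#' @param seed Integer seed fixing the whole ensemble.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sequence = "GCTCTGTACGTGAGCAG",
                             pairing = NULL,
                             mean_state = NULL,
                             fluctuation_sd = NULL,
                             two_state = NULL,
                             flip_sweep = NULL,
                             flip_spec = NULL,
                             target_pair = 9,
                             n_runs = 3, n_frames = 200,
                             burn_in_frames = 0, seed = 1) {
  bases <- seq_letters(sequence)
  n <- length(bases)
  if (is.null(mean_state)) mean_state <- canonical_b_state(n)
  if (is.null(fluctuation_sd)) fluctuation_sd <- fluctuation_state(n)
  if (any(fluctuation_sd$pair < 0) || any(fluctuation_sd$step < 0)) {
    stop("fluctuation SDs must be >= 0")
  }
  if (!is.null(flip_sweep)) {
    if (length(flip_sweep) != 3 || flip_sweep[3] < 1) {
      stop("flip_sweep must be c(start, end, n_frames)")
    }
    n_frames <- as.integer(flip_sweep[3])
  }
  if (!(n_frames > burn_in_frames && burn_in_frames >= 0)) {
    stop("need n_frames > burn_in_frames >= 0")
  }
  if (is.null(flip_spec)) flip_spec <- flip_angle_spec("I", target_pair)
  structure(list(sequence = bases, pairing = pairing,
                 mean_state = mean_state, fluctuation_sd = fluctuation_sd,
                 two_state = two_state, flip_sweep = flip_sweep,
                 flip_spec = flip_spec, target_pair = target_pair,
                 n_runs = n_runs, n_frames = n_frames,
                 burn_in_frames = burn_in_frames, seed = seed),
            class = "generator_config")
}

#' Generate a seeded synthetic trajectory ensemble
#'
#' Per frame, every helical parameter is drawn independently from
#' `N(mean, sd)` except the two-state target parameter, which follows the
#' hidden Markov path; frames with any inter-atomic distance below 0.5
#' Angstrom are rejected and redrawn (at most 100 attempts).  A
#' `flip_sweep` replaces the stochastic frames by a deterministic sweep of
#' the flip coordinate.  The same seed reproduces the ensemble
#' bit-for-bit.
#'
#' @param config A [generator_config()].
#' @return An object of class `trajectory_ensemble`: list with
#'   `topology` (a reference `duplex`), `runs` (list of
#'   `n_atoms x 3 x n_frames` coordinate arrays), `ground_truth` (per run:
#'   drawn pair/step parameter arrays and hidden state labels), `burn_in`
#'   and `config`.
#' @export
generate_trajectory <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config")
  }
  set.seed(config$seed)
  n <- length(config$sequence)
  topo <- build_duplex(config$sequence, config$pairing, config$mean_state)
  plan <- duplex_plan(topo, flip_spec = config$flip_spec)
  runs <- vector("list", config$n_runs)
  truth <- vector("list", config$n_runs)
  sweep_targets <- if (!is.null(config$flip_sweep)) {
    seq(config$flip_sweep[1], config$flip_sweep[2],
        length.out = config$n_frames)
  }
  for (r in seq_len(config$n_runs)) {
    coords <- array(NA_real_, c(nrow(topo$atoms), 3, config$n_frames))
    pair_truth <- array(NA_real_, c(n, 6, config$n_frames),
                        dimnames = list(NULL, PAIR_PARAMS, NULL))
    step_truth <- array(NA_real_, c(max(n - 1, 0), 6, config$n_frames),
                        dimnames = list(NULL, STEP_PARAMS, NULL))
    labels <- rep(NA_integer_, config$n_frames)
    path <- if (!is.null(config$two_state)) {
      sample_two_state_path(config$two_state, config$n_frames)
    }
    # during a sweep the flipping base is driven past its neighbours on
    # purpose, so its nucleotide is excluded from the clash scan
    clash_rows <- if (is.null(sweep_targets)) {
      rep(TRUE, nrow(topo$atoms))
    } else {
      !(topo$atoms$strand == config$flip_spec$strand &
          topo$atoms$pair == config$flip_spec$pair)
    }
    n_redraws <- 0L
    for (f in seq_len(config$n_frames)) {
      for (attempt in seq_len(100)) {
        st <- draw_state(config$mean_state, config$fluctuation_sd)
        if (!is.null(path)) {
          ts <- config$two_state
          labels[f] <- path$labels[f]
          # the hidden label is part of the recorded path; on a clash the
          # state-conditional value is redrawn together with the
          # fluctuations (a truncated-tail rejection step)
          val <- if (attempt == 1) path$values[f] else {
            stats::rnorm(1,
                         if (labels[f] == 1L) ts$open_mean else ts$closed_mean,
                         if (labels[f] == 1L) ts$open_sd else ts$closed_sd)
          }
          if (ts$parameter %in% PAIR_PARAMS) {
            st$pair[ts$target_pair, ts$parameter] <- val
          } else {
            st$step[ts$target_pair, ts$parameter] <- val
          }
        }
        xyz <- frame_coords(plan, st)
        if (!is.null(sweep_targets)) {
          xyz <- set_flip_coords(plan, xyz, sweep_targets[f])
        }
        if (!has_clash(xyz[clash_rows, , drop = FALSE], 0.5)) break
        if (attempt == 100) {
          stop("frame ", f, " of run ", r,
               " still clashes after 100 redraws")
        }
        n_redraws <- n_redraws + 1L
      }
      coords[, , f] <- xyz
      pair_truth[, , f] <- st$pair
      if (n > 1) step_truth[, , f] <- st$step
    }
    if (n_redraws > 0) {
      message("run ", r, ": ", n_redraws, " frame redraw(s) after steric clash")
    }
    runs[[r]] <- coords
    truth[[r]] <- list(pair = pair_truth, step = step_truth, labels = labels)
  }
  structure(list(topology = topo, runs = runs, ground_truth = truth,
                 burn_in = config$burn_in_frames, config = config),
            class = "trajectory_ensemble")
}

#' Extract one frame of an ensemble as a duplex
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param run,frame Run and frame indices (1-based).
#' @return A `duplex`.
#' @export
get_frame <- function(ensemble, run, frame) {
  dx <- ensemble$topology
  dx$atoms[, c("x", "y", "z")] <- ensemble$runs[[run]][, , frame]
  dx
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$runs, function(a) dim(a)[3], integer(1))
  cat("<trajectory_ensemble>", length(x$runs), "run(s) x", nf[1],
      "frame(s),", x$topology$n_pairs, "bp,",
      "burn-in", x$burn_in, "frame(s)\n")
  invisible(x)
}

#' Overall dimensions of a duplex along its helix axis
#'
#' Fits the helix axis as the principal axis of the base-pair origins and
#' reports the end-to-end atom extent projected on the axis plus the width
#' (twice the maximal atom distance from the axis).
#'
#' @param duplex A `duplex`.
#' @return Named numeric vector `c(length = , width = )`, Angstrom.
#' @export
helix_dimensions <- function(duplex) {
  m <- measure_duplex(duplex)
  origins <- t(vapply(m$pair_frames, function(f) f$o, numeric(3)))
  ctr <- colMeans(origins)
  ax <- svd(sweep(origins, 2, ctr))$v[, 1]
  xyz <- sweep(duplex_coords(duplex), 2, ctr)
  proj <- as.numeric(xyz %*% ax)
  perp <- xyz - outer(proj, ax)
  c(length = max(proj) - min(proj),
    width = 2 * sqrt(max(rowSums(perp^2))))
}
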