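# Base-frame fitting and the twelve helical parameters.

#' Fit a base reference frame to observed coordinates
#'
#' Least-squares rigid superposition (rotation + translation, no scaling)
#' of the idealized ring atoms of the base type onto the observed ring
#' atoms; the base frame is the ideal pair-frame axes mapped through that
#' transform.
#'
#' @param coords Data frame with columns `atom`, `x`, `y`, `z` holding the
#'   observed nucleotide (at least all ring atoms), or a `duplex` atom
#'   subset.
#' @param base Base letter, one of A/C/G/T.
#' @return A `base_frame`: list with `R` (3x3 rotation, columns are the
#'   x/y/z axes in global coordinates) and `o` (origin, Angstrom).
#' @export
fit_base_frame <- function(coords, base) {
  ring <- ring_atom_names(base)
  idx <- match(ring, coords$atom)
  if (anyNA(idx)) {
    stop("missing ring atom(s) for base ", base, ": ",
         paste(ring[is.na(idx)], collapse = ", "))
  }
  obs <- as.matrix(coords[idx, c("x", "y", "z")])
  tpl <- base_geometry(base)
  ref <- as.matrix(tpl[match(ring, tpl$atom), c("x", "y", "z")])
  fit <- kabsch(ref, obs)
  structure(list(R = fit$R, o = fit$t), class = "base_frame")
}

#' Base-pair parameters from two base frames
#'
#' The strand-II frame is flipped about its x-axis; the six mid-frame
#' coordinates between the flipped strand-II frame and the strand-I frame
#' are reported as shear, stretch, stagger (Angstrom) and buckle,
#' propeller, opening (degrees).  An error is raised when the two base
#' normals are not antiparallel (pairing violation).
#'
#' @param frame_i Strand-I base frame (from [fit_base_frame()]).
#' @param frame_ii Strand-II base frame.
#' @return Named numeric vector of the six pair parameters, with the pair
#'   mid-frame attached as attribute `"pair_frame"`.
#' @export
pair_parameters <- function(frame_i, frame_ii) {
  flipped <- list(R = frame_ii$R %*% FLIP_MAT, o = frame_ii$o)
  dec <- cehs_decompose(flipped, frame_i)
  out <- c(dec$trans, dec$rot)
  names(out) <- PAIR_PARAMS
  attr(out, "pair_frame") <- dec$mid
  out
}

#' Base-step parameters from two successive pair frames
#'
#' @param pair_frame_i,pair_frame_j Mid-frames of pairs `i` and `i + 1`
#'   (attribute `"pair_frame"` of [pair_parameters()]).
#' @return Named numeric vector: shift, slide, rise (Angstrom), tilt,
#'   roll, twist (degrees).
#' @export
step_parameters <- function(pair_frame_i, pair_frame_j) {
  dec <- cehs_decompose(pair_frame_i, pair_frame_j)
  out <- c(dec$trans, dec$rot)
  names(out) <- STEP_PARAMS
  out
}

#' Lambda angles of a base pair
#'
#' Angle, per strand, between the glycosidic bond (C1' to N1/N9) and the
#' C1'-C1' vector pointing toward the partner nucleotide; both vectors are
#' taken from the C1' atom, giving the conventional value near 52 degrees
#' for a canonical pair.
#'
#' @param duplex A `duplex`.
#' @param pair Pair index.
#' @return Named numeric vector `c(lambda_1, lambda_2)` in degrees
#'   (strand I, strand II).
#' @export
lambda_angles <- function(duplex, pair) {
  c1_i <- duplex_atom(duplex, "I", pair, "C1'")
  c1_ii <- duplex_atom(duplex, "II", pair, "C1'")
  b_i <- duplex$sequence[pair]
  b_ii <- duplex$pairing[pair]
  n_i <- duplex_atom(duplex, "I", pair, GLYCOSIDIC_N[[b_i]])
  n_ii <- duplex_atom(duplex, "II", pair, GLYCOSIDIC_N[[b_ii]])
  c(lambda_1 = vec_angle(n_i - c1_i, c1_ii - c1_i),
    lambda_2 = vec_angle(n_ii - c1_ii, c1_i - c1_ii))
}

#' @noRd
#' All base frames of one duplex frame; strand II frames are the unflipped
#' fitted frames.
duplex_base_frames <- function(duplex) {
  n <- duplex$n_pairs
  fI <- vector("list", n); fII <- vector("list", n)
  a <- duplex$atoms
  for (i in seq_len(n)) {
    fI[[i]] <- fit_base_frame(a[a$strand == "I" & a$pair == i, , drop = FALSE],
                              duplex$sequence[i])
    fII[[i]] <- fit_base_frame(a[a$strand == "II" & a$pair == i, , drop = FALSE],
                               duplex$pairing[i])
  }
  list(I = fI, II = fII)
}

#' @noRd
#' Inverse of build_duplex for a single frame
measure_duplex <- function(duplex, flip_spec = NULL) {
  n <- duplex$n_pairs
  frames <- duplex_base_frames(duplex)
  pair <- matrix(NA_real_, n, 6, dimnames = list(NULL, PAIR_PARAMS))
  lambda <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("lambda_1", "lambda_2")))
  pair_frames <- vector("list", n)
  for (i in seq_len(n)) {
    pp <- pair_parameters(frames$I[[i]], frames$II[[i]])
    pair[i, ] <- pp
    pair_frames[[i]] <- attr(pp, "pair_frame")
    lambda[i, ] <- lambda_angles(duplex, i)
  }
  step <- matrix(NA_real_, max(n - 1, 0), 6, dimnames = list(NULL, STEP_PARAMS))
  for (i in seq_len(max(n - 1, 0))) {
    step[i, ] <- step_parameters(pair_frames[[i]], pair_frames[[i + 1]])
  }
  out <- list(state = helical_state(pair, step), lambda = lambda,
              pair_frames = pair_frames)
  if (!is.null(flip_spec)) out$flip <- flip_angle(duplex, flip_spec)
  out
}

#' Measure all structural observables of a frame or ensemble
#'
#' Applies base-frame fitting, the twelve helical parameters and the
#' lambda angles to a single `duplex` frame or to every frame of a
#' [trajectory_ensemble]; optionally also the pseudo-dihedral flip angle.
#' For ensembles the result is a long table carrying the burn-in mask so
#' downstream analyses can mirror the discard-early-frames rule.
#'
#' @param x A `duplex` or a `trajectory_ensemble`.
#' @param flip_spec Optional [flip_angle_spec()]; when supplied the flip
#'   angle is measured per frame.
#' @return For a `duplex`: list with `state` ([helical_state]), `lambda`
#'   (n x 2 matrix) and optionally `flip`.  For an ensemble: data frame
#'   with columns `run`, `frame`, `burn_in`, `kind` (`"pair"`, `"step"`,
#'   `"lambda"`, `"flip"`), `index`, `parameter`, `value`.
#' @export
measure_all <- function(x, flip_spec = NULL) {
  if (inherits(x, "duplex")) {
    m <- measure_duplex(x, flip_spec)
    return(m[c("state", "lambda", if (!is.null(flip_spec)) "flip")])
  }
  if (!inherits(x, "trajectory_ensemble")) {
    stop("x must be a duplex or a trajectory_ensemble")
  }
  plan <- duplex_plan(x$topology, flip_spec = flip_spec)
  n <- x$topology$n_pairs
  # fixed per-frame observable layout
  kind <- c(rep("pair", n * 6), if (n > 1) rep("step", (n - 1) * 6),
            rep("lambda", n * 2),
            if (!is.null(flip_spec)) "flip")
  index <- c(rep(seq_len(n), 6), if (n > 1) rep(seq_len(n - 1), 6),
             rep(seq_len(n), 2), if (!is.null(flip_spec)) flip_spec$pair)
  parameter <- c(rep(PAIR_PARAMS, each = n),
                 if (n > 1) rep(STEP_PARAMS, each = n - 1),
                 rep(c("lambda_1", "lambda_2"), each = n),
                 if (!is.null(flip_spec)) "flip_angle")
  k <- length(kind)
  res <- vector("list", length(x$runs))
  for (r in seq_along(x$runs)) {
    nf <- dim(x$runs[[r]])[3]
    vals <- matrix(NA_real_, k, nf)
    for (f in seq_len(nf)) {
      m <- measure_frame(plan, x$runs[[r]][, , f])
      vals[, f] <- c(as.vector(m$pair), if (n > 1) as.vector(m$step),
                     as.vector(m$lambda), if (!is.null(flip_spec)) m$flip)
    }
    res[[r]] <- data.frame(
      run = r, frame = rep(seq_len(nf), each = k),
      burn_in = rep(seq_len(nf) <= x$burn_in, each = k),
      kind = rep(kind, nf), index = rep(index, nf),
      parameter = rep(parameter, nf), value = as.vector(vals))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract one observable series per run from a measurement table
#'
#' Convenience accessor on the long table returned by [measure_all()]:
#' returns the per-run series of one parameter at one index, with burn-in
#' frames dropped by default.
#'
#' @param measurements Data frame from [measure_all()].
#' @param parameter Parameter name (e.g. `"opening"`, `"twist"`,
#'   `"flip_angle"`).
#' @param index Pair or step index.
#' @param drop_burn_in Drop frames inside the burn-in window (default TRUE).
#' @return Named list of numeric vectors, one per run.
#' @export
observable_series <- function(measurements, parameter, index,
                              drop_burn_in = TRUE) {
  m <- measurements[measurements$parameter == parameter &
                      measurements$index == index, , drop = FALSE]
  if (drop_burn_in) m <- m[!m$burn_in, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for ", parameter, " at index ", index)
  split(m$value, m$run)
}
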