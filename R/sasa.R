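# Solvent-accessible surface area, Shrake-Rupley style with a
# deterministic quasi-uniform sphere sampling (golden-spiral lattice).

#' SASA configuration
#'
#' @param probe_radius Probe radius, Angstrom (default 1.4, water).
#' @param radii Named van der Waals radius table (default [vdw_radii()]).
#' @param n_points Sphere points per atom (default 960).
#' @return An object of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 1.4, radii = vdw_radii(),
                        n_points = 960) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (any(radii <= 0)) stop("radii must be > 0")
  structure(list(probe_radius = probe_radius, radii = radii,
                 n_points = as.integer(n_points)), class = "sasa_config")
}

#' @noRd
#' Deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' For each selected atom, test points on the expanded sphere of radius
#' `r_vdw + probe` are kept when the probe centre placed there penetrates
#' no other expanded atom sphere; the accessible fraction times the
#' expanded-sphere area is the atom's SASA.  Deterministic for a fixed
#' point count and additive over atoms.
#'
#' @param duplex A `duplex` frame (or any data frame with `atom`,
#'   `element`, `x`, `y`, `z`).
#' @param config A [sasa_config()].
#' @param selection Logical or integer index of atoms to report (default
#'   all); all atoms always act as occluders.
#' @return Numeric vector of areas (Angstrom^2) for the selected atoms,
#'   named by atom name.
#' @export
sasa <- function(duplex, config = sasa_config(), selection = NULL) {
  a <- if (inherits(duplex, "duplex")) duplex$atoms else duplex
  unknown <- setdiff(unique(a$element), names(config$radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " (atoms ", paste(unique(a$atom[a$element %in% unknown]),
                           collapse = ", "), ")")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- config$radii[a$element] + config$probe_radius
  sel <- if (is.null(selection)) seq_len(nrow(a)) else seq_len(nrow(a))[selection]
  pts <- sphere_points(config$n_points)
  out <- numeric(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    ri <- rad[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(nrow(a)) != i)
    if (!length(nb)) {
      out[k] <- 4 * pi * ri^2
      next
    }
    surf <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(surf))
    for (j in nb) {
      if (!any(free)) break
      dj <- colSums((t(surf[free, , drop = FALSE]) - xyz[j, ])^2)
      free[free] <- dj >= rad[j]^2
    }
    out[k] <- 4 * pi * ri^2 * mean(free)
  }
  names(out) <- a$atom[sel]
  out
}

#' Profile of a per-frame quantity against the flip angle
#'
#' Assigns every analyzed frame (burn-in excluded) to a flip-angle bin
#' and reports the per-bin mean over all frames together with the
#' standard error over runs (per-run bin means, then SE across the runs
#' populating the bin).  Empty bins are omitted.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param quantity Function `duplex -> numeric scalar` evaluated per
#'   frame (e.g. a SASA sum or a hydrogen-bond count), or a precomputed
#'   list of per-run numeric vectors.
#' @param flip_spec A [flip_angle_spec()].
#' @param bin_width Flip-angle bin width, degrees (default 2).
#' @return Data frame: `center`, `mean`, `se`, `n_frames`, `n_runs`.
#' @export
profile_vs_flip <- function(ensemble, quantity, flip_spec, bin_width = 2) {
  per_frame <- list()
  for (r in seq_along(ensemble$runs)) {
    nf <- dim(ensemble$runs[[r]])[3]
    use <- setdiff(seq_len(nf), seq_len(ensemble$burn_in))
    q <- if (is.function(quantity)) {
      vapply(use, function(f) quantity(get_frame(ensemble, r, f)), numeric(1))
    } else {
      quantity[[r]][use]
    }
    ang <- vapply(use, function(f) {
      flip_angle(get_frame(ensemble, r, f), flip_spec)
    }, numeric(1))
    per_frame[[r]] <- data.frame(run = r, q = q,
                                 bin = floor(ang / bin_width) * bin_width +
                                   bin_width / 2)
  }
  tab <- do.call(rbind, per_frame)
  if (!nrow(tab)) stop("no analyzable frames")
  centers <- sort(unique(tab$bin))
  res <- lapply(centers, function(ct) {
    sub <- tab[tab$bin == ct, , drop = FALSE]
    run_means <- tapply(sub$q, sub$run, mean)
    data.frame(center = ct, mean = mean(sub$q),
               se = if (length(run_means) >= 2) {
                 stats::sd(run_means) / sqrt(length(run_means))
               } else NA_real_,
               n_frames = nrow(sub), n_runs = length(run_means))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
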