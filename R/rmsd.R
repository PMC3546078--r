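# Superposition RMSD between frames.

#' Minimum RMSD after rigid superposition
#'
#' Superposes the selected atoms of `frame` onto `reference` by the
#' optimal rotation + translation (Kabsch) and returns the residual RMSD.
#'
#' @param frame,reference `duplex` objects sharing a topology, or plain
#'   `n x 3` coordinate matrices.
#' @param selection Logical or integer index into the atom table (or the
#'   rows of the matrices); default all atoms.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(frame, reference, selection = NULL) {
  xyz <- function(x, sel) {
    m <- if (inherits(x, "duplex")) duplex_coords(x) else as.matrix(x)
    if (!is.null(sel)) m <- m[sel, , drop = FALSE]
    m
  }
  obs <- xyz(frame, selection)
  ref <- xyz(reference, selection)
  if (nrow(obs) != nrow(ref)) {
    stop("selection size mismatch: ", nrow(obs), " vs ", nrow(ref))
  }
  fit <- kabsch(ref, obs)
  moved <- ref %*% t(fit$R)
  moved <- sweep(moved, 2, fit$t, "+")
  sqrt(mean(rowSums((obs - moved)^2)))
}
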