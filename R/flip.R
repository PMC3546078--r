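# Pseudo-dihedral base-flip coordinate.
#
# The flip angle is the dihedral of four mass-weighted centres of mass:
#   1. heavy atoms of the flipping base,
#   2. the sugar of the same nucleotide,
#   3. the sugar of the neighbouring nucleotide (3' by default),
#   4. the neighbour's base plus the base paired to the neighbour
#      ("figure1" preset), optionally plus that partner's sugar
#      ("methods_text" preset).
# Reported in [0, 360) so that the 10-180 degree biasing window of the
# major-groove opening pathway is contiguous.

#' Specification of the base-flip pseudo-dihedral
#'
#' @param strand Strand of the flipping nucleotide, `"I"` or `"II"`.
#' @param pair Pair index of the flipping nucleotide.
#' @param neighbor_direction `"3'"` (default) or `"5'"`: which neighbour
#'   along the flipping strand supplies groups 3 and 4.
#' @param group_preset `"figure1"` (group 4 = neighbour base + its
#'   partner's base) or `"methods_text"` (additionally the partner's
#'   sugar).
#' @return An object of class `flip_angle_spec`.
#' @export
flip_angle_spec <- function(strand = "I", pair, neighbor_direction = "3'",
                            group_preset = c("figure1", "methods_text")) {
  group_preset <- match.arg(group_preset)
  if (!strand %in% c("I", "II")) stop("strand must be 'I' or 'II'")
  if (!neighbor_direction %in% c("3'", "5'")) {
    stop("neighbor_direction must be \"3'\" or \"5'\"")
  }
  structure(list(strand = strand, pair = pair,
                 neighbor_direction = neighbor_direction,
                 group_preset = group_preset),
            class = "flip_angle_spec")
}

#' @noRd
#' Pair index of the neighbour: strand I runs 5'->3' with increasing pair
#' index, strand II antiparallel.
neighbor_pair <- function(spec) {
  towards3 <- spec$neighbor_direction == "3'"
  if (spec$strand == "I") {
    if (towards3) spec$pair + 1 else spec$pair - 1
  } else {
    if (towards3) spec$pair - 1 else spec$pair + 1
  }
}

#' @noRd
flip_groups <- function(duplex, spec) {
  a <- duplex$atoms
  np <- neighbor_pair(spec)
  if (np < 1 || np > duplex$n_pairs) {
    stop("flip-angle neighbour (pair ", np, ") outside the duplex")
  }
  other <- if (spec$strand == "I") "II" else "I"
  base_sel <- function(strand, pair) {
    a$strand == strand & a$pair == pair & a$role %in% c("ring", "base")
  }
  sugar_sel <- function(strand, pair) {
    a$strand == strand & a$pair == pair & a$role == "sugar"
  }
  g1 <- base_sel(spec$strand, spec$pair)
  g2 <- sugar_sel(spec$strand, spec$pair)
  g3 <- sugar_sel(spec$strand, np)
  g4 <- base_sel(spec$strand, np) | base_sel(other, np)
  if (spec$group_preset == "methods_text") {
    g4 <- g4 | sugar_sel(other, np)
  }
  list(g1, g2, g3, g4)
}

#' @noRd
group_com <- function(duplex, sel) {
  a <- duplex$atoms[sel, , drop = FALSE]
  if (!nrow(a)) stop("empty atom group in flip-angle computation")
  w <- a$mass / sum(a$mass)
  c(sum(a$x * w), sum(a$y * w), sum(a$z * w))
}

#' Pseudo-dihedral flip angle of a base
#'
#' Dihedral of the four mass-weighted group centres of mass defined by
#' `spec`, in degrees within [0, 360).  In the canonical flipped-in
#' conformation the angle sits near 35-50 degrees and grows toward 180 as
#' the base opens through the major groove.
#'
#' @param duplex A `duplex` frame.
#' @param spec A [flip_angle_spec()].
#' @return Numeric scalar, degrees in [0, 360).
#' @export
flip_angle <- function(duplex, spec) {
  gs <- flip_groups(duplex, spec)
  coms <- lapply(gs, function(sel) group_com(duplex, sel))
  dihedral4(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
}

#' @noRd
#' Rotate the flipping nucleotide about the COM2-COM3 axis so the measured
#' flip angle equals `target` (degrees).  Used by the sweep generator;
#' exact because COM1 rotates rigidly about the dihedral axis while COM2
#' and COM3 are invariant.
set_flip_angle <- function(duplex, spec, target) {
  gs <- flip_groups(duplex, spec)
  com2 <- group_com(duplex, gs[[2]])
  com3 <- group_com(duplex, gs[[3]])
  cur <- flip_angle(duplex, spec)
  delta <- (target - cur) %% 360
  axis <- com3 - com2
  sel <- duplex$atoms$strand == spec$strand & duplex$atoms$pair == spec$pair
  rot_about <- function(dx, ang) {
    R <- rot_axis(axis, ang)
    xyz <- as.matrix(dx$atoms[sel, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, com2)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, com2, "+")
    dx$atoms[sel, c("x", "y", "z")] <- xyz
    dx
  }
  out <- rot_about(duplex, delta)
  # the rotation sense depends on the axis orientation; fall back once
  if (abs(((flip_angle(out, spec) - target + 180) %% 360) - 180) > 1e-6) {
    out <- rot_about(duplex, -delta)
  }
  out
}
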