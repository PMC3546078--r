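# Hydrogen-bond detection and occupancy.
#
# Geometric criterion: donor-acceptor distance <= 3.0 Angstrom AND
# acceptor-hydrogen-donor angle >= 135 degrees, both boundaries inclusive.

#' Hydrogen-bond geometric criteria
#'
#' @param max_distance Maximal donor-acceptor heavy-atom distance,
#'   Angstrom (default 3.0, inclusive).
#' @param min_angle Minimal acceptor-hydrogen-donor angle, degrees
#'   (default 135, inclusive).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.0, min_angle = 135) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' @noRd
#' Donor (heavy, hydrogen) and acceptor atom rows of a duplex, restricted
#' to selected pairs when given.
hbond_sites <- function(duplex, pairs = NULL, table = donor_acceptor_table()) {
  a <- duplex$atoms
  if (!is.null(pairs)) a <- a[a$pair %in% pairs, , drop = FALSE]
  a$.row <- seq_len(nrow(a))
  don <- merge(a, table$donors, by.x = c("base", "atom"),
               by.y = c("base", "donor"))
  if (nrow(don)) {
    hyd <- a[match(paste(don$strand, don$pair, don$hydrogen),
                   paste(a$strand, a$pair, a$atom)), , drop = FALSE]
    missing_h <- is.na(hyd$atom)
    if (any(missing_h)) {
      warning("donor(s) without attached hydrogen skipped: ",
              paste(unique(don$atom[missing_h]), collapse = ", "))
      don <- don[!missing_h, , drop = FALSE]
      hyd <- hyd[!missing_h, , drop = FALSE]
    }
  } else {
    hyd <- don
  }
  acc <- merge(a, table$acceptors, by.x = c("base", "atom"),
               by.y = c("base", "acceptor"))
  list(donors = don, hydrogens = hyd, acceptors = acc)
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates all donor/acceptor combinations from the donor-acceptor
#' table (excluding donor and acceptor on the same nucleotide) and returns
#' the triples satisfying both inclusive criteria.
#'
#' @param duplex A `duplex` frame.
#' @param criteria An [hbond_criteria()].
#' @param pairs Optional pair indices to restrict the search to.
#' @param table Donor/acceptor definition, see [donor_acceptor_table()].
#' @return Data frame with one row per bond: donor and acceptor identity
#'   (`donor_strand`, `donor_pair`, `donor_base`, `donor_atom`,
#'   `hydrogen`, and the acceptor analogues), `distance` (Angstrom) and
#'   `angle` (degrees).
#' @export
detect_hbonds <- function(duplex, criteria = hbond_criteria(), pairs = NULL,
                          table = donor_acceptor_table()) {
  s <- hbond_sites(duplex, pairs, table)
  out <- list()
  if (nrow(s$donors) && nrow(s$acceptors)) {
    dxyz <- as.matrix(s$donors[, c("x", "y", "z")])
    hxyz <- as.matrix(s$hydrogens[, c("x", "y", "z")])
    axyz <- as.matrix(s$acceptors[, c("x", "y", "z")])
    for (i in seq_len(nrow(s$donors))) {
      same <- s$acceptors$strand == s$donors$strand[i] &
        s$acceptors$pair == s$donors$pair[i]
      d2 <- colSums((t(axyz) - dxyz[i, ])^2)
      cand <- which(!same & d2 <= criteria$max_distance^2)
      for (j in cand) {
        v1 <- axyz[j, ] - hxyz[i, ]
        v2 <- dxyz[i, ] - hxyz[i, ]
        ang <- vec_angle(v1, v2)
        if (ang >= criteria$min_angle) {
          out[[length(out) + 1]] <- data.frame(
            donor_strand = s$donors$strand[i], donor_pair = s$donors$pair[i],
            donor_base = s$donors$base[i], donor_atom = s$donors$atom[i],
            hydrogen = s$donors$hydrogen[i],
            acceptor_strand = s$acceptors$strand[j],
            acceptor_pair = s$acceptors$pair[j],
            acceptor_base = s$acceptors$base[j],
            acceptor_atom = s$acceptors$atom[j],
            distance = sqrt(d2[j]), angle = ang,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_strand = character(), donor_pair = integer(),
                      donor_base = character(), donor_atom = character(),
                      hydrogen = character(), acceptor_strand = character(),
                      acceptor_pair = integer(), acceptor_base = character(),
                      acceptor_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Fraction of analyzed frames (burn-in excluded) in which the specified
#' donor-acceptor contact satisfies the criteria, evaluated per run and
#' then averaged: mean occupancy in percent with the standard error over
#' runs (absent with a single run).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param donor Named list or vector identifying the donor nucleotide and
#'   atom: `strand`, `pair`, `atom`.
#' @param acceptor Same for the acceptor.
#' @param criteria An [hbond_criteria()].
#' @return Data frame (one row): donor/acceptor ids, `occupancy` (mean
#'   percent over runs), `se` (NA for a single run), `n_runs`.
#' @export
hbond_occupancy <- function(ensemble, donor, acceptor,
                            criteria = hbond_criteria()) {
  a <- ensemble$topology$atoms
  row_of <- function(id, atom_name) {
    k <- which(a$strand == id[["strand"]] & a$pair == as.integer(id[["pair"]]) &
                 a$atom == atom_name)
    if (length(k) != 1) stop("atom ", atom_name, " of pair ", id[["pair"]],
                             " strand ", id[["strand"]], " not found")
    k
  }
  dr <- row_of(donor, donor[["atom"]])
  ar <- row_of(acceptor, acceptor[["atom"]])
  tab <- donor_acceptor_table()$donors
  hyd <- tab$hydrogen[tab$base == a$base[dr] & tab$donor == donor[["atom"]]]
  if (!length(hyd)) stop("atom ", donor[["atom"]], " is not a donor")
  hr <- vapply(hyd, function(h) row_of(donor, h), integer(1))
  per_run <- vapply(seq_along(ensemble$runs), function(r) {
    co <- ensemble$runs[[r]]
    nf <- dim(co)[3]
    use <- setdiff(seq_len(nf), seq_len(ensemble$burn_in))
    if (!length(use)) stop("no analyzable frames after burn-in")
    dd <- sqrt(colSums((co[dr, , use] - co[ar, , use])^2))
    ok_ang <- rep(FALSE, length(use))
    for (h in hr) {
      v1 <- co[ar, , use] - co[h, , use]
      v2 <- co[dr, , use] - co[h, , use]
      cosang <- colSums(v1 * v2) /
        sqrt(colSums(v1^2) * colSums(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) / DEG
      ok_ang <- ok_ang | ang >= criteria$min_angle
    }
    100 * mean(dd <= criteria$max_distance & ok_ang)
  }, numeric(1))
  n <- length(per_run)
  data.frame(donor_strand = donor[["strand"]], donor_pair = as.integer(donor[["pair"]]),
             donor_atom = donor[["atom"]], acceptor_strand = acceptor[["strand"]],
             acceptor_pair = as.integer(acceptor[["pair"]]),
             acceptor_atom = acceptor[["atom"]],
             occupancy = mean(per_run),
             se = if (n >= 2) stats::sd(per_run) / sqrt(n) else NA_real_,
             n_runs = n, stringsAsFactors = FALSE)
}
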