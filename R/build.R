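# Forward model: idealized duplex coordinates from helical parameters.

#' Build a B-DNA duplex from helical parameters
#'
#' Constructs atomic coordinates of a DNA duplex whose base-pair and
#' base-step parameters are exactly the supplied [helical_state]: base-pair
#' frames are propagated 5' to 3' along strand I with the six step
#' parameters, each pair frame is split into the two base frames with the
#' six pair parameters, and the idealized nucleotide template of each base
#' ([base_geometry]) is placed rigidly in its base frame (strand II through
#' the 180-degree flip about the frame x-axis, making the strands
#' antiparallel).  The construction is the exact inverse of
#' [measure_all()]: measuring a built duplex returns `state` to near
#' machine precision.
#'
#' @param sequence Character scalar, strand I bases 5' to 3' (e.g.
#'   `"GCTCTGTACGTGAGCAG"`), or a character vector of single letters.
#' @param pairing Strand II bases by pair index (aligned with `sequence`,
#'   so `pairing[i]` is paired with `substr(sequence, i, i)`).  Defaults to
#'   the Watson-Crick complement; supplying e.g. a `"G"` opposite a `"T"`
#'   creates a mismatched (wobble-like) pair.
#' @param state A [helical_state] with one row per pair; defaults to the
#'   canonical straight B form.
#' @return An object of class `duplex`: list with `atoms` (data frame:
#'   `atom`, `element`, `role`, `base`, `pair`, `strand`, `x`, `y`, `z`,
#'   `mass`), `sequence`, `pairing`, `n_pairs`.  5'-terminal residues
#'   carry no phosphate group.
#' @export
#' @examples
#' dx <- build_duplex("GCGC")
#' nrow(dx$atoms)
build_duplex <- function(sequence, pairing = NULL,
                         state = canonical_b_state(length(seq_letters(sequence)))) {
  bases_i <- seq_letters(sequence)
  n <- length(bases_i)
  if (n == 0) stop("sequence must be non-empty")
  bad <- which(!bases_i %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("unknown base letter '", bases_i[bad[1]], "' at position ", bad[1])
  }
  if (is.null(pairing)) {
    bases_ii <- wc_complement(bases_i)
  } else {
    bases_ii <- seq_letters(pairing)
    if (length(bases_ii) != n) stop("pairing length must match sequence length")
    bad <- which(!bases_ii %in% c("A", "C", "G", "T"))
    if (length(bad)) {
      stop("unknown base letter '", bases_ii[bad[1]], "' at pairing position ", bad[1])
    }
  }
  if (!inherits(state, "helical_state")) stop("state must be a helical_state")
  if (nrow(state$pair) != n) {
    stop("dimension mismatch: state has ", nrow(state$pair),
         " pairs but sequence has ", n)
  }

  pair_frame <- list(R = diag(3), o = c(0, 0, 0))
  rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    if (i > 1) {
      pair_frame <- cehs_compose(pair_frame, state$step[i - 1, 1:3],
                                 state$step[i - 1, 4:6])$frame
    }
    sp <- cehs_split(pair_frame, state$pair[i, 1:3], state$pair[i, 4:6])
    # frame_i is the flipped strand-II frame, frame_j the strand-I frame
    rows[[2 * i - 1]] <- place_nucleotide(bases_i[i], sp$frame_j, flip = FALSE,
                                          pair = i, strand = "I",
                                          five_prime = (i == 1))
    rows[[2 * i]] <- place_nucleotide(bases_ii[i], sp$frame_i, flip = TRUE,
                                      pair = i, strand = "II",
                                      five_prime = (i == n))
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, sequence = bases_i, pairing = bases_ii,
                 n_pairs = n), class = "duplex")
}

#' @noRd
seq_letters <- function(sequence) {
  if (length(sequence) == 1) {
    strsplit(toupper(sequence), "")[[1]]
  } else {
    toupper(as.character(sequence))
  }
}

#' @noRd
place_nucleotide <- function(base, frame, flip, pair, strand, five_prime) {
  tpl <- base_geometry(base)
  if (five_prime) {
    tpl <- tpl[!tpl$atom %in% c("P", "OP1", "OP2"), , drop = FALSE]
  }
  local <- as.matrix(tpl[, c("x", "y", "z")])
  if (flip) local <- local %*% FLIP_MAT  # FLIP_MAT is symmetric
  glob <- local %*% t(frame$R)
  glob <- sweep(glob, 2, frame$o, "+")
  data.frame(atom = tpl$atom, element = tpl$element, role = tpl$role,
             base = base, pair = pair, strand = strand,
             x = glob[, 1], y = glob[, 2], z = glob[, 3],
             mass = tpl$mass, stringsAsFactors = FALSE)
}

#' @export
print.duplex <- function(x, ...) {
  cat("<duplex>", x$n_pairs, "base pairs,", nrow(x$atoms), "atoms\n")
  cat("strand I  5'-", paste(x$sequence, collapse = ""), "-3'\n", sep = "")
  cat("strand II 3'-", paste(x$pairing, collapse = ""), "-5'\n", sep = "")
  invisible(x)
}

#' @noRd
#' Coordinates of one named atom of one nucleotide
duplex_atom <- function(duplex, strand, pair, atom) {
  a <- duplex$atoms
  k <- which(a$strand == strand & a$pair == pair & a$atom == atom)
  if (length(k) != 1) {
    stop("atom ", atom, " of pair ", pair, " strand ", strand,
         " not found exactly once")
  }
  c(a$x[k], a$y[k], a$z[k])
}

#' @noRd
duplex_coords <- function(duplex, sel = TRUE) {
  as.matrix(duplex$atoms[sel, c("x", "y", "z")])
}
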