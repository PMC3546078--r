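# Idealized nucleotide geometry and the chemical look-up tables.
#
# Base/sugar/phosphate template coordinates live in
# inst/extdata/base_templates.tsv.  They were derived from the ideal residue
# geometries of the Chemical Component Dictionary (entries DA/DC/DG/DT):
# bases planarized, the glycosidic torsion set to a B-form anti value, one
# common sugar-phosphate unit grafted onto all four bases, and each
# nucleotide posed in a base-pair reference frame in which the Watson-Crick
# partner is obtained by the 180-degree rotation about x.  The derivation
# script is shipped in data-raw/.

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041

PURINES <- c("A", "G")

RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

GLYCOSIDIC_N <- c(A = "N9", G = "N9", C = "N1", T = "N1")

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

# environment caching the parsed template table
.template_cache <- new.env(parent = emptyenv())

load_base_templates <- function() {
  if (!is.null(.template_cache$tab)) return(.template_cache$tab)
  path <- system.file("extdata", "base_templates.tsv", package = "duplexflip")
  if (path == "") path <- file.path("inst", "extdata", "base_templates.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  tab$mass <- ATOMIC_MASS[tab$element]
  .template_cache$tab <- tab
  tab
}

#' Idealized base/nucleotide geometry in the pair reference frame
#'
#' Returns the template atoms of one nucleotide (base heavy atoms, polar
#' base hydrogens, sugar and phosphate) in the base-pair reference frame of
#' this package.  In that frame a Watson-Crick partner base is obtained by
#' rotating its own template 180 degrees about the x-axis, and a duplex is
#' built by propagating pair frames with the six base-step parameters.
#'
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A data frame with columns `atom`, `element`, `role` (one of
#'   `ring`, `base`, `sugar`, `backbone`, `hpolar`), coordinates `x`, `y`,
#'   `z` (Angstrom) and `mass` (amu).
#' @export
#' @examples
#' g <- base_geometry("G")
#' g[g$role == "ring", "atom"]
base_geometry <- function(base) {
  if (!base %in% c("A", "C", "G", "T")) {
    stop("unknown base letter: ", base)
  }
  tab <- load_base_templates()
  tab[tab$base == base, setdiff(names(tab), "base"), drop = FALSE]
}

#' @noRd
ring_atom_names <- function(base) RING_ATOMS[[base]]

#' Hydrogen-bond donor and acceptor atoms per base type
#'
#' The canonical donor/acceptor assignment for the four DNA bases plus
#' water.  Donors are (heavy atom, attached hydrogen) pairs; acceptors are
#' heavy atoms.
#'
#' @return A list with components `donors` (data frame: `base`, `donor`,
#'   `hydrogen`) and `acceptors` (data frame: `base`, `acceptor`).
#' @export
donor_acceptor_table <- function() {
  donors <- rbind(
    data.frame(base = "G", donor = "N1", hydrogen = "H1"),
    data.frame(base = "G", donor = "N2", hydrogen = c("H21", "H22")),
    data.frame(base = "T", donor = "N3", hydrogen = "H3"),
    data.frame(base = "C", donor = "N4", hydrogen = c("H41", "H42")),
    data.frame(base = "A", donor = "N6", hydrogen = c("H61", "H62")),
    data.frame(base = "W", donor = "O", hydrogen = c("H1", "H2"))
  )
  acceptors <- data.frame(
    base = c("G", "G", "G", "T", "T", "C", "C", "A", "A", "A", "W"),
    acceptor = c("O6", "N3", "N7", "O2", "O4", "O2", "N3", "N1", "N3", "N7", "O")
  )
  list(donors = donors, acceptors = acceptors)
}

#' Van der Waals radii used for surface-area calculations
#'
#' Bondi radii for the elements occurring in nucleic acids, Angstrom.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80)
}

#' @noRd
#' Canonical Watson-Crick complement
wc_complement <- function(bases) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  unname(comp[bases])
}
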