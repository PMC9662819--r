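#' Bundled amino-acid property tables
#'
#' Two lookup tables derived from the AAindex database and standard
#' references ship with the package:
#'
#' * `aa_physicochemical()` — the eight wild-type physicochemical
#'   residue features used in the site feature matrix: molecular weight
#'   of the free amino acid (Da), number of electrostatic charges at
#'   neutral pH (His counted as 0.1 for its partial protonation),
#'   Kyte-Doolittle hydrophobicity, aromaticity (ring indicator, His
#'   0.5), side-chain hydrogen-bond donor+acceptor count, Grantham
#'   polarity, Charton-Charton polarizability, and
#'   Bhaskaran-Ponnuswamy flexibility.
#' * `aa_mutation_properties()` — the six properties compared between
#'   dead and tolerated substitutions: Hopp-Woods hydrophilicity,
#'   Kyte-Doolittle hydrophobicity, Grantham polarity, residue mass
#'   (Da), theoretical maximum solvent accessibility (Tien et al.
#'   values, A^2), and Charton-Charton polarizability.
#'
#' @return A `data.frame` with one row per canonical amino acid
#'   (column `aa`, single-letter code) and one column per property.
#' @export
aa_physicochemical <- function() {
  read_aa_table("aa_physicochemical.tsv")
}

#' @rdname aa_physicochemical
#' @export
aa_mutation_properties <- function() {
  read_aa_table("aa_mutation_properties.tsv")
}

read_aa_table <- function(file) {
  path <- system.file("extdata", file, package = "allohot", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(setequal(tab$aa, AA1))
  tab[match(AA1, tab$aa), , drop = FALSE]
}
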