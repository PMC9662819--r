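#' The canonical 27-feature registry
#'
#' Every site feature matrix in the package uses the same 27 named
#' columns, grouped into three classes:
#'
#' * physicochemical (1-8): wild-type amino-acid properties looked up
#'   from [aa_physicochemical()];
#' * local (9-16): properties of the residue's immediate structural
#'   environment; four of these (backbone/sidechain conformational
#'   entropy loss, hydrogen-bond count, frustration index, local
#'   structural entropy) come from external predictors and are imported
#'   as columns rather than computed here;
#' * global (17-27): whole-structure properties — motional correlations
#'   from a Gaussian network model, distances to the DNA/ligand sites,
#'   contact-network closeness centrality, distances to the four main
#'   centrality peaks, and sequence propagation.
#'
#' The numeric indices are a package convention (the registry is
#' by-name); they order the physicochemical, local and global blocks as
#' listed above.
#'
#' @return A `data.frame` with columns `index`, `name`, `class` and
#'   `provenance` (`"computed"` or `"imported"`).
#' @export
feature_registry <- function() {
  data.frame(
    index = 1:27,
    name = c(
      "molecular_weight", "charge", "hydrophobicity", "aromaticity",
      "hbond_potential", "polarity", "polarizability", "flexibility",
      "atomic_density", "backbone_entropy_loss", "sidechain_entropy_loss",
      "sasa", "hydrogen_bonds", "frustration_index", "b_factor",
      "local_structural_entropy",
      "corr_dna", "corr_ligand", "max_correlation", "dist_dna",
      "dist_ligand", "closeness_centrality", "dist_peak1", "dist_peak2",
      "dist_peak3", "dist_peak4", "sequence_propagation"
    ),
    class = rep(c("physicochemical", "local", "global"), c(8L, 8L, 11L)),
    provenance = c(
      rep("computed", 9L), "imported", "imported", "computed", "imported",
      "imported", "computed", "imported", rep("computed", 11L)
    ),
    stringsAsFactors = FALSE
  )
}

feature_names <- function() feature_registry()$name

## Validate a residue x feature data.frame carrying the 27 registry
## columns plus `residue` and (optionally) `label`.
validate_feature_matrix <- function(fm) {
  reg <- feature_names()
  missing <- setdiff(reg, names(fm))
  if (length(missing)) {
    stopf("feature matrix is missing registry columns: %s",
          paste(missing, collapse = ", "))
  }
  bad <- reg[vapply(fm[reg], function(x) anyNA(x) || !is.numeric(x),
                    logical(1))]
  if (length(bad)) {
    stopf("feature columns with missing or non-numeric values: %s",
          paste(bad, collapse = ", "))
  }
  if (!is.null(fm$label) && !all(fm$label %in% c(0, 1))) {
    stopf("labels must be binary (0 = non-hotspot, 1 = hotspot)")
  }
  invisible(fm)
}
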