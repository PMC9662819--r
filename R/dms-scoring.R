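#' Normalize sort-seq read counts
#'
#' Two-step normalization applied before any thresholding. Step 1
#' rescales each sub-library pool so that its reads sum to
#' `total_target / n_sublibraries` across all three conditions and
#' replicates (with the default 200,000 total and two pools, each pool
#' sums to 100,000), which makes conditions, replicates and proteins
#' comparable under one common read threshold. Step 2 (only when
#' `library_sizes` is supplied and the table carries a `protein`
#' column) multiplies each protein's reads by the ratio of its
#' theoretical single-mutant library size to the smallest library size
#' among the proteins compared, so that larger mutant libraries are not
#' penalized for spreading the same sequencing budget over more
#' variants. Normalized counts are kept real-valued; thresholds are
#' applied to the normalized values.
#'
#' @param table Count table (see [generate_dms_counts()] for schema).
#' @param total_target Total normalized reads per protein across all
#'   conditions and replicates.
#' @param library_sizes Named numeric vector of theoretical mutant
#'   counts per protein (names matching the `protein` column), or
#'   `NULL` to skip the cross-protein step.
#' @return The table with `reads` replaced by normalized (real) values.
#' @export
normalize_counts <- function(table, total_target = 200000,
                             library_sizes = NULL) {
  tab <- data.table::as.data.table(table)
  if (nrow(tab) == 0L) stopf("count table is empty")
  has_protein <- "protein" %in% names(tab)
  grp <- if (has_protein) c("protein", "sublibrary") else "sublibrary"
  n_sub <- if (has_protein) {
    tab[, data.table::uniqueN(sublibrary), by = protein]$V1[1]
  } else data.table::uniqueN(tab$sublibrary)
  pool_target <- total_target / n_sub

  totals <- tab[, .(total = sum(reads)), by = grp]
  zero <- totals[totals$total == 0]
  if (nrow(zero)) {
    stopf("sub-library %s has zero total reads; cannot normalize",
          paste(zero$sublibrary, collapse = ", "))
  }
  tab <- merge(tab, totals, by = grp, sort = FALSE)
  tab[, reads := reads * pool_target / total]
  tab[, total := NULL]

  if (has_protein && !is.null(library_sizes)) {
    prots <- unique(tab$protein)
    missing <- setdiff(prots, names(library_sizes))
    if (length(missing)) {
      stopf("library_sizes missing for: %s", paste(missing, collapse = ", "))
    }
    ref <- min(library_sizes[prots])
    tab[, reads := reads * library_sizes[[protein[1]]] / ref, by = protein]
  }
  tab[]
}

#' Call variant presence from presorted reads
#'
#' A variant is considered present in the dataset only if it has at
#' least `read_threshold` (normalized) reads in the presorted
#' population of every replicate.
#'
#' @param table Normalized count table.
#' @param read_threshold Minimum presorted reads per replicate.
#' @return A `data.table` keyed by (`position`, `wt_aa`, `mut_aa`) with
#'   a logical `present` column.
#' @export
call_presence <- function(table, read_threshold = 5) {
  tab <- data.table::as.data.table(table)
  pre <- tab[condition == "presorted",
             .(present = all(reads >= read_threshold) &
                 .N >= max(tab$replicate)),
             by = .(position, wt_aa, mut_aa)]
  data.table::setkey(pre, position, wt_aa, mut_aa)
  pre
}

#' Call dead variants per replicate
#'
#' Within a single replicate a present variant is called dead when it
#' has at least `read_threshold` reads in both the sorted-induced and
#' the sorted-uninduced populations — i.e. it occupies the
#' low-fluorescence gate whether or not inducer is supplied, the
#' signature of a repressor locked in its non-inducible state.
#' Variants dead in 1, 2 or 3 replicates carry confidence scores of 0,
#' 1 and 2 respectively; single-replicate calls are retained in the
#' output but carry zero weight downstream.
#'
#' @param table Normalized count table.
#' @param read_threshold Minimum reads in each sorted population.
#' @param presence Optional precomputed [call_presence()] table; when
#'   `NULL` it is computed from `table` with the same threshold.
#' @return A `data.table` with one row per variant: `position`,
#'   `wt_aa`, `mut_aa`, `present`, `dead_replicates`, and
#'   `confidence_score` (`NA` unless dead in at least one replicate).
#' @export
call_dead <- function(table, read_threshold = 5, presence = NULL) {
  tab <- data.table::as.data.table(table)
  if (is.null(presence)) presence <- call_presence(tab, read_threshold)

  sorted <- data.table::dcast(
    tab[condition != "presorted"],
    position + wt_aa + mut_aa + replicate ~ condition,
    value.var = "reads", fill = 0)
  sorted[, dead := sorted_induced >= read_threshold &
           sorted_uninduced >= read_threshold]
  per_var <- sorted[, .(dead_replicates = sum(dead)),
                    by = .(position, wt_aa, mut_aa)]
  calls <- merge(presence, per_var,
                 by = c("position", "wt_aa", "mut_aa"), all.x = TRUE)
  calls[is.na(dead_replicates), dead_replicates := 0L]
  calls[present == FALSE, dead_replicates := 0L]
  calls[, confidence_score := data.table::fifelse(
    present & dead_replicates >= 1L, pmin(dead_replicates, 3L) - 1L,
    NA_integer_)]
  calls[]
}

#' Weighted positional scores
#'
#' At each position `x`, let `D1`, `D2`, `D3` be the numbers of present
#' variants called dead in exactly one, two or three replicates and
#' `Total` the number of present variants; the weighted positional
#' score is `(0*D1 + 1*D2 + 2*D3) / Total`. Single-replicate calls thus
#' count for nothing, two-replicate calls have unit weight and
#' three-replicate calls double weight, so the score lies in `[0, 2]`.
#' Positions with no present variants are flagged `no_data` and carry
#' an `NA` score.
#'
#' @param calls Output of [call_dead()].
#' @return A `data.table` with `position`, `D1`, `D2`, `D3`, `Total`,
#'   `weighted_score` and `no_data`.
#' @export
position_scores <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) stopf("no variant calls supplied")
  sc <- calls[, .(
    D1 = sum(present & dead_replicates == 1L),
    D2 = sum(present & dead_replicates == 2L),
    D3 = sum(present & dead_replicates >= 3L),
    Total = sum(present)
  ), by = position]
  sc[, weighted_score := data.table::fifelse(
    Total > 0L, (0 * D1 + 1 * D2 + 2 * D3) / Total, NA_real_)]
  sc[, no_data := Total == 0L]
  data.table::setorder(sc, position)
  sc[]
}

#' Designate allosteric hotspots by the upper quartile rule
#'
#' Computes the third quartile (Q3) of the weighted positional scores
#' over all scored positions and designates every position scoring
#' strictly above Q3 as an allosteric hotspot. Positions without data
#' are excluded from the quartile computation by default (absence of
#' variants is not evidence of mutational tolerance); set
#' `include_no_data = TRUE` to count them as zero scores instead.
#'
#' @param scores Output of [position_scores()].
#' @param probs Quartile probability (0.75 = Q3).
#' @param quantile_type Percentile method passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param include_no_data Treat no-data positions as score 0.
#' @return A list of class `hotspot_set`: `q3_threshold`,
#'   `hotspot_positions`, `scores` (the score table used), and empty
#'   `ligand_excluded_positions` / `post_exclusion_hotspots` slots
#'   filled in by [exclude_ligand_contacts()].
#' @export
call_hotspots <- function(scores, probs = 0.75, quantile_type = 7,
                          include_no_data = FALSE) {
  sc <- data.table::as.data.table(scores)
  if (include_no_data) {
    sc <- data.table::copy(sc)
    sc[no_data == TRUE, weighted_score := 0]
    sc[, no_data := FALSE]
  }
  used <- sc[no_data == FALSE]
  if (nrow(used) < 4L) stopf("need at least 4 scored positions")
  q3 <- unname(stats::quantile(used$weighted_score, probs = probs,
                               type = quantile_type))
  hot <- used$position[used$weighted_score > q3]
  if (length(hot) == 0L) {
    warnf("degenerate score distribution: no position above Q3 = %g", q3)
  }
  structure(list(q3_threshold = q3,
                 hotspot_positions = sort(hot),
                 ligand_excluded_positions = integer(),
                 post_exclusion_hotspots = sort(hot),
                 scores = sc[]),
            class = "hotspot_set")
}

#' Remove ligand-contacting residues from a hotspot set
#'
#' A residue is ligand-contacting when any of its heavy atoms lies
#' within `cutoff` of any ligand heavy atom; mutations there typically
#' kill induction by destroying ligand affinity rather than allosteric
#' signalling, so such positions are set aside. Residue numbering in
#' the structure must match the score positions (monomer numbering;
#' both chains of a dimer are checked).
#'
#' @param hotspots A `hotspot_set` from [call_hotspots()].
#' @param structure An `allohot_structure` or the `atoms` table of
#'   [read_structure()].
#' @param ligand_atoms Matrix of ligand coordinates; defaults to the
#'   structure's own `ligand_sites` when present.
#' @param cutoff Contact distance in Angstrom (inclusive).
#' @return The `hotspot_set` with `ligand_excluded_positions` and
#'   `post_exclusion_hotspots` filled in.
#' @export
exclude_ligand_contacts <- function(hotspots, structure,
                                    ligand_atoms = NULL, cutoff = 5) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  atoms <- if (inherits(structure, "allohot_structure")) {
    structure$atoms
  } else if (is.list(structure) && !is.null(structure$atoms)) {
    structure$atoms
  } else structure
  if (is.null(ligand_atoms)) {
    ligand_atoms <- if (inherits(structure, "allohot_structure")) {
      structure$ligand_sites
    } else if (is.list(structure)) structure$het
  }
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0L) {
    stopf(paste("no ligand atoms found; supply `ligand_atoms` from a",
                "sidecar site file (see read_sites_tsv())"))
  }
  d <- euclidean_cross(as.matrix(atoms[, c("x", "y", "z")]),
                       ligand_atoms[, 1:3, drop = FALSE])
  touching <- sort(unique(atoms$resno[apply(d <= cutoff, 1, any)]))
  excluded <- intersect(hotspots$hotspot_positions, touching)
  hotspots$ligand_excluded_positions <- excluded
  hotspots$post_exclusion_hotspots <-
    setdiff(hotspots$hotspot_positions, excluded)
  hotspots
}

#' Compare mutation properties between dead and tolerated substitutions
#'
#' Splits present variants into a dead group (dead in at least two
#' replicates, i.e. confidence score >= 1) and a not-dead group, drops
#' variants at ligand-contacting positions when `exclude_positions` is
#' given, and reports (i) the percentage of each final mutated amino
#' acid within each group and (ii) group means +/- standard error and
#' two-sample t-test p-values for six physicochemical properties of
#' the mutated amino acid (hydrophilicity, hydrophobicity, polarity,
#' mass, solvent accessibility, polarizability).
#'
#' @param calls Output of [call_dead()].
#' @param property_table Per-amino-acid property table; defaults to the
#'   bundled [aa_mutation_properties()].
#' @param exclude_positions Positions to drop before binning.
#' @return A list of class `mutation_property_report`: `composition`
#'   (percentages per amino acid and group), `properties` (per-property
#'   group means, SEMs and p-values), and group sizes. When either
#'   group is empty the report is flagged `computable = FALSE`.
#' @export
mutation_property_comparison <- function(calls,
                                         property_table =
                                           aa_mutation_properties(),
                                         exclude_positions = integer()) {
  calls <- data.table::as.data.table(calls)
  dat <- calls[present == TRUE & !(position %in% exclude_positions)]
  dat[, group := data.table::fifelse(dead_replicates >= 2L,
                                     "dead", "not_dead")]
  sizes <- table(factor(dat$group, levels = c("dead", "not_dead")))
  if (any(sizes == 0L)) {
    return(structure(list(computable = FALSE, n_dead = sizes[["dead"]],
                          n_not_dead = sizes[["not_dead"]]),
                     class = "mutation_property_report"))
  }

  comp <- dat[, .(n = .N), by = .(group, mut_aa)]
  comp[, percent := 100 * n / sum(n), by = group]
  composition <- data.table::dcast(comp, mut_aa ~ group,
                                   value.var = "percent", fill = 0)

  props <- setdiff(names(property_table), "aa")
  vals <- property_table[match(dat$mut_aa, property_table$aa), props,
                         drop = FALSE]
  properties <- do.call(rbind, lapply(props, function(p) {
    x <- vals[[p]][dat$group == "dead"]
    y <- vals[[p]][dat$group == "not_dead"]
    pval <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else stats::t.test(x, y)$p.value
    data.frame(property = p,
               mean_dead = mean(x), sem_dead = stats::sd(x) / sqrt(length(x)),
               mean_not_dead = mean(y),
               sem_not_dead = stats::sd(y) / sqrt(length(y)),
               p_value = pval, stringsAsFactors = FALSE)
  }))
  structure(list(computable = TRUE, composition = composition,
                 properties = properties,
                 n_dead = sizes[["dead"]], n_not_dead = sizes[["not_dead"]]),
            class = "mutation_property_report")
}

#' Run the full count-to-hotspot scoring chain
#'
#' Convenience wrapper: normalization, presence calling, dead calling,
#' weighted positional scores and the Q3 hotspot designation in one
#' call.
#'
#' @inheritParams normalize_counts
#' @inheritParams call_presence
#' @inheritParams call_hotspots
#' @return A list with `calls`, `scores` and `hotspots`.
#' @export
score_pipeline <- function(table, read_threshold = 5,
                           total_target = 200000, library_sizes = NULL,
                           include_no_data = FALSE) {
  norm <- normalize_counts(table, total_target = total_target,
                           library_sizes = library_sizes)
  calls <- call_dead(norm, read_threshold = read_threshold)
  scores <- position_scores(calls)
  hotspots <- call_hotspots(scores, include_no_data = include_no_data)
  list(calls = calls, scores = scores, hotspots = hotspots)
}
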