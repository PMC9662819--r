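#' Describe a synthetic sort-seq scanning scenario
#'
#' A `dms_scenario` fixes everything the count generator needs: the
#' library design (positions 2..`n_positions`, 19 substitutions each,
#' split into two contiguous sub-library pools), the planted truth
#' (which positions are allosteric hotspots and how likely a
#' substitution there is to lock the repressor in its non-inducible
#' state), sequencing depth, variant dropout, and the seed.
#'
#' @param n_positions Last mutagenized position (mutagenesis starts at
#'   position 2, as in saturation libraries built on an intact start
#'   codon).
#' @param planted_hotspots Integer positions in `2..n_positions` whose
#'   substitutions are dead with probability `p_dead_hotspot`.
#' @param p_dead_hotspot,p_dead_other Per-substitution probability of an
#'   allosterically dead phenotype at hotspot / background positions.
#' @param mean_depth Expected presorted reads per variant.
#' @param dropout_rate Probability a designed variant is absent from the
#'   library.
#' @param n_replicates Number of sorted/sequenced replicates.
#' @param n_sublibraries Number of pooled sub-library blocks (2 mirrors
#'   the N-terminal / C-terminal pooling of the real libraries).
#' @param dispersion Negative-binomial size parameter of read counts.
#' @param gate_leakage Probability an individual read of a functional
#'   (inducible) variant still falls inside the low-fluorescence sort
#'   gate under induction; models imperfect sorting.
#' @param seed Integer seed.
#' @return A validated list of class `dms_scenario`.
#' @export
dms_scenario <- function(n_positions = 100L,
                         planted_hotspots = integer(),
                         p_dead_hotspot = 0.9,
                         p_dead_other = 0.03,
                         mean_depth = 100,
                         dropout_rate = 0.05,
                         n_replicates = 3L,
                         n_sublibraries = 2L,
                         dispersion = 10,
                         gate_leakage = 0.01,
                         seed = 1L) {
  n_positions <- assert_count(n_positions, "n_positions", min = 2L)
  n_replicates <- assert_count(n_replicates, "n_replicates")
  n_sublibraries <- assert_count(n_sublibraries, "n_sublibraries")
  assert_prob(p_dead_hotspot, "p_dead_hotspot")
  assert_prob(p_dead_other, "p_dead_other")
  assert_prob(dropout_rate, "dropout_rate")
  assert_prob(gate_leakage, "gate_leakage")
  planted_hotspots <- as.integer(planted_hotspots)
  if (length(planted_hotspots) &&
      (min(planted_hotspots) < 2L || max(planted_hotspots) > n_positions)) {
    stopf("planted_hotspots must lie in 2..n_positions")
  }
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  structure(list(n_positions = n_positions,
                 planted_hotspots = sort(unique(planted_hotspots)),
                 p_dead_hotspot = p_dead_hotspot,
                 p_dead_other = p_dead_other,
                 mean_depth = mean_depth,
                 dropout_rate = dropout_rate,
                 n_replicates = n_replicates,
                 n_sublibraries = n_sublibraries,
                 dispersion = dispersion,
                 gate_leakage = gate_leakage,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "dms_scenario")
}

#' Simulate a sort-seq variant count table
#'
#' Draws a per-variant read-count table for the three sequenced
#' populations (presorted, sorted-uninduced, sorted-induced) across
#' replicates, mirroring the statistical structure of a pooled
#' saturation-mutagenesis sort-seq screen. Counts are negative binomial
#' around `mean_depth`. Every present variant represses without inducer
#' and therefore appears in the uninduced low-fluorescence gate; a dead
#' (non-inducible) variant additionally appears in the induced gate
#' with the same count distribution, while a functional variant's
#' induced-gate count is a Bernoulli thinning (rate `gate_leakage`) of
#' its uninduced-scale count.
#'
#' @param scenario A [dms_scenario()].
#' @return A `data.table` with columns `position`, `wt_aa`, `mut_aa`,
#'   `sublibrary`, `replicate`, `condition`
#'   (`presorted`/`sorted_uninduced`/`sorted_induced`) and `reads`.
#'   Attributes `truth` (per-variant present/dead flags) and `scenario`
#'   carry the planted ground truth for evaluation.
#' @export
generate_dms_counts <- function(scenario) {
  stopifnot(inherits(scenario, "dms_scenario"))
  s <- scenario
  with_seed(s$seed, {
    positions <- 2:s$n_positions
    wt <- sample(AA1, s$n_positions, replace = TRUE)
    ## contiguous sub-library blocks over the mutagenized range
    block <- cut(positions, breaks = s$n_sublibraries, labels = FALSE)

    vars <- data.table::CJ(position = positions, mut_rank = 1:19)
    vars[, wt_aa := wt[position]]
    vars[, mut_aa := vapply(seq_len(.N), function(k)
      setdiff(AA1, wt_aa[k])[mut_rank[k]], character(1))]
    vars[, mut_rank := NULL]
    vars[, sublibrary := block[match(position, positions)]]
    vars[, present := stats::runif(.N) > s$dropout_rate]
    p_dead <- ifelse(vars$position %in% s$planted_hotspots,
                     s$p_dead_hotspot, s$p_dead_other)
    vars[, dead := present & stats::runif(.N) < p_dead]

    reps <- seq_len(s$n_replicates)
    tab <- vars[, {
      nb <- function(n) stats::rnbinom(n, size = s$dispersion,
                                       mu = s$mean_depth)
      pre <- nb(length(reps))
      unind <- nb(length(reps))
      ind <- if (dead) nb(length(reps))
             else stats::rbinom(length(reps), unind, s$gate_leakage)
      if (!present) pre <- unind <- ind <- rep(0L, length(reps))
      data.table::data.table(
        replicate = rep(reps, 3L),
        condition = rep(c("presorted", "sorted_uninduced",
                          "sorted_induced"), each = length(reps)),
        reads = as.numeric(c(pre, unind, ind)))
    }, by = .(position, wt_aa, mut_aa, sublibrary, present, dead)]

    truth <- unique(tab[, .(position, wt_aa, mut_aa, present, dead)])
    out <- tab[, .(position, wt_aa, mut_aa, sublibrary, replicate,
                   condition, reads)]
    data.table::setattr(out, "truth", truth)
    data.table::setattr(out, "scenario", s)
    out[]
  })
}

#' Read and write variant count tables
#'
#' TSV round trip for the count-table schema (`position`, `wt_aa`,
#' `mut_aa`, `sublibrary`, `replicate`, `condition`, `reads`).
#'
#' @param table A count `data.table`.
#' @param file Path to a TSV file.
#' @export
write_counts_tsv <- function(table, file) {
  data.table::fwrite(table, file, sep = "\t")
  invisible(file)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(file) {
  tab <- data.table::fread(file, sep = "\t")
  need <- c("position", "wt_aa", "mut_aa", "sublibrary", "replicate",
            "condition", "reads")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stopf("count table is missing columns: %s",
          paste(missing, collapse = ", "))
  }
  tab
}
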