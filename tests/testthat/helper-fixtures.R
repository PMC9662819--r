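# Shared in-code fixtures for the test suite.

# Minimal count table for one variant with explicit per-replicate reads.
variant_counts <- function(position = 2L, wt = "A", mut = "W",
                           presorted = c(50, 50, 50),
                           uninduced = c(50, 50, 50),
                           induced = c(50, 50, 50), sublibrary = 1L) {
  reps <- seq_along(presorted)
  data.table::data.table(
    position = position, wt_aa = wt, mut_aa = mut,
    sublibrary = sublibrary,
    replicate = rep(reps, 3L),
    condition = rep(c("presorted", "sorted_uninduced", "sorted_induced"),
                    each = length(reps)),
    reads = as.numeric(c(presorted, uninduced, induced)))
}

# Stack several variant_counts() rows into one table.
counts_table <- function(...) data.table::rbindlist(list(...))

# A dead-call table in the call_dead() output schema.
calls_table <- function(position, mut_aa, dead_replicates,
                        present = TRUE, wt_aa = "A") {
  data.table::data.table(
    position = position, wt_aa = wt_aa, mut_aa = mut_aa,
    present = present, dead_replicates = as.integer(dead_replicates),
    confidence_score = ifelse(present & dead_replicates >= 1L,
                              pmin(dead_replicates, 3L) - 1L, NA_integer_))
}

# Atom table with one CA atom per residue at the given coordinates.
ca_atoms <- function(xyz, chain = "A", resid = "ALA", b = 20) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(chain = chain, resno = seq_len(nrow(xyz)), resid = resid,
             elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             b = b, stringsAsFactors = FALSE)
}

# Labelled two-class feature matrix with a planted informative block.
planted_matrix <- function(n = 300, informative = c(17, 18, 19, 20),
                           effect = 2, sigma = 1, prevalence = 0.5,
                           seed = 1) {
  labels <- rep(0L, n)
  labels[seq_len(round(n * prevalence))] <- 1L
  effects <- numeric(27)
  effects[informative] <- effect
  generate_feature_matrix(n, labels, effects = effects, sigma = sigma,
                          seed = seed)
}

# Cheap network settings for tests that only exercise bookkeeping.
fast_spec <- function() nn_spec(epochs = 30L)
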