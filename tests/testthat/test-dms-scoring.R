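test_that("sub-library normalization is an identity at target and scale-free", {
  tab <- counts_table(
    variant_counts(2, presorted = c(10000, 10000, 10000),
                   uninduced = c(20000, 10000, 10000),
                   induced = c(10000, 10000, 10000)),
    variant_counts(3, mut = "F", presorted = c(0, 0, 0),
                   uninduced = c(0, 0, 0), induced = c(0, 0, 0)))
  # table already sums to 100000 in its (single) sub-library pool
  norm <- normalize_counts(tab, total_target = 200000 / 2)
  expect_equal(norm$reads, tab$reads)

  doubled <- data.table::copy(tab)[, reads := reads * 2]
  expect_equal(normalize_counts(doubled, total_target = 1e5)$reads,
               norm$reads)

  empty <- data.table::copy(tab)[, reads := 0]
  expect_error(normalize_counts(empty), "zero total")
})

test_that("cross-protein normalization applies the library-size ratio", {
  one <- variant_counts(2, presorted = c(100, 100, 100),
                        uninduced = c(100, 100, 100),
                        induced = c(100, 100, 100))
  tab <- data.table::rbindlist(list(
    data.table::copy(one)[, protein := "RolR"],
    data.table::copy(one)[, protein := "MphR"]))
  norm <- normalize_counts(tab, total_target = 200000,
                           library_sizes = c(RolR = 4332, MphR = 3667))
  tot <- norm[, sum(reads), by = protein]
  ratio <- tot$V1[tot$protein == "RolR"] / tot$V1[tot$protein == "MphR"]
  # reads of the larger RolR library scale up by ~1.18 relative to MphR
  expect_equal(ratio, 4332 / 3667, tolerance = 1e-12)
  expect_equal(ratio, 1.18, tolerance = 0.005)
  expect_equal(tot$V1[tot$protein == "MphR"], 200000)
})

test_that("presence requires the read threshold in every replicate", {
  ok <- variant_counts(2, presorted = c(6, 6, 6))
  miss <- variant_counts(3, mut = "F", presorted = c(6, 6, 4))
  pres <- call_presence(counts_table(ok, miss))
  expect_true(pres[position == 2]$present)
  expect_false(pres[position == 3]$present)
  # threshold is a parameter
  strict <- call_presence(variant_counts(2, presorted = c(7, 7, 7)),
                          read_threshold = 10)
  expect_false(strict$present)
})

test_that("dead calls follow the two-sorted-pools rule per replicate", {
  tab <- counts_table(
    variant_counts(2, mut = "W", uninduced = c(9, 9, 9),
                   induced = c(7, 7, 7)),              # dead in 3
    variant_counts(2, mut = "F", uninduced = c(200, 200, 200),
                   induced = c(4, 4, 4)),              # never dead
    variant_counts(2, mut = "P", uninduced = c(9, 9, 9),
                   induced = c(7, 2, 2)))              # dead in 1 only
  calls <- call_dead(tab)
  expect_equal(calls[mut_aa == "W"]$dead_replicates, 3L)
  expect_equal(calls[mut_aa == "W"]$confidence_score, 2L)
  expect_equal(calls[mut_aa == "F"]$dead_replicates, 0L)
  expect_true(is.na(calls[mut_aa == "F"]$confidence_score))
  # single-replicate deaths carry confidence 0 (weight 0 downstream)
  expect_equal(calls[mut_aa == "P"]$confidence_score, 0L)
})

test_that("weighted positional score follows the D2/D3 weighting", {
  # D1=2, D2=1, D3=3 among Total=10 -> (0 + 1 + 6)/10
  calls <- calls_table(position = rep(2L, 10),
                       mut_aa = AA_LETTERS <- c("C", "D", "E", "F", "G",
                                                "H", "I", "K", "L", "M"),
                       dead_replicates = c(1, 1, 2, 3, 3, 3, 0, 0, 0, 0))
  sc <- position_scores(calls)
  expect_equal(sc$D1, 2L); expect_equal(sc$D2, 1L); expect_equal(sc$D3, 3L)
  expect_equal(sc$weighted_score, 0.7)

  # all-tolerant position scores 0; fully dead position hits the max of 2
  zero <- position_scores(calls_table(2L, AA_LETTERS, rep(0, 10)))
  expect_equal(zero$weighted_score, 0)
  top <- position_scores(calls_table(rep(2L, 19), c(LETTERS[1:19]),
                                     rep(3, 19)))
  expect_equal(top$weighted_score, 2)

  # absent variants and empty positions are flagged, not scored
  mixed <- rbind(calls, calls_table(3L, "W", 0, present = FALSE))
  sc2 <- position_scores(mixed)
  expect_true(sc2[position == 3]$no_data)
  expect_true(is.na(sc2[position == 3]$weighted_score))
})

test_that("monotonicity: scores never decrease in D2/D3 and thresholds prune", {
  base <- calls_table(2L, LETTERS[1:10], c(0, 0, 0, 0, 0, 1, 1, 2, 2, 3))
  more <- calls_table(2L, LETTERS[1:10], c(0, 0, 0, 0, 0, 1, 2, 2, 3, 3))
  expect_gte(position_scores(more)$weighted_score,
             position_scores(base)$weighted_score)

  scen <- dms_scenario(n_positions = 40,
                       planted_hotspots = c(10, 20, 30), seed = 31)
  tab <- normalize_counts(generate_dms_counts(scen))
  d5 <- call_dead(tab, read_threshold = 5)
  d10 <- call_dead(tab, read_threshold = 10)
  merged <- merge(d5, d10, by = c("position", "wt_aa", "mut_aa"))
  expect_true(all(merged$dead_replicates.y <= merged$dead_replicates.x))
})

test_that("Q3 hotspot designation uses interpolated quartiles, strictly above", {
  sc <- data.table::data.table(
    position = 1:8, D1 = 0L, D2 = 0L, D3 = 0L, Total = 19L,
    weighted_score = c(0, 0, 0, 0, 0, 0, 1, 2), no_data = FALSE)
  hs <- call_hotspots(sc)
  expect_equal(hs$q3_threshold, 0.25)
  expect_setequal(hs$hotspot_positions, c(7L, 8L))

  flat <- data.table::copy(sc)[, weighted_score := 0]
  expect_warning(h0 <- call_hotspots(flat), "degenerate")
  expect_length(h0$hotspot_positions, 0L)

  spike <- data.table::copy(flat)[position == 5, weighted_score := 1.5]
  expect_equal(call_hotspots(spike)$hotspot_positions, 5L)

  # order-preserving relabeling of positions maps the hotspot set
  relab <- data.table::copy(sc)[, position := position * 10L]
  expect_equal(call_hotspots(relab)$hotspot_positions,
               hs$hotspot_positions * 10L)
})

test_that("ligand-contact exclusion removes residues within the cutoff", {
  # 10 single-atom residues on a line, 12 A apart
  atoms <- ca_atoms(cbind(seq(0, 108, by = 12), 0, 0))
  hs <- structure(list(q3_threshold = 0.1, hotspot_positions = 1:10,
                       ligand_excluded_positions = integer(),
                       post_exclusion_hotspots = 1:10,
                       scores = NULL), class = "hotspot_set")
  # ligand atom coincident with residue 1; others out of reach
  lig <- matrix(c(0, 0, 0), 1)
  out <- exclude_ligand_contacts(hs, atoms, ligand_atoms = lig)
  expect_equal(out$ligand_excluded_positions, 1L)

  # boundary: nearest ligand atom at 5.1 A -> retained
  lig2 <- matrix(c(-5.1, 0, 0), 1)
  out2 <- exclude_ligand_contacts(hs, atoms, ligand_atoms = lig2)
  expect_length(out2$ligand_excluded_positions, 0L)

  # 3 of 10 hotspots within the cutoff -> 7 left (brute-force constructed)
  lig3 <- matrix(c(0, 12, 24, 0, 0, 0, 0, 0, 0), ncol = 3)
  out3 <- exclude_ligand_contacts(hs, atoms, ligand_atoms = lig3)
  expect_setequal(out3$ligand_excluded_positions, 1:3)
  expect_length(out3$post_exclusion_hotspots, 7L)

  expect_error(exclude_ligand_contacts(hs, atoms,
                                       ligand_atoms = matrix(0, 0, 3)),
               "sidecar")
})

test_that("mutation property comparison reports composition and t-tests", {
  calls <- calls_table(position = rep(2:11),
                       mut_aa = c("F", "F", "P", "A", "G", "G", "S", "S",
                                  "T", "V"),
                       dead_replicates = c(3, 3, 2, 2, 0, 0, 0, 0, 0, 0))
  rep1 <- mutation_property_comparison(calls)
  expect_true(rep1$computable)
  comp <- as.data.frame(rep1$composition)
  expect_equal(comp$dead[comp$mut_aa == "F"], 50)
  expect_equal(comp$dead[comp$mut_aa == "P"], 25)
  expect_equal(comp$dead[comp$mut_aa == "A"], 25)
  expect_equal(sum(comp$dead), 100)
  expect_equal(sum(comp$not_dead), 100)
  expect_true(all(c("mass", "polarizability") %in%
                    rep1$properties$property))

  # identical composition in both groups -> zero differences, p = 1
  same <- calls_table(position = 2:5, mut_aa = c("W", "W", "W", "W"),
                      dead_replicates = c(3, 3, 0, 0))
  rep2 <- mutation_property_comparison(same)
  expect_true(all(abs(rep2$properties$mean_dead -
                        rep2$properties$mean_not_dead) < 1e-12))
  expect_true(all(rep2$properties$p_value == 1))

  # empty dead group -> flagged not computable
  none <- calls_table(position = 2:4, mut_aa = c("A", "C", "D"),
                      dead_replicates = c(0, 0, 0))
  expect_false(mutation_property_comparison(none)$computable)
})

test_that("scoring chain is deterministic end to end", {
  scen <- dms_scenario(n_positions = 30, planted_hotspots = c(7, 19),
                       seed = 77)
  tab <- generate_dms_counts(scen)
  a <- score_pipeline(tab)
  b <- score_pipeline(tab)
  expect_identical(a$hotspots$hotspot_positions,
                   b$hotspots$hotspot_positions)
  expect_identical(a$scores, b$scores)
})
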