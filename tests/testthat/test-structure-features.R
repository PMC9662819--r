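test_that("contact map equals a brute-force all-pairs filter", {
  # collinear Calphas at 0, 5, 10 A: only consecutive pairs touch at 8 A
  cm <- contact_map(ca_atoms(cbind(c(0, 5, 10), 0, 0)), cutoff = 8)
  expect_equal(cm$pairs[, c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  expect_equal(cm$pairs$distance, c(5, 5))

  # random toy dimer vs an independent all-pairs scan
  s <- generate_structure(40, seed = 14)
  cm2 <- contact_map(s, cutoff = 8)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  idx <- ca$resno + ifelse(ca$chain == "A", 0L, s$n_res)
  ord <- order(idx)
  d <- as.matrix(dist(ca[ord, c("x", "y", "z")]))
  brute <- which(upper.tri(d) & d <= 8, arr.ind = TRUE)
  expect_equal(nrow(cm2$pairs), nrow(brute))
  expect_setequal(paste(cm2$pairs$i, cm2$pairs$j),
                  paste(idx[ord][brute[, 1]], idx[ord][brute[, 2]]))

  # one-residue chain: empty map; missing Calpha is an error
  expect_equal(nrow(contact_map(ca_atoms(c(0, 0, 0)))$pairs), 0L)
  bad <- ca_atoms(cbind(c(0, 5), 0, 0))
  bad$elety[2] <- "CB"
  expect_error(contact_map(bad), "Calpha")
})

test_that("LRI extraction applies the separation rule on dimer indices", {
  pairs <- data.frame(i = c(5L, 5L, 7L), j = c(14L, 15L, 8L),
                      distance = c(4, 4, 4))
  map <- structure(list(pairs = pairs, n_residues = 20L,
                        monomer_length = 10L), class = "contact_map")
  lri <- extract_lri(map, min_sep = 10)
  expect_equal(lri$i, 5L)
  expect_equal(lri$j, 15L)   # separation 10 kept, 9 dropped, i+1 dropped

  s <- generate_structure(50, seed = 6)
  cm <- contact_map(s)
  lri2 <- extract_lri(cm)
  expect_true(all(abs(lri2$i - lri2$j) >= 10))
  expect_true(all(paste(lri2$i, lri2$j) %in%
                    paste(cm$pairs$i, cm$pairs$j)))
})

test_that("LRI clustering finds planted blobs and a sane elbow", {
  # two well-separated blobs of contact-map points
  set.seed(2)
  blob1 <- data.frame(i = round(rnorm(30, 20, 1)),
                      j = round(rnorm(30, 40, 1)))
  blob2 <- data.frame(i = round(rnorm(30, 120, 1)),
                      j = round(rnorm(30, 160, 1)))
  lri <- rbind(blob1, blob2)
  lri$distance <- 5
  cl <- cluster_lri(lri, k_range = 1:6, seed = 3)
  expect_equal(cl$chosen_k, 2L)
  split_ids <- split(cl$assignment, rep(1:2, each = 30))
  expect_length(unique(split_ids[[1]]), 1L)
  expect_length(unique(split_ids[[2]]), 1L)

  # k = 1 WCSS equals the total variance around the grand centroid
  xy <- as.matrix(lri[, c("i", "j")])
  tot <- sum(sweep(xy, 2, colMeans(xy))^2)
  expect_equal(cl$elbow$wcss[cl$elbow$k == 1], tot, tolerance = 1e-8)

  # WCSS non-increasing in k; determinism per seed
  expect_true(all(diff(cl$elbow$wcss) <= 1e-8))
  cl2 <- cluster_lri(lri, k_range = 1:6, seed = 3)
  expect_identical(cl$assignment, cl2$assignment)

  expect_error(cluster_lri(lri[1:4, ], k_range = 1:6), "LRI pairs")
})

test_that("cluster ranking counts unique monomer hotspots with tie rule", {
  clusters <- list(
    assignment = c(1L, 1L, 1L, 1L, 1L, 2L, 3L),
    pairs = data.frame(
      i = c(1L, 3L, 5L, 7L, 9L, 31L, 15L),
      j = c(2L, 4L, 6L, 8L, 10L, 12L, 36L)))
  # cluster 1: residues 1..10 with 5 hotspots -> 50%
  # cluster 2: dimer 31 -> monomer 11, plus 12: one of two is a hotspot
  # cluster 3: residues 15, 16 (36 - 21): no hotspots -> 0, ranked last
  ranked <- rank_clusters(clusters, hotspots = c(2, 4, 6, 8, 10, 11),
                          monomer_length = 21L)
  expect_equal(ranked$unique_hotspot_fraction[ranked$cluster == 1], 50)
  expect_equal(ranked$unique_hotspot_fraction[ranked$cluster == 2], 50)
  expect_equal(ranked$unique_hotspot_fraction[ranked$cluster == 3], 0)
  expect_equal(ranked$rank[ranked$cluster == 3], 3L)
  # equal fractions tie-broken by smaller cluster id
  expect_equal(ranked$rank[ranked$cluster == 1], 1L)
  expect_equal(ranked$rank[ranked$cluster == 2], 2L)
})

test_that("physicochemical lookup matches the bundled table", {
  tab <- aa_physicochemical()
  seq20 <- tab$aa
  ph <- physicochemical_features(seq20)
  expect_equal(ph$molecular_weight, tab$molecular_weight)
  expect_equal(ph$polarity, tab$polarity)
  # homopolymer -> constant columns
  hp <- physicochemical_features(rep("W", 6))
  expect_length(unique(hp$hydrophobicity), 1L)
  # Leu/Ile are isomers: 19 distinct molecular weights among the 20
  expect_length(unique(ph$molecular_weight), 19L)
  expect_error(physicochemical_features(c("A", "X")), "position")
})

test_that("atomic density counts other-residue atoms at 5 A", {
  two <- ca_atoms(cbind(c(0, 4), 0, 0))
  lf <- local_features(two)
  expect_equal(lf$atomic_density, c(1, 1))
  far <- ca_atoms(cbind(c(0, 6), 0, 0))
  expect_equal(local_features(far)$atomic_density, c(0, 0))
  # isolated residue: zero density, B-factor passthrough
  one <- ca_atoms(c(0, 0, 0), b = 33)
  lf1 <- local_features(one)
  expect_equal(lf1$atomic_density, 0)
  expect_equal(lf1$b_factor, 33)
})

test_that("Shrake-Rupley SASA matches a Monte-Carlo surface oracle", {
  # free glycine-like fragment: N, CA, C, O
  gly <- data.frame(chain = "A", resno = 1L, resid = "GLY",
                    elety = c("N", "CA", "C", "O"),
                    x = c(-1.46, 0, 1.51, 2.2), y = c(0, 0, 0, 1.0),
                    z = 0, b = 10, stringsAsFactors = FALSE)
  pkg <- sum(sasa_shrake_rupley(gly))

  # independent Monte-Carlo estimate with random sphere points
  set.seed(99)
  radii <- c(N = 1.55, C = 1.70, O = 1.52)
  elem <- substr(gly$elety, 1, 1)
  r <- radii[elem] + 1.4
  xyz <- as.matrix(gly[, c("x", "y", "z")])
  mc <- 0
  for (a in 1:4) {
    u <- matrix(rnorm(3 * 20000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[a], 2, xyz[a, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (b in setdiff(1:4, a)) {
      free <- free & (colSums((t(pts) - xyz[b, ])^2) >= r[b]^2)
    }
    mc <- mc + 4 * pi * unname(r[a])^2 * mean(free)
  }
  expect_equal(pkg, mc, tolerance = 0.05)
})

test_that("GNM correlations match closed forms and a dense oracle", {
  # two connected nodes: normalized cross-correlation is exactly -1
  two <- ca_atoms(cbind(c(0, 5), 0, 0))
  g2 <- gnm_correlations(two, cutoff = 7.3)
  expect_equal(g2$correlations[1, 2], -1, tolerance = 1e-10)

  s <- generate_structure(10, seed = 8)   # 20-residue dimer
  g <- gnm_correlations(s, cutoff = 7.3)
  C <- g$correlations
  expect_true(isSymmetric(C, tol = 1e-10))
  expect_equal(unname(diag(C)), rep(1, nrow(C)))
  expect_true(all(C >= -1 - 1e-9 & C <= 1 + 1e-9))

  # dense eigendecomposition oracle on the same Kirchhoff matrix
  ca <- g$calpha
  d <- as.matrix(dist(ca[, c("x", "y", "z")]))
  k <- -(d <= 7.3) * 1
  diag(k) <- 0; diag(k) <- -rowSums(k)
  e <- eigen(k, symmetric = TRUE)
  keep <- e$values > 1e-8
  cov <- e$vectors[, keep] %*% diag(1 / e$values[keep]) %*%
    t(e$vectors[, keep])
  oracle <- cov / sqrt(outer(diag(cov), diag(cov)))
  expect_equal(unname(C), unname(oracle), tolerance = 1e-8)

  # disconnected spring network is refused with advice
  apart <- ca_atoms(cbind(c(0, 50), 0, 0))
  expect_error(gnm_correlations(apart), "cutoff")
})

test_that("closeness centrality matches hand values and Floyd-Warshall", {
  # path graph of 5 residues: ends 4/10, middle 4/6
  path5 <- ca_atoms(cbind(seq(0, 16, by = 4), 0, 0))
  cf <- centrality_features(path5, peaks = c(1, 2, 3, 4))
  expect_equal(cf$closeness_centrality,
               c(4 / 10, 4 / 7, 4 / 6, 4 / 7, 4 / 10))
  # a peak residue is at distance 0 from itself
  expect_equal(cf$dist_peak1[1], 0)
  expect_equal(cf$dist_peak3[3], 0)

  # complete graph: all closeness equal
  tri <- ca_atoms(cbind(c(0, 3, 1.5), c(0, 0, 2.6), 0))
  cf2 <- centrality_features(tri, peaks = c(1, 2, 3, 1))
  expect_length(unique(round(cf2$closeness_centrality, 12)), 1L)

  # random structure vs Floyd-Warshall closeness oracle
  s <- generate_structure(20, seed = 4)
  cf3 <- centrality_features(s, peaks = c(1, 5, 9, 30))
  atoms <- s$atoms
  idx <- atoms$resno + ifelse(atoms$chain == "A", 0L, s$n_res)
  n <- max(idx)
  adj <- matrix(FALSE, n, n)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dd <- as.matrix(dist(xyz)) <= 5
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b && any(dd[idx == a, idx == b])) adj[a, b] <- TRUE
  }
  sp <- ifelse(adj, 1, Inf); diag(sp) <- 0
  for (k in 1:n) for (a in 1:n) for (b in 1:n) {
    if (sp[a, k] + sp[k, b] < sp[a, b]) sp[a, b] <- sp[a, k] + sp[k, b]
  }
  expect_equal(cf3$closeness_centrality, (n - 1) / rowSums(sp))
})

test_that("geometry features: site distances and sequence propagation", {
  atoms <- ca_atoms(cbind(seq(0, 36, by = 4), 0, 0))
  dna <- matrix(c(0, 0, 0), 1, dimnames = list(NULL, c("x", "y", "z")))
  lig <- matrix(c(36, 10, 0), 1, dimnames = list(NULL, c("x", "y", "z")))
  gf <- geometry_features(atoms, dna_sites = dna, ligand_sites = lig)
  expect_equal(gf$dist_dna[1], 0)          # coincident site
  expect_equal(gf$dist_dna[10], 36)
  expect_equal(gf$dist_ligand[10], 10)
  # neighbours on a 4-A line are only i+/-1 -> propagation 1
  expect_equal(gf$sequence_propagation[5], 1)

  # contact with a residue 100 positions away at 4.9 A
  far <- ca_atoms(rbind(cbind(0:100 * 100, 0, 0),
                        c(4.9, 0, 0)))  # residue 102 next to residue 1
  gf2 <- geometry_features(far, dna_sites = dna, ligand_sites = lig)
  expect_equal(gf2$sequence_propagation[1], 101)

  expect_error(geometry_features(atoms, dna_sites = matrix(0, 0, 3),
                                 ligand_sites = lig), "non-empty")
})

test_that("feature matrix assembly resolves the registry and round-trips", {
  s <- generate_structure(20, seed = 13)
  fm <- assemble_feature_matrix(s, hotspots = c(3, 7, 11),
                                imported = zero_imported_columns(20))
  expect_equal(nrow(fm), 20L)
  expect_true(all(feature_registry()$name %in% names(fm)))
  expect_equal(sum(fm$label), 3)
  prov <- attr(fm, "provenance")
  expect_equal(sum(prov == "imported"), 5L)

  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$sasa, fm$sasa, tolerance = 1e-12)
  expect_equal(back$closeness_centrality, fm$closeness_centrality,
               tolerance = 1e-12)

  # imported column with a missing residue names the gap
  broken <- zero_imported_columns(20)[-5, ]
  expect_error(assemble_feature_matrix(s, hotspots = 3, imported = broken),
               "missing residue")
  # unresolved imported features are listed
  expect_error(assemble_feature_matrix(s, hotspots = 3), "unresolved")
})
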