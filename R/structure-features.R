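## Structural feature stack: contact maps, long-range interactions and
## their clusters, and the computed columns of the 27-feature site
## matrix. All structure-based quantities are computed on the
## renumbered dimer: chain A keeps monomer numbering, chain B residue i
## becomes i + monomer_length, so inter-chain contacts are visible to
## the sequence-separation rules.

## Calpha table on renumbered dimer indices.
dimer_calpha <- function(atoms) {
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  chains <- sort(unique(atoms$chain))
  if (length(chains) > 2L) stopf("expected at most two chains")
  mono_len <- max(ca$resno[ca$chain == chains[1]])
  idx <- ca$resno + ifelse(ca$chain == chains[1], 0L, mono_len)
  if (anyDuplicated(idx)) stopf("duplicate Calpha records in structure")
  full <- atoms
  full_idx <- full$resno + ifelse(full$chain == chains[1], 0L, mono_len)
  no_ca <- setdiff(unique(full_idx), idx)
  if (length(no_ca)) {
    stopf("residue(s) without a Calpha atom: %s",
          paste(no_ca, collapse = ", "))
  }
  ord <- order(idx)
  data.frame(index = idx[ord], chain = ca$chain[ord],
             resno = ca$resno[ord],
             x = ca$x[ord], y = ca$y[ord], z = ca$z[ord],
             monomer_length = mono_len)
}

get_atoms <- function(structure) {
  if (inherits(structure, "allohot_structure")) structure$atoms
  else if (is.list(structure) && !is.null(structure$atoms)) structure$atoms
  else structure
}

#' Calpha contact map of a renumbered dimer
#'
#' All residue pairs whose Calpha atoms lie within `cutoff` of each
#' other, indexed on the renumbered dimer (chain B residues shifted by
#' the monomer length) so that intermolecular contacts appear as
#' ordinary pairs.
#'
#' @param structure An `allohot_structure`, a [read_structure()] result
#'   or an atom table.
#' @param cutoff Contact distance in Angstrom (inclusive).
#' @return Object of class `contact_map`: list with `pairs`
#'   (data.frame `i`, `j`, `distance`, `i < j`), `n_residues`,
#'   `monomer_length`, and `chain` (chain of origin per index).
#' @export
contact_map <- function(structure, cutoff = 8) {
  ca <- dimer_calpha(get_atoms(structure))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- euclidean_cross(xyz, xyz)
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(i = ca$index[sel[, 1]], j = ca$index[sel[, 2]],
                      distance = d[sel])
  ## upper.tri is on row order == index order, so i < j already
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_residues = nrow(ca),
                 monomer_length = ca$monomer_length[1],
                 chain = stats::setNames(ca$chain, ca$index),
                 calpha = ca),
            class = "contact_map")
}

#' Long-range interactions
#'
#' Subset of the contact map with sequence separation of at least
#' `min_sep` on the renumbered dimer indices: residue pairs in spatial
#' contact but far apart in sequence (or on different chains).
#'
#' @param map A [contact_map()].
#' @param min_sep Minimum `|i - j|` (inclusive).
#' @return The pair data.frame restricted to long-range interactions.
#' @export
extract_lri <- function(map, min_sep = 10) {
  stopifnot(inherits(map, "contact_map"))
  p <- map$pairs
  lri <- p[abs(p$i - p$j) >= min_sep, , drop = FALSE]
  rownames(lri) <- NULL
  lri
}

#' Cluster long-range interactions on the contact map
#'
#' k-means on the contact-map coordinates `(i, j)` of the long-range
#' pairs, with the within-cluster sum of squares recorded over
#' `k_range` and the elbow chosen automatically as the point of maximum
#' second difference of the curve (override with `k`).
#'
#' @param lri Pair data.frame from [extract_lri()].
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed (k-means restarts are stochastic).
#' @param nstart Restarts per k.
#' @param k Manual override of the chosen number of clusters.
#' @return List with `assignment` (cluster id per pair), `chosen_k`,
#'   `elbow` (data.frame `k`, `wcss`), `pairs`.
#' @export
cluster_lri <- function(lri, k_range = 2:12, seed = 1L, nstart = 10L,
                        k = NULL) {
  if (nrow(lri) < max(k_range)) {
    stopf("need at least max(k_range) = %d LRI pairs, have %d",
          max(k_range), nrow(lri))
  }
  xy <- as.matrix(lri[, c("i", "j")])
  with_seed(seed, {
    fits <- lapply(k_range, function(kk)
      stats::kmeans(xy, centers = kk, nstart = nstart, iter.max = 100))
    wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    chosen_k <- if (!is.null(k)) {
      assert_count(k, "k")
    } else if (length(k_range) >= 3L) {
      d2 <- diff(diff(wcss))
      k_range[which.max(d2) + 1L]
    } else k_range[which.min(wcss)]
    fit <- if (chosen_k %in% k_range) {
      fits[[match(chosen_k, k_range)]]
    } else stats::kmeans(xy, centers = chosen_k, nstart = nstart,
                         iter.max = 100)
    list(assignment = fit$cluster, chosen_k = chosen_k,
         elbow = data.frame(k = k_range, wcss = wcss),
         centers = fit$centers, pairs = lri)
  })
}

#' Rank LRI clusters by their unique-hotspot fraction
#'
#' Collapses each cluster's member residues to monomer positions
#' (dimer index `i > monomer_length` maps back to `i -
#' monomer_length`), computes the percentage of those unique positions
#' that are hotspots, and ranks clusters from highest to lowest
#' fraction; ties are broken by smaller cluster id.
#'
#' @param clusters Output of [cluster_lri()].
#' @param hotspots A `hotspot_set` or an integer vector of hotspot
#'   positions (monomer numbering).
#' @param monomer_length Number of residues per monomer.
#' @return data.frame with one row per cluster: `cluster`, `n_pairs`,
#'   `n_residues`, `n_hotspots`, `unique_hotspot_fraction` (percent),
#'   `rank`.
#' @export
rank_clusters <- function(clusters, hotspots, monomer_length) {
  hot <- if (inherits(hotspots, "hotspot_set")) {
    hotspots$hotspot_positions
  } else as.integer(hotspots)
  ids <- sort(unique(clusters$assignment))
  rows <- lapply(ids, function(cl) {
    sel <- clusters$assignment == cl
    res <- unique(c(clusters$pairs$i[sel], clusters$pairs$j[sel]))
    mono <- unique(ifelse(res > monomer_length, res - monomer_length, res))
    n_hot <- length(intersect(mono, hot))
    frac <- if (length(mono)) 100 * n_hot / length(mono) else 0
    data.frame(cluster = cl, n_pairs = sum(sel),
               n_residues = length(mono), n_hotspots = n_hot,
               unique_hotspot_fraction = frac)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$unique_hotspot_fraction, out$cluster)
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}

#' Physicochemical feature columns (registry 1-8)
#'
#' Per-residue lookup of the wild-type amino acid's eight bundled
#' physicochemical values.
#'
#' @param sequence Character vector of single-letter amino acids.
#' @param table Lookup table, defaults to [aa_physicochemical()].
#' @return data.frame `residue` plus the eight feature columns.
#' @export
physicochemical_features <- function(sequence,
                                     table = aa_physicochemical()) {
  sequence <- as.character(sequence)
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  bad <- which(!(sequence %in% table$aa))
  if (length(bad)) {
    stopf("non-canonical amino acid at position(s): %s",
          paste(bad, collapse = ", "))
  }
  vals <- table[match(sequence, table$aa),
                setdiff(names(table), "aa"), drop = FALSE]
  rownames(vals) <- NULL
  cbind(data.frame(residue = seq_along(sequence)), vals)
}

## ---- local structural features -------------------------------------

vdw_radius <- function(elety) {
  elem <- substr(gsub("^[0-9]", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  out <- unname(r[elem])
  out[is.na(out)] <- 1.70
  out
}

## Evenly distributed unit sphere points (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA with the classic point-sampling algorithm: each
#' heavy atom is inflated by the probe radius (1.4 A), a deterministic
#' Fibonacci lattice of test points is placed on the inflated sphere,
#' and the exposed fraction is the share of points not buried inside
#' any neighbouring inflated sphere.
#'
#' @param atoms Atom table (chain, resno, elety, x, y, z).
#' @param probe Probe radius, A.
#' @param n_points Test points per atom.
#' @return Numeric vector of per-atom SASA values (A^2).
#' @export
sasa_shrake_rupley <- function(atoms, probe = 1.4, n_points = 192L) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$elety) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d <- euclidean_cross(xyz, xyz)
  out <- numeric(n)
  for (a in seq_len(n)) {
    nb <- which(d[a, ] < rad[a] + rad & seq_len(n) != a)
    if (!length(nb)) {
      out[a] <- 4 * pi * rad[a]^2
      next
    }
    p <- pts * rad[a]
    p <- sweep(p, 2, xyz[a, ], "+")
    buried <- rep(FALSE, n_points)
    for (b in nb) {
      if (all(buried)) break
      db <- colSums((t(p) - xyz[b, ])^2)
      buried <- buried | db < rad[b]^2
    }
    out[a] <- 4 * pi * rad[a]^2 * sum(!buried) / n_points
  }
  out
}

#' Local structural feature columns (atomic density, SASA, B-factor)
#'
#' Local atomic density of residue R is the number of heavy atoms from
#' other residues within 5 A of any atom of R; SASA is the per-residue
#' sum of [sasa_shrake_rupley()] atom areas; the B-factor is the mean
#' over the residue's atoms as read from the PDB.
#'
#' @param structure Structure or atom table.
#' @param density_cutoff Neighbour distance for the density count, A.
#' @return data.frame per renumbered dimer residue: `index`,
#'   `atomic_density`, `sasa`, `b_factor`.
#' @export
local_features <- function(structure, density_cutoff = 5) {
  atoms <- get_atoms(structure)
  ca <- dimer_calpha(atoms)
  chains <- sort(unique(atoms$chain))
  idx <- atoms$resno + ifelse(atoms$chain == chains[1], 0L,
                              ca$monomer_length[1])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- euclidean_cross(xyz, xyz)
  close <- d <= density_cutoff
  ## density = number of other-residue atoms within cutoff of any atom of R
  dens <- vapply(ca$index, function(r) {
    mine <- idx == r
    other_close <- close[mine, !mine, drop = FALSE]
    sum(apply(other_close, 2, any))
  }, numeric(1))

  atom_sasa <- sasa_shrake_rupley(atoms)
  sasa <- vapply(ca$index, function(r) sum(atom_sasa[idx == r]),
                 numeric(1))
  bfac <- vapply(ca$index, function(r) mean(atoms$b[idx == r]),
                 numeric(1))
  data.frame(index = ca$index, atomic_density = dens, sasa = sasa,
             b_factor = bfac)
}

## ---- global structural features ------------------------------------

#' Gaussian network model cross-correlations
#'
#' Builds the Kirchhoff (connectivity) matrix on Calpha atoms with the
#' given cutoff, takes its Moore-Penrose pseudo-inverse, and normalizes
#' to unit diagonal, yielding motional cross-correlations in
#' `[-1, 1]`.
#'
#' @param structure Structure or atom table.
#' @param cutoff Spring cutoff, A (7.3 by default).
#' @return List with `correlations` (normalized matrix, dimnames =
#'   renumbered indices) and `calpha`.
#' @export
gnm_correlations <- function(structure, cutoff = 7.3) {
  ca <- dimer_calpha(get_atoms(structure))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- euclidean_cross(xyz, xyz)
  adj <- (d <= cutoff) & !diag(TRUE, n)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::components(g)$no > 1L) {
    stopf(paste("GNM contact network is disconnected at cutoff %.1f A;",
                "increase the cutoff"), cutoff)
  }
  kirch <- -1 * adj
  diag(kirch) <- rowSums(adj)
  cov <- MASS::ginv(kirch)
  cov <- (cov + t(cov)) / 2  # symmetrize numerical noise

  dg <- diag(cov)
  corr <- cov / sqrt(outer(dg, dg))
  dimnames(corr) <- list(ca$index, ca$index)
  list(correlations = corr, calpha = ca)
}

## Indices (renumbered) of the n_sites residues closest to the given
## site coordinates, by minimum Calpha-to-site distance.
closest_residues <- function(ca, sites, n_sites = 10L) {
  d <- euclidean_cross(as.matrix(ca[, c("x", "y", "z")]),
                       sites[, 1:3, drop = FALSE])
  mind <- apply(d, 1, min)
  ca$index[order(mind)][seq_len(min(n_sites, nrow(ca)))]
}

#' Motional-correlation feature columns (registry 17-19)
#'
#' Correlation-with-DNA (resp. ligand) of a residue is the maximum
#' absolute Gaussian-network-model cross-correlation between the
#' residue and any of the 10 residues closest to the DNA (resp.
#' ligand) sites, the residue itself excluded; maximum correlation is
#' the mean of the residue's five largest absolute correlations with
#' any other residue.
#'
#' @param structure Structure or atom table.
#' @param dna_sites,ligand_sites Coordinate matrices; default to the
#'   structure's own pseudo-sites when it is an `allohot_structure`.
#' @param cutoff GNM spring cutoff, A.
#' @param n_site_residues Number of site-proximal residues considered.
#' @param n_top Number of top correlations averaged for
#'   `max_correlation`.
#' @return data.frame per renumbered residue: `index`, `corr_dna`,
#'   `corr_ligand`, `max_correlation`.
#' @export
enm_features <- function(structure, dna_sites = NULL, ligand_sites = NULL,
                         cutoff = 7.3, n_site_residues = 10L, n_top = 5L) {
  if (inherits(structure, "allohot_structure")) {
    dna_sites <- dna_sites %||% structure$dna_sites
    ligand_sites <- ligand_sites %||% structure$ligand_sites
  }
  if (is.null(dna_sites) || is.null(ligand_sites)) {
    stopf("dna_sites and ligand_sites are required")
  }
  gnm <- gnm_correlations(structure, cutoff = cutoff)
  corr <- abs(gnm$correlations)
  diag(corr) <- NA
  ca <- gnm$calpha
  dna_res <- match(closest_residues(ca, dna_sites, n_site_residues),
                   ca$index)
  lig_res <- match(closest_residues(ca, ligand_sites, n_site_residues),
                   ca$index)
  site_max <- function(i, cols) {
    v <- corr[i, setdiff(cols, i)]
    if (!length(v)) 0 else max(v)
  }
  n <- nrow(ca)
  data.frame(
    index = ca$index,
    corr_dna = vapply(seq_len(n), site_max, numeric(1), cols = dna_res),
    corr_ligand = vapply(seq_len(n), site_max, numeric(1), cols = lig_res),
    max_correlation = vapply(seq_len(n), function(i) {
      v <- sort(corr[i, -i], decreasing = TRUE)
      mean(v[seq_len(min(n_top, length(v)))])
    }, numeric(1))
  )
}

## Prominence of each local maximum of a profile (signal-processing
## definition: height above the key saddle towards the nearest higher
## point, in profile order).
peak_prominence <- function(p) {
  n <- length(p)
  is_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) p[i - 1] else -Inf
    right <- if (i < n) p[i + 1] else -Inf
    p[i] >= left && p[i] >= right && (p[i] > left || p[i] > right)
  }, logical(1)))
  prom <- vapply(is_max, function(i) {
    higher_l <- which(p[seq_len(i - 1)] > p[i])
    lo_l <- if (length(higher_l)) min(p[(max(higher_l) + 1):i]) else min(p[1:i])
    higher_r <- which(p[(i + 1):n] > p[i]) + i
    lo_r <- if (i < n) {
      if (length(higher_r)) min(p[i:(min(higher_r) - 1)]) else min(p[i:n])
    } else p[i]
    p[i] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(position = is_max, value = p[is_max], prominence = prom)
}

#' Centrality feature columns (registry 22-26)
#'
#' Builds the unweighted residue contact network (edge when any heavy
#' atom pair between two residues is within `cutoff`), measures
#' closeness centrality `(n - 1) / sum(shortest path lengths)`, locates
#' the four most prominent local maxima of the per-residue centrality
#' profile, and reports each residue's Calpha distance to the four peak
#' residues (peak 1 = most prominent).
#'
#' @param structure Structure or atom table.
#' @param cutoff Atom-contact threshold, A.
#' @param peaks Optional manual vector of four peak residue indices
#'   (renumbered), overriding automatic peak detection.
#' @return data.frame per renumbered residue: `index`,
#'   `closeness_centrality`, `dist_peak1` .. `dist_peak4`; the chosen
#'   peaks are attached as attribute `"peaks"`.
#' @export
centrality_features <- function(structure, cutoff = 5, peaks = NULL) {
  atoms <- get_atoms(structure)
  ca <- dimer_calpha(atoms)
  chains <- sort(unique(atoms$chain))
  idx <- atoms$resno + ifelse(atoms$chain == chains[1], 0L,
                              ca$monomer_length[1])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- euclidean_cross(xyz, xyz) <= cutoff
  n <- nrow(ca)
  adj <- matrix(FALSE, n, n)
  pos <- match(idx, ca$index)
  for (a in seq_len(n)) {
    mine <- pos == a
    hit <- unique(pos[apply(d[mine, , drop = FALSE], 2, any)])
    adj[a, hit] <- TRUE
  }
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  clo <- igraph::closeness(g, normalized = TRUE)
  clo[is.nan(clo)] <- 0

  if (is.null(peaks)) {
    pk <- peak_prominence(as.numeric(clo))
    if (nrow(pk) < 4L) {
      stopf(paste("found only %d local maxima in the centrality profile;",
                  "supply the four peak residues via `peaks`"), nrow(pk))
    }
    pk <- pk[order(-pk$prominence, pk$position), ]
    peaks <- ca$index[pk$position[1:4]]
  }
  if (length(peaks) != 4L) stopf("`peaks` must name four residues")
  caxyz <- as.matrix(ca[, c("x", "y", "z")])
  pd <- euclidean_cross(caxyz, caxyz[match(peaks, ca$index), , drop = FALSE])
  out <- data.frame(index = ca$index, closeness_centrality = as.numeric(clo),
                    dist_peak1 = pd[, 1], dist_peak2 = pd[, 2],
                    dist_peak3 = pd[, 3], dist_peak4 = pd[, 4])
  attr(out, "peaks") <- peaks
  out
}

#' Geometric feature columns (registry 20, 21, 27)
#'
#' Distance-to-DNA (resp. ligand) is the minimum distance between the
#' residue's Calpha and the DNA nucleotide (resp. ligand)
#' centers-of-mass. Sequence propagation of residue R is the largest
#' same-chain sequence separation `|i - j|` over residues j whose
#' Calpha lies within `prop_cutoff` of R's Calpha.
#'
#' @param structure Structure or atom table.
#' @param dna_sites,ligand_sites Coordinate matrices (centers of mass).
#' @param prop_cutoff Neighbour cutoff for sequence propagation, A.
#' @return data.frame per renumbered residue: `index`, `dist_dna`,
#'   `dist_ligand`, `sequence_propagation`.
#' @export
geometry_features <- function(structure, dna_sites = NULL,
                              ligand_sites = NULL, prop_cutoff = 5) {
  if (inherits(structure, "allohot_structure")) {
    dna_sites <- dna_sites %||% structure$dna_sites
    ligand_sites <- ligand_sites %||% structure$ligand_sites
  }
  if (is.null(dna_sites) || !nrow(dna_sites) ||
      is.null(ligand_sites) || !nrow(ligand_sites)) {
    stopf("dna_sites and ligand_sites are required and must be non-empty")
  }
  ca <- dimer_calpha(get_atoms(structure))
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  ddna <- apply(euclidean_cross(xyz, dna_sites[, 1:3, drop = FALSE]), 1, min)
  dlig <- apply(euclidean_cross(xyz, ligand_sites[, 1:3, drop = FALSE]),
                1, min)
  d <- euclidean_cross(xyz, xyz)
  prop <- vapply(seq_len(nrow(ca)), function(a) {
    same <- ca$chain == ca$chain[a]
    nb <- which(same & d[a, ] <= prop_cutoff & seq_len(nrow(ca)) != a)
    if (!length(nb)) 0 else max(abs(ca$resno[nb] - ca$resno[a]))
  }, numeric(1))
  data.frame(index = ca$index, dist_dna = ddna, dist_ligand = dlig,
             sequence_propagation = prop)
}

#' Assemble the 27-column site feature matrix
#'
#' Computes every computed registry column from the structure, merges
#' the five webserver-derived columns from `imported`, collapses the
#' renumbered dimer back to monomer positions by averaging the two
#' chain copies, and attaches binary hotspot labels.
#'
#' @param structure Structure or atom table (two-chain dimer).
#' @param sequence Monomer amino-acid sequence (single letters); for an
#'   `allohot_structure` the embedded sequence is used.
#' @param hotspots A `hotspot_set`, integer vector of hotspot
#'   positions, or `NULL` for an unlabelled matrix.
#' @param imported data.frame of imported feature columns — either wide
#'   (`residue` plus named columns) or long (`residue`,
#'   `feature_name`, `value`) as read by [read_imported_features()].
#'   Must cover every monomer residue for each imported registry name.
#' @param dna_sites,ligand_sites Site coordinate matrices.
#' @param gnm_cutoff,centrality_cutoff,density_cutoff,prop_cutoff
#'   Distance thresholds (A) forwarded to the feature functions.
#' @param peaks Optional manual centrality peak residues.
#' @return data.frame: `residue`, the 27 registry columns, and `label`
#'   when hotspots were given; per-column provenance in attribute
#'   `"provenance"`.
#' @export
assemble_feature_matrix <- function(structure, sequence = NULL,
                                    hotspots = NULL, imported = NULL,
                                    dna_sites = NULL, ligand_sites = NULL,
                                    gnm_cutoff = 7.3,
                                    centrality_cutoff = 5,
                                    density_cutoff = 5, prop_cutoff = 5,
                                    peaks = NULL) {
  if (inherits(structure, "allohot_structure")) {
    sequence <- sequence %||% structure$sequence
    dna_sites <- dna_sites %||% structure$dna_sites
    ligand_sites <- ligand_sites %||% structure$ligand_sites
  }
  if (is.null(sequence)) stopf("`sequence` is required")

  loc <- local_features(structure, density_cutoff = density_cutoff)
  enm <- enm_features(structure, dna_sites, ligand_sites,
                      cutoff = gnm_cutoff)
  cen <- centrality_features(structure, cutoff = centrality_cutoff,
                             peaks = peaks)
  geo <- geometry_features(structure, dna_sites, ligand_sites,
                           prop_cutoff = prop_cutoff)
  dimer <- Reduce(function(a, b) merge(a, b, by = "index"),
                  list(loc, enm, cen, geo))
  mono_len <- length(sequence)
  dimer$residue <- ifelse(dimer$index > mono_len,
                          dimer$index - mono_len, dimer$index)
  num <- setdiff(names(dimer), c("index", "residue"))
  mono <- stats::aggregate(dimer[num], by = list(residue = dimer$residue),
                           FUN = mean)

  phys <- physicochemical_features(sequence)
  fm <- merge(phys, mono, by = "residue")

  reg <- feature_registry()
  imp_names <- reg$name[reg$provenance == "imported"]
  if (!is.null(imported)) {
    if (all(c("feature_name", "value") %in% names(imported))) {
      imported <- stats::reshape(
        imported[, c("residue", "feature_name", "value")],
        idvar = "residue", timevar = "feature_name", direction = "wide")
      names(imported) <- sub("^value\\.", "", names(imported))
    }
    have <- intersect(imp_names, names(imported))
    for (nm in have) {
      miss <- setdiff(fm$residue, imported$residue[!is.na(imported[[nm]])])
      if (length(miss)) {
        stopf("imported column '%s' is missing residue(s): %s", nm,
              paste(miss, collapse = ", "))
      }
    }
    fm <- merge(fm, imported[, c("residue", have), drop = FALSE],
                by = "residue", all.x = TRUE)
  }
  unresolved <- setdiff(reg$name, names(fm))
  if (length(unresolved)) {
    stopf("unresolved feature columns (supply via `imported`): %s",
          paste(unresolved, collapse = ", "))
  }
  fm <- fm[, c("residue", reg$name)]

  if (!is.null(hotspots)) {
    hot <- if (inherits(hotspots, "hotspot_set")) {
      hotspots$hotspot_positions
    } else as.integer(hotspots)
    fm$label <- as.integer(fm$residue %in% hot)
  }
  validate_feature_matrix(fm)
  prov <- stats::setNames(reg$provenance, reg$name)
  prov[intersect(imp_names, names(fm))] <- "imported"
  attr(fm, "provenance") <- prov
  fm
}

#' Zero-filled imported feature columns
#'
#' Convenience constructor of an all-zero imported-column table for the
#' five webserver-derived registry features, used in toy runs where no
#' external predictions are available. Synthetic stand-in values only.
#'
#' @param n_res Number of monomer residues.
#' @return Wide data.frame consumable by [assemble_feature_matrix()].
#' @export
zero_imported_columns <- function(n_res) {
  reg <- feature_registry()
  imp <- reg$name[reg$provenance == "imported"]
  out <- data.frame(residue = seq_len(n_res))
  for (nm in imp) out[[nm]] <- 0
  out
}

#' @rdname assemble_feature_matrix
#' @param file Long-format TSV (`residue`, `feature_name`, `value`).
#' @export
read_imported_features <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write feature matrices and contact maps as TSV
#'
#' @param fm Feature matrix from [assemble_feature_matrix()].
#' @param file Output path.
#' @export
write_feature_matrix <- function(fm, file) {
  utils::write.table(fm, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(file) {
  fm <- utils::read.delim(file, stringsAsFactors = FALSE)
  validate_feature_matrix(fm)
  fm
}
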