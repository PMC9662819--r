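#' Generate a toy two-chain helical structure
#'
#' Builds a deterministic pseudo-helical homodimer used to exercise the
#' structural feature stack offline. Each chain is an ideal alpha-helix
#' (2.3 A radius, 1.5 A rise, 100 degrees per residue) whose axis folds
#' back on itself as a hairpin, so that residues far apart in sequence
#' (separation of about `n_res/2`) come within contact distance — the
#' geometry guarantees both short-range and genuine long-range contacts
#' at the usual 8 A Calpha cutoff once `n_res` is a few dozen. Chain B
#' is a translated copy of chain A forming a dimer interface. Besides
#' the Calpha trace, each residue carries dummy backbone atoms (N, C,
#' O) and a CB pseudo-side-chain (except glycine) so heavy-atom
#' features (density, SASA, atom-contact networks) have something to
#' chew on. A single ligand pseudo-site sits in the hairpin cleft of
#' each chain and three DNA pseudo-sites sit below the helix N-termini.
#'
#' @param n_res Number of residues per chain (>= 1).
#' @param seed Integer seed; output is bit-reproducible per seed.
#' @param jitter Standard deviation (A) of Gaussian coordinate noise.
#' @param hairpin_gap Distance (A) between the two hairpin arm axes.
#' @param chain_offset Translation (A) of chain B along y.
#' @return An object of class `allohot_structure`: a list with
#'   `atoms` (data.frame: chain, resno, resid, elety, x, y, z, b),
#'   `sequence` (per-chain amino-acid vector), `n_res`,
#'   `ligand_sites` and `dna_sites` (matrices of coordinates, A).
#' @export
generate_structure <- function(n_res, seed = 1L, jitter = 0.1,
                               hairpin_gap = 9.0, chain_offset = 10.4) {
  n_res <- assert_count(n_res, "n_res")
  with_seed(seed, {
    sequence <- sample(AA1, n_res, replace = TRUE)
    ca <- hairpin_helix(n_res, hairpin_gap)
    ca <- ca + matrix(stats::rnorm(3 * n_res, sd = jitter), ncol = 3)
    bfac <- round(stats::runif(n_res, 10, 50), 2)

    atoms_a <- residue_atoms(ca, sequence, chain = "A", bfac = bfac)
    atoms_b <- atoms_a
    atoms_b$y <- atoms_b$y + chain_offset
    atoms_b$chain <- "B"
    atoms <- rbind(atoms_a, atoms_b)

    half <- ceiling(n_res / 2)
    cleft <- c(hairpin_gap / 2, 0, 0.75 * half * 1.5)
    ligand_sites <- rbind(cleft, cleft + c(0, chain_offset, 0))
    dna_sites <- rbind(c(0, chain_offset / 2, -4),
                       c(2, chain_offset / 2, -6),
                       c(hairpin_gap, chain_offset / 2, -4))
    dimnames(ligand_sites) <- list(NULL, c("x", "y", "z"))
    dimnames(dna_sites) <- list(NULL, c("x", "y", "z"))

    structure(list(atoms = atoms, sequence = sequence, n_res = n_res,
                   ligand_sites = ligand_sites, dna_sites = dna_sites),
              class = "allohot_structure")
  })
}

## Calpha trace of a hairpin-folded ideal helix.
hairpin_helix <- function(n_res, hairpin_gap) {
  radius <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  half <- ceiling(n_res / 2)
  i <- seq_len(n_res)
  theta <- turn * i
  up <- i <= half
  x <- ifelse(up, radius * cos(theta), hairpin_gap + radius * cos(theta))
  y <- radius * sin(theta)
  z <- ifelse(up, rise * i, rise * (2 * half - i + 1))
  cbind(x = x, y = y, z = z)
}

## Dummy backbone + CB atoms around each Calpha, oriented by the local
## chain tangent and a radial direction.
residue_atoms <- function(ca, sequence, chain, bfac) {
  n <- nrow(ca)
  nxt <- ca[pmin(n, seq_len(n) + 1L), , drop = FALSE]
  prv <- ca[pmax(1L, seq_len(n) - 1L), , drop = FALSE]
  tang <- nxt - prv
  nrm <- sqrt(rowSums(tang^2)); nrm[nrm == 0] <- 1
  tang <- tang / nrm
  if (n == 1L) tang <- matrix(c(0, 0, 1), 1L)
  radial <- cbind(ca[, 1] %% 7 - 3.5, ca[, 2], 0)   # rough outward direction
  nrm <- sqrt(rowSums(radial^2)); nrm[nrm == 0] <- 1
  radial <- radial / nrm
  binder <- cbind(
    tang[, 2] * radial[, 3] - tang[, 3] * radial[, 2],
    tang[, 3] * radial[, 1] - tang[, 1] * radial[, 3],
    tang[, 1] * radial[, 2] - tang[, 2] * radial[, 1]
  )

  one <- function(elety, off) {
    data.frame(chain = chain, resno = seq_len(n),
               resid = unname(AA3[sequence]), elety = elety,
               x = ca[, 1] + off[, 1], y = ca[, 2] + off[, 2],
               z = ca[, 3] + off[, 3], b = bfac,
               stringsAsFactors = FALSE)
  }
  at <- rbind(one("N", -1.2 * tang),
              one("CA", 0 * tang),
              one("C", 1.2 * tang),
              one("O", 1.2 * tang + 1.2 * binder),
              one("CB", 1.5 * radial))
  at <- at[!(at$elety == "CB" & sequence[at$resno] == "G"), ]
  at <- at[order(at$resno, match(at$elety, c("N", "CA", "C", "O", "CB"))), ]
  rownames(at) <- NULL
  at
}

#' Write and read toy/real structures
#'
#' `write_structure_pdb()` serializes an `allohot_structure` to a
#' standard PDB file (chains A/B) via bio3d; ligand and DNA pseudo-site
#' coordinates go to a sidecar TSV written by `write_sites_tsv()`.
#' `read_structure()` reads any two-chain PDB (toy or crystallographic)
#' into the same atom table the feature code consumes; HETATM records
#' are returned separately as candidate ligand coordinates.
#'
#' @param struct An `allohot_structure`.
#' @param file Output path.
#' @return `write_structure_pdb()` returns `file` invisibly;
#'   `read_structure()` returns a list with `atoms`, `het`, `chains`.
#' @export
write_structure_pdb <- function(struct, file) {
  at <- struct$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = round(xyz, 3),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, eleno = seq_len(nrow(at)),
                   b = at$b, o = rep(1, nrow(at)))
  invisible(file)
}

#' @rdname write_structure_pdb
#' @param sites Matrix of coordinates (columns x, y, z).
#' @param what Label written in the `site` column (e.g. "ligand").
#' @export
write_sites_tsv <- function(sites, file, what = "ligand") {
  df <- data.frame(site = what, x = sites[, 1], y = sites[, 2],
                   z = sites[, 3])
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_structure_pdb
#' @export
read_sites_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  split(as.matrix(df[, c("x", "y", "z")]), df$site) |>
    lapply(function(v) matrix(v, ncol = 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
}

#' @rdname write_structure_pdb
#' @export
read_structure <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  prot <- at[at$type == "ATOM", ]
  het <- at[at$type == "HETATM" & at$resid != "HOH", ]
  atoms <- data.frame(chain = prot$chain, resno = prot$resno,
                      resid = prot$resid, elety = prot$elety,
                      x = prot$x, y = prot$y, z = prot$z, b = prot$b,
                      stringsAsFactors = FALSE)
  list(atoms = atoms,
       het = as.matrix(het[, c("x", "y", "z")]),
       chains = sort(unique(atoms$chain)))
}
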