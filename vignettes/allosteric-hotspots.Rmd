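---
title: "Scoring, featurizing and predicting allosteric hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, featurizing and predicting allosteric hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allohot)
```

# The problem

Allosteric transcription factors (aTFs) of the TetR family repress a
promoter until an inducer ligand switches them off the DNA. A mutation
that locks the protein in its non-inducible state — a *dead* variant —
still represses but can no longer be induced. Residues where many
substitutions are dead are *allosteric hotspots*: positions critical
for transmitting the signal between the ligand-binding and DNA-binding
domains. `allohot` implements the complete computational chain from
pooled sort-seq read counts to hotspot calls, and from hotspot labels
plus a dimer structure to machine-learned rules for what distinguishes
hotspots, including prediction across homologous proteins.

# From counts to hotspots

The experimental design sequences three populations (presorted,
sorted-uninduced, sorted-induced) in triplicate for each of two pooled
sub-libraries. The scoring chain is:

1. **Normalization** (`normalize_counts()`): each sub-library pool is
   rescaled to a fixed total (100,000 reads per pool, 200,000 per
   protein) across its conditions and replicates, then — when several
   proteins are compared — reads are multiplied by the ratio of each
   protein's theoretical mutant-library size to the smallest one, so
   that a larger library (e.g. 4332 possible mutants vs. 3667) is not
   penalized for spreading the same sequencing budget more thinly.
   Normalized counts stay real-valued; thresholds are applied to the
   normalized scale.
2. **Presence** (`call_presence()`): a variant is in the dataset only
   with at least 5 normalized presorted reads in *every* replicate.
3. **Dead calling** (`call_dead()`): within a replicate, a present
   variant is dead when it has at least 5 reads in *both* sorted
   populations — it sits in the low-fluorescence gate with and without
   inducer. Dead-in-1/2/3-replicate variants carry confidence scores
   0/1/2.
4. **Positional score** (`position_scores()`): at position $x$ with
   $D1$, $D2$, $D3$ variants dead in exactly one, two, three
   replicates out of $\mathrm{Total}$ present variants,
   $$\mathrm{score}(x) = \frac{0\cdot D1 + 1\cdot D2 + 2\cdot D3}
   {\mathrm{Total}} \in [0, 2].$$
   Single-replicate calls are deliberately given zero weight.
5. **Hotspot designation** (`call_hotspots()`): Q3 — the 75th
   percentile of the positional scores — is computed over all scored
   positions and every position scoring *strictly above* Q3 is a
   hotspot.
6. **Ligand-contact exclusion** (`exclude_ligand_contacts()`):
   positions with any heavy atom within 5 Å of a ligand atom are set
   aside, since substitutions there typically kill induction through
   ligand affinity, not allostery.

Numerical choices worth making explicit: the quartile uses linear
interpolation between order statistics (`stats::quantile` type 7,
configurable); ties *at* Q3 are excluded by the strict inequality;
positions with no present variants are excluded from the quartile
computation rather than scored 0 — absence of data is not evidence of
tolerance — with a flag (`include_no_data`) to include them for
sensitivity analysis; Q3 is computed before ligand exclusion, matching
the narrative order of the analysis this package reproduces (exclusion
prunes the designated set, it does not re-draw the threshold); all
distance comparisons use inclusive cutoffs.

`mutation_property_comparison()` contrasts the dead group (confidence
≥ 1, i.e. dead in at least two replicates) with all other present
variants: amino-acid composition of the final mutated state as
percentages per group, and group means ± SEM with two-sample t-tests
for six properties of the substituting residue (hydrophilicity,
hydrophobicity, polarity, mass, maximum solvent accessibility,
polarizability; bundled, AAindex-derived).

# The 27-feature site description

`assemble_feature_matrix()` produces one row per residue with 27 named
columns in three classes (see `feature_registry()`):

* **Physicochemical (1–8)** — wild-type amino-acid lookups: molecular
  weight, charge count, hydrophobicity (Kyte–Doolittle), aromaticity,
  hydrogen-bond potential, polarity (Grantham), polarizability
  (Charton–Charton), flexibility (Bhaskaran–Ponnuswamy).
* **Local (9–16)** — atomic density (other-residue heavy atoms within
  5 Å), SASA (in-package Shrake–Rupley, probe 1.4 Å, deterministic
  Fibonacci point lattice), crystallographic B-factor, plus four
  columns that come from external predictors and are *imported*, not
  computed: backbone and sidechain conformational entropy loss,
  hydrogen-bond count, frustration index, and local structural
  entropy.
* **Global (17–27)** — Gaussian-network-model motional correlations
  (correlation with the 10 residues nearest the DNA and ligand sites,
  and the mean of the five largest absolute correlations with any
  residue), distances from the Cα to the DNA/ligand centers of mass,
  closeness centrality of the residue in the 5 Å atom-contact network,
  distances to the four most prominent peaks of the centrality
  profile, and sequence propagation (the largest same-chain sequence
  separation among 5 Å Cα neighbours).

All structural quantities are computed on the renumbered dimer (chain
B residue $i$ becomes $i + L$ for monomer length $L$) so intermolecular
contacts are first-class, then collapsed back to monomer positions by
averaging the two chain copies. The GNM uses a 7.3 Å Cα cutoff
(configurable); correlations are the unit-diagonal-normalized
pseudo-inverse of the Kirchhoff matrix, so values lie in $[-1, 1]$.
Centrality peaks are local maxima ranked by topographic prominence —
the automated stand-in for reading peaks off a profile figure — with a
manual `peaks` override. The numeric feature indices are a package
convention fixed by the registry ordering above; everything is
addressed by name internally.

Long-range interactions (LRIs) are contact-map pairs (Cα–Cα ≤ 8 Å)
with sequence separation ≥ 10 on the renumbered dimer. `cluster_lri()`
k-means-clusters LRIs on their contact-map coordinates (10 restarts,
seeded; within-cluster sum of squares recorded over a k range; the
automated elbow is the maximum second difference, overridable since
elbow reading is a judgment call), and `rank_clusters()` ranks clusters
by the percentage of unique hotspot residues among their members,
dimer copies collapsed to monomer positions, ties broken by cluster
id.

# Feature importance and the GA–NN model

Single-feature discrimination is measured two ways (`rank_features()`):
the F score $|\bar x_h - \bar x_n| / (\sigma_h + \sigma_n)$ with
sample standard deviations, and the Jensen–Shannon divergence between
the two class histograms (shared range, 20 bins, base-2 logs, so
JSD ∈ [0, 1]). Binning and base are not canonical — JSD values are
comparable in rank, which is how they are used.

The classifier (`nn_spec()`, `mlp_fit()`) is a single-hidden-layer
feedforward network: 10 rectified-linear units, 2-unit softmax output,
Glorot initialization, full-batch Adam at learning rate 0.0007,
categorical cross-entropy, 200 epochs by default, no early stopping.
Inputs are z-scored with training-fold statistics. A batch-normalized
variant serves the high-dimensional per-mutation featurizations. Zero
denominators in recall/precision/F1 yield 0. The fitness of a feature
combination (`cv_fitness()`) is the mean test F1 over five repeats of
stratified five-fold cross-validation (stratification stabilizes F1 at
~200 samples with ~25% positives; a non-stratified switch exists).

Combination search is exhaustive for 1–3 features
(`exhaustive_search()`) and evolutionary for 4–10 (`ga_select()`): a
pool of 300 distinct random combinations (sized to the real screens;
tests scale it down), one-feature point mutations that avoid every
previously evaluated combination, evaluation of the sons, and
truncation selection of the fittest 300 from parents plus sons.
Because parents survive, best and mean pool fitness are non-decreasing
— the property that makes convergence detection (a 5-generation
unchanged-best window) sound. The random-model baseline F1 equals the
hotspot prevalence (`random_baseline()`).

# Cross-protein prediction and transfer learning

`cpp_predict()` trains on the full data of one or several source
proteins and predicts every residue of a held-out homolog (five
independent runs averaged). `cpp_tl()` adds the transfer step: the
target's residues are split into ten stratified subsets; a
source-trained network is further trained on one subset and evaluated
on the other nine, averaging the ten F1s. Fine-tuning keeps the source
model's optimizer, learning rate and standardization and runs for 400
full-batch epochs by default: the fine-tune set is ten times smaller
than a training set, so its epochs are ten times cheaper, and this
budget gives the fine-tuned network a number of effective updates
comparable to a 200-epoch scratch fit — with fewer, fine-tuning
under-adapts and cannot beat a model trained from scratch on the same
10% of data, defeating the point of the warm start.

`mutation_phenotype_cv()` evaluates per-mutation phenotype prediction
(imported sequence embeddings, broadcast site features, or their
concatenation) with residue-level folds — all mutations of a residue
share a fold — and `hotspots_from_mutations()` turns per-mutation
predictions into hotspot calls: residues are ranked by the percentage
of their mutations predicted dead and the top N taken (N = the
experimental hotspot count), ties broken by higher mean predicted dead
probability, then lower residue index. `relative_performance()`
summarizes homology-model-based runs as the ratio of their F1 to the
crystal-structure F1, with least-squares trends against template
identity and RMSD.

# What the synthetic data emulates — and what it does not

The package is developed and tested entirely against its own
generators, chosen to mirror the screens' design:

* `generate_dms_counts()` draws negative-binomial reads (dispersion
  10) for 19 substitutions at positions 2..N, split into two
  contiguous sub-library pools, three conditions × three replicates.
  Every present variant appears in the uninduced sorted gate; a dead
  variant's induced-gate count follows the same distribution, while a
  functional variant's induced count is a Bernoulli thinning (rate
  0.01) of its uninduced-scale count. This asymmetry is a stand-in for
  the sorting gate, not a model of FACS physics; no generative model
  of the gate was published. Default recovery conditions plant 25
  hotspots in 100 positions — the ~25% prevalence the quartile rule
  presumes and the real screens show — with dead probabilities 0.9 at
  hotspots and 0.03 elsewhere at depth 100.
* `generate_structure()` builds a hairpin-folded ideal helix dimer
  whose geometry guarantees short- and long-range contacts, with dummy
  backbone/CB atoms, B-factors, and ligand/DNA pseudo-sites. It is a
  geometric testbed, not a protein: its SASA, density and centrality
  profiles are plausible but carry no biochemistry.
* `generate_homolog_family()` draws 27 standard-normal features per
  residue and labels them by member-specific logistic rules
  $\beta_k = \beta_{\mathrm{shared}} + \varepsilon_k$. Defaults: 200
  residues per member (aTF length), 25% prevalence (intercept
  calibrated numerically), shared weight on six global features, and
  per-coordinate divergence 0.35 — a perturbation of roughly 70% of
  the shared-rule norm, the regime in which direct cross-protein
  prediction is poor but pooled training and fine-tuning help, as
  observed for homologs of 14–19% sequence identity. At zero
  divergence transfer learning is redundant; at much larger divergence
  pooling hurts because rule heterogeneity dominates.

Passing tests on these generators demonstrates that the chain is
implemented correctly and behaves as the design predicts under known
truth; it does not certify performance on real screens, where feature
distributions are correlated, labels are noisy in structured ways, and
the imported feature columns carry their own biases.

# Problem sizes and runtime choices

Tests and the acceptance script run at desk scale: screens of 60–100
positions, toy dimers of 20–60 residues per chain, GA searches with a
pool of 50 over 10 generations on 300 residues, and 10-seed
replications for stochastic claims. These sizes keep the full suite in
the tens of minutes on a single core while leaving every algorithmic
property (monotonicity, archive uniqueness, recovery of planted
signal) at full strength; the real-data configuration (pool 300,
~200-residue proteins) is reached purely through parameters.

# Known limitations

* The weighted-score/Q3 chain designates roughly the top quarter of
  scored positions; when true hotspot prevalence is far below 25%,
  precision against planted truth is structurally capped — a property
  of the designation rule, not of the implementation.
* SASA is computed with a point lattice (192 points/atom); values are
  within a few percent of dense numerical integration, adequate for
  feature ranking but not for reporting absolute surface areas.
* The five imported feature columns are consumed, never recomputed;
  toy runs substitute zeros (`zero_imported_columns()`), which makes
  those columns uninformative rather than realistic.
* JSD depends on binning; only its ranking is meaningful.
* The GA archives every evaluated combination in memory; at the real
  screens' scale (thousands of evaluations) this is cheap, but the
  design assumes combination sizes ≤ 10 of 27 features.
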