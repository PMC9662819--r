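## Cross-protein prediction (CPP), transfer learning (CPP_TL),
## homology-model relative performance, and hotspot calling from
## mutation-level phenotype predictions.

combine_matrices <- function(train) {
  if (is.data.frame(train)) train <- list(train)
  nm <- feature_names()
  for (m in train) {
    if (!all(nm %in% names(m))) stopf("train matrices must share the registry")
    if (is.null(m$label)) stopf("train matrices must be labelled")
  }
  do.call(rbind, lapply(train, function(m) m[, c(nm, "label")]))
}

#' Cross-protein prediction
#'
#' Trains the classifier on the full data of one or more source
#' proteins (pooled when several are given — the "homologs" mode) using
#' the selected feature combination, predicts every residue of the
#' held-out target protein, and repeats the train/predict cycle
#' `n_runs` times with independent weight initializations. The
#' performance is the mean test F1 over runs.
#'
#' @param train A labelled feature matrix or list of matrices (source
#'   proteins).
#' @param test Labelled feature matrix of the target protein.
#' @param combo Feature indices or names.
#' @param spec An [nn_spec()].
#' @param n_runs Independent train/predict cycles.
#' @param seed Integer seed.
#' @return A list of class `cpp_result`: `cpp_f1` (mean), `run_f1`,
#'   `baseline_f1` (target prevalence), plus the inputs' metadata.
#' @export
cpp_predict <- function(train, test, combo, spec = nn_spec(),
                        n_runs = 5L, seed = 1L) {
  tr <- combine_matrices(train)
  cols <- resolve_combo(combo)
  if (!all(cols %in% names(test))) stopf("combo not resolvable in test matrix")
  xtr <- as.matrix(tr[, cols, drop = FALSE])
  xte <- as.matrix(test[, cols, drop = FALSE])
  yte <- test$label
  run_f1 <- with_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      model <- mlp_fit(xtr, tr$label, spec = spec,
                       seed = sample.int(2^31 - 1, 1))
      confusion_f1(mlp_predict(model, xte), yte)$f1
    }, numeric(1))
  })
  structure(list(cpp_f1 = mean(run_f1), run_f1 = run_f1,
                 cpp_tl_f1 = NA_real_,
                 baseline_f1 = random_baseline(yte),
                 combo = cols, n_runs = n_runs),
            class = "cpp_result")
}

#' Cross-protein prediction with transfer learning
#'
#' As [cpp_predict()], with one extra step: the target protein's
#' residues are partitioned into `n_partitions` equal subsets
#' (stratified by class by default); for each subset, a network trained
#' on the source protein(s) is further trained on that subset alone and
#' evaluated on the remaining subsets. The performance is the mean of
#' the `n_partitions` test F1 scores. Fine-tuning keeps the source
#' model's optimizer settings and standardization and runs for
#' `spec$fine_tune_epochs` epochs.
#'
#' @inheritParams cpp_predict
#' @param n_partitions Number of target-data subsets (each is the
#'   fine-tuning set once, i.e. a 10% fine-tune fraction by default).
#' @param stratified Stratify the partitions by class.
#' @return A `cpp_result` with `cpp_tl_f1` and `partition_f1` filled
#'   in.
#' @export
cpp_tl <- function(train, test, combo, spec = nn_spec(),
                   n_partitions = 10L, seed = 1L, stratified = TRUE) {
  tr <- combine_matrices(train)
  cols <- resolve_combo(combo)
  xtr <- as.matrix(tr[, cols, drop = FALSE])
  xte <- as.matrix(test[, cols, drop = FALSE])
  yte <- test$label
  if (min(table(yte)) < n_partitions) {
    stopf("test protein needs at least n_partitions samples per class")
  }
  part_f1 <- with_seed(seed, {
    for (attempt in 1:20) {
      fold <- if (stratified) stratified_folds(yte, n_partitions) else
        sample(rep_len(seq_len(n_partitions), length(yte)))
      if (all(vapply(seq_len(n_partitions), function(ff)
        length(unique(yte[fold == ff])) == 2L, logical(1)))) break
    }
    base <- mlp_fit(xtr, tr$label, spec = spec,
                    seed = sample.int(2^31 - 1, 1))
    vapply(seq_len(n_partitions), function(ff) {
      tune <- which(fold == ff)
      hold <- which(fold != ff)
      tuned <- mlp_fit(xte[tune, , drop = FALSE], yte[tune],
                       spec = spec, init = base,
                       epochs = spec$fine_tune_epochs)
      confusion_f1(mlp_predict(tuned, xte[hold, , drop = FALSE]),
                   yte[hold])$f1
    }, numeric(1))
  })
  structure(list(cpp_f1 = NA_real_, cpp_tl_f1 = mean(part_f1),
                 partition_f1 = part_f1,
                 baseline_f1 = random_baseline(yte),
                 combo = cols, n_partitions = n_partitions),
            class = "cpp_result")
}

#' Relative performance of homology-model features
#'
#' Ratio of the F1 achieved with features computed on a homology model
#' to the F1 achieved with features from the crystal structure (same
#' combination, same protocol), optionally regressed against template
#' sequence identity and RMSD across several templates.
#'
#' @param f1_model,f1_crystal F1 values (vectors of equal length, one
#'   entry per template/protein pair).
#' @param identity Template-target sequence identity (percent).
#' @param rmsd Template-target RMSD (Angstrom).
#' @return A list with `ratio` (and `ratio_percent`), and, when
#'   metadata is given, `fit_identity` / `fit_rmsd` (slope, intercept,
#'   r_squared).
#' @export
relative_performance <- function(f1_model, f1_crystal, identity = NULL,
                                 rmsd = NULL) {
  if (length(f1_model) != length(f1_crystal)) {
    stopf("f1_model and f1_crystal differ in length")
  }
  ratio <- ifelse(f1_crystal == 0, NA_real_, f1_model / f1_crystal)
  if (any(f1_crystal == 0)) {
    warnf("crystal F1 of 0: relative performance undefined for that entry")
  }
  out <- list(ratio = ratio, ratio_percent = 100 * ratio)
  lsq <- function(xx) {
    ok <- !is.na(ratio) & !is.na(xx)
    fit <- stats::lm(ratio[ok] ~ xx[ok])
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared)
  }
  if (!is.null(identity)) out$fit_identity <- lsq(identity)
  if (!is.null(rmsd)) out$fit_rmsd <- lsq(rmsd)
  out
}

#' Cross-validated mutation-phenotype prediction
#'
#' 5 x 5-fold cross-validation of the classifier on per-mutation
#' feature vectors (imported sequence embeddings, broadcast site
#' features, or their concatenation) against dead/not-dead labels.
#' Uses the batch-normalized network variant by default, as
#' appropriate for high-dimensional inputs.
#'
#' @param x Numeric matrix, mutants x features.
#' @param labels Binary dead (1) / not-dead (0) labels.
#' @param spec An [nn_spec()]; defaults to the batch-norm variant.
#' @param residue Optional residue index per mutant; when supplied,
#'   folds are drawn at residue level so that all mutations of one
#'   residue share a fold.
#' @inheritParams cv_fitness
#' @return Mean F1 with per-fold values in attribute `"fold_f1"`; when
#'   `residue` is given, the per-residue predicted-dead fractions of
#'   each repeat are in attribute `"profiles"`.
#' @export
mutation_phenotype_cv <- function(x, labels, spec = nn_spec(batch_norm = TRUE),
                                  n_repeats = 5L, k = 5L, seed = 1L,
                                  residue = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stopf("x and labels disagree in length")
  if (!is.null(residue) && length(residue) != length(labels)) {
    stopf("residue must align with the mutant rows")
  }
  with_seed(seed, {
    f1s <- numeric(0)
    profiles <- list()
    for (r in seq_len(n_repeats)) {
      fold <- if (is.null(residue)) {
        stratified_folds(labels, k)
      } else {
        res_ids <- unique(residue)
        res_fold <- stats::setNames(
          sample(rep_len(seq_len(k), length(res_ids))), res_ids)
        unname(res_fold[as.character(residue)])
      }
      pred <- numeric(length(labels))
      for (ff in seq_len(k)) {
        te <- which(fold == ff)
        tr <- which(fold != ff)
        if (length(unique(labels[tr])) < 2L) {
          stopf("training fold degenerated to one class")
        }
        model <- mlp_fit(x[tr, , drop = FALSE], labels[tr], spec = spec,
                         seed = sample.int(2^31 - 1, 1))
        pr <- mlp_predict(model, x[te, , drop = FALSE])
        pred[te] <- pr
        f1s <- c(f1s, confusion_f1(pr, labels[te])$f1)
      }
      if (!is.null(residue)) {
        profiles[[r]] <- data.frame(
          residue = sort(unique(residue)),
          x = 100 * tapply(pred, residue, mean)[
            as.character(sort(unique(residue)))],
          prob = tapply(pred, residue, mean)[
            as.character(sort(unique(residue)))])
      }
    }
    out <- mean(f1s)
    attr(out, "fold_f1") <- f1s
    if (!is.null(residue)) attr(out, "profiles") <- profiles
    out
  })
}

#' Call hotspots from mutation-level predictions
#'
#' Given per-mutation dead predictions grouped by residue, computes for
#' every residue the percentage `x` of its mutations predicted dead and
#' designates the `N` residues with highest `x` as predicted hotspots
#' (`N` = the experimentally determined hotspot count). Ties at the
#' cutoff are broken by higher mean predicted dead probability, then by
#' lower residue index.
#'
#' @param predictions Binary per-mutation predictions.
#' @param residue Residue index per mutation.
#' @param N Number of hotspots to call.
#' @param prob Optional per-mutation dead probabilities for
#'   tie-breaking (defaults to the binary predictions).
#' @param truth Optional true hotspot positions; when given, the F1 of
#'   the called set is reported.
#' @return A list of class `mutation_prediction_profile`: `profile`
#'   (residue, `x` percent, mean probability), `predicted_hotspots`,
#'   and `f1`/`confusion` when `truth` was supplied.
#' @export
hotspots_from_mutations <- function(predictions, residue, N,
                                    prob = NULL, truth = NULL) {
  N <- assert_count(N, "N")
  if (length(predictions) != length(residue)) {
    stopf("predictions and residue disagree in length")
  }
  prob <- prob %||% predictions
  res <- sort(unique(residue))
  if (N > length(res)) stopf("N exceeds the number of residues")
  xfrac <- 100 * tapply(predictions, residue, mean)[as.character(res)]
  mprob <- tapply(prob, residue, mean)[as.character(res)]
  ord <- order(-xfrac, -mprob, res)
  called <- sort(res[ord[seq_len(N)]])
  out <- list(profile = data.frame(residue = res, x = unname(xfrac),
                                   mean_prob = unname(mprob)),
              predicted_hotspots = called, N = N)
  if (!is.null(truth)) {
    lab <- as.integer(res %in% truth)
    pred <- as.integer(res %in% called)
    cf <- confusion_f1(pred, lab)
    out$confusion <- cf
    out$f1 <- cf$f1
  }
  structure(out, class = "mutation_prediction_profile")
}
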