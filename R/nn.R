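#' Neural-network specification
#'
#' Hyperparameters of the shallow feedforward hotspot classifier: one
#' hidden layer of 10 rectified-linear units and a 2-unit softmax
#' output, Glorot (Xavier) initialization, Adam optimization of the
#' categorical cross-entropy at learning rate 0.0007. An optional batch
#' normalization layer in front of the hidden layer is used for the
#' high-dimensional per-mutation featurizations (1900/1927 inputs);
#' optional class weights rescale the loss per class.
#'
#' @param hidden_units Hidden layer width.
#' @param learning_rate Adam learning rate.
#' @param epochs Full-batch training epochs.
#' @param batch_norm Add a batch-normalization layer on the inputs.
#' @param class_weights Length-2 weights for classes (0, 1), or `NULL`.
#' @param fine_tune_epochs Epochs used when a trained network is
#'   further trained on a small target-protein subset.
#' @return A list of class `nn_spec`.
#' @export
nn_spec <- function(hidden_units = 10L, learning_rate = 0.0007,
                    epochs = 200L, batch_norm = FALSE,
                    class_weights = NULL, fine_tune_epochs = 400L) {
  stopifnot(learning_rate > 0)
  structure(list(hidden_units = assert_count(hidden_units, "hidden_units"),
                 learning_rate = learning_rate,
                 epochs = assert_count(epochs, "epochs"),
                 batch_norm = isTRUE(batch_norm),
                 class_weights = class_weights,
                 fine_tune_epochs = assert_count(fine_tune_epochs,
                                                 "fine_tune_epochs")),
            class = "nn_spec")
}

#' Fit the classifier on a feature matrix
#'
#' Standardizes the inputs with the training-set statistics, trains the
#' network of [nn_spec()] with full-batch Adam, and returns a model
#' usable by [mlp_predict()]. Pass `init` (a previous fit) to continue
#' training from its weights — the transfer-learning primitive; the
#' warm start keeps the original standardization so source and target
#' features live on the same scale.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary labels (0/1).
#' @param spec An [nn_spec()].
#' @param seed Integer seed for the weight initialization.
#' @param init Optional model to warm-start from.
#' @param epochs Override of `spec$epochs` (used for fine-tuning).
#' @return A list of class `mlp_model`.
#' @export
mlp_fit <- function(x, y, spec = nn_spec(), seed = 1L, init = NULL,
                    epochs = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  epochs <- epochs %||% spec$epochs
  cw <- spec$class_weights %||% c(1, 1)
  if (is.null(init)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    weights <- NULL
  } else {
    stopifnot(inherits(init, "mlp_model"))
    center <- init$center
    scale <- init$scale
    weights <- init$weights
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- .mlp_train_cpp(xs, y, spec$hidden_units, spec$learning_rate,
                        as.integer(epochs),
                        as.integer(assert_count(seed, "seed", min = 0L)),
                        spec$batch_norm, as.numeric(cw), weights)
  structure(list(weights = fit[setdiff(names(fit), "loss")],
                 loss = as.numeric(fit$loss), center = center,
                 scale = scale, spec = spec),
            class = "mlp_model")
}

#' @rdname mlp_fit
#' @param model An `mlp_model`.
#' @param type `"class"` for 0/1 predictions, `"prob"` for the
#'   positive-class probability.
#' @export
mlp_predict <- function(model, x, type = c("class", "prob")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "mlp_model"))
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  p <- .mlp_predict_cpp(model$weights, xs)[, 2]
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Confusion counts, recall, precision and F1
#'
#' Counts true/false positives and negatives of a binary prediction
#' and computes recall `TP / (TP + FN)`, precision `TP / (TP + FP)`
#' and their harmonic mean F1. Any ratio with a zero denominator is
#' reported as 0.
#'
#' @param predictions,labels Binary vectors of equal length.
#' @return A list of class `confusion_summary` with `TP`, `FP`, `TN`,
#'   `FN`, `recall`, `precision`, `f1`.
#' @export
confusion_f1 <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stopf("predictions and labels differ in length")
  }
  stopifnot(all(predictions %in% c(0, 1)), all(labels %in% c(0, 1)))
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, recall = recall,
                 precision = precision, f1 = f1),
            class = "confusion_summary")
}

## Stratified k-fold assignment: class counts per fold within +/- 1.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train on one split and evaluate on the held-out set
#'
#' @param matrix Labelled feature matrix (registry columns + `label`).
#' @param combo Integer feature indices or character feature names.
#' @param spec An [nn_spec()].
#' @param train_idx,test_idx Disjoint row index vectors.
#' @param seed Integer seed.
#' @return A `confusion_summary` for the test set.
#' @export
train_eval <- function(matrix, combo, spec = nn_spec(), train_idx,
                       test_idx, seed = 1L) {
  if (length(intersect(train_idx, test_idx))) {
    stopf("train and test indices overlap")
  }
  cols <- resolve_combo(combo)
  x <- as.matrix(matrix[, cols, drop = FALSE])
  y <- matrix$label
  if (length(unique(y[train_idx])) < 2L) {
    stopf("training fold contains a single class")
  }
  model <- mlp_fit(x[train_idx, , drop = FALSE], y[train_idx],
                   spec = spec, seed = seed)
  confusion_f1(mlp_predict(model, x[test_idx, , drop = FALSE]),
               y[test_idx])
}

resolve_combo <- function(combo) {
  nm <- feature_names()
  if (is.numeric(combo)) {
    if (any(combo < 1 | combo > length(nm))) {
      stopf("feature indices out of the 1..27 registry")
    }
    nm[sort(unique(as.integer(combo)))]
  } else {
    bad <- setdiff(combo, nm)
    if (length(bad)) stopf("unknown features: %s", paste(bad, collapse = ", "))
    nm[sort(match(unique(combo), nm))]
  }
}

#' Repeated cross-validated fitness of a feature combination
#'
#' The fitness of a feature combination is the mean test F1 over
#' `n_repeats` independent rounds of stratified `k`-fold
#' cross-validation (5 x 5-fold by default, 25 trained networks). If a
#' training fold degenerates to a single class the round is redrawn
#' with a new shuffle.
#'
#' @inheritParams train_eval
#' @param n_repeats Cross-validation repeats.
#' @param k Folds per repeat.
#' @param seed Integer seed controlling partitioning and weight
#'   initializations.
#' @param stratified Use class-stratified folds (default) or plain
#'   random partitions.
#' @return Mean F1, with the per-fold F1 values in attribute
#'   `"fold_f1"`.
#' @export
cv_fitness <- function(matrix, combo, spec = nn_spec(), n_repeats = 5L,
                       k = 5L, seed = 1L, stratified = TRUE) {
  y <- matrix$label
  if (is.null(y)) stopf("feature matrix carries no labels")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  n <- length(y)
  if (n < k) stopf("need at least k samples")
  cols <- resolve_combo(combo)
  x <- as.matrix(matrix[, cols, drop = FALSE])

  with_seed(seed, {
    f1s <- numeric(0)
    for (r in seq_len(n_repeats)) {
      for (attempt in 1:20) {
        fold <- if (stratified) stratified_folds(y, k) else
          sample(rep_len(seq_len(k), n))
        ok <- all(vapply(seq_len(k), function(ff)
          length(unique(y[fold != ff])) == 2L, logical(1)))
        if (ok) break
      }
      if (!ok) stopf("could not build folds with both classes in training")
      for (ff in seq_len(k)) {
        te <- which(fold == ff)
        tr <- which(fold != ff)
        model <- mlp_fit(x[tr, , drop = FALSE], y[tr], spec = spec,
                         seed = sample.int(2^31 - 1, 1))
        cf <- confusion_f1(mlp_predict(model, x[te, , drop = FALSE]),
                           y[te])
        f1s <- c(f1s, cf$f1)
      }
    }
    out <- mean(f1s)
    attr(out, "fold_f1") <- f1s
    out
  })
}
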