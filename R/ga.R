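## Feature-combination search: exhaustive for 1-3 features, genetic
## algorithm for larger subsets, plus the frequency analysis of
## features among the top-ranked combinations.

combo_key <- function(combo) paste(sort(combo), collapse = ",")

#' Random-model baseline F1
#'
#' The F1 score of a random classifier equals the hotspot prevalence —
#' the fraction of residues labelled hotspots.
#'
#' @param labels Binary label vector.
#' @return The prevalence as a single number.
#' @export
random_baseline <- function(labels) {
  if (!length(labels)) stopf("labels must be non-empty")
  stopifnot(all(labels %in% c(0, 1)))
  mean(labels == 1)
}

#' Exhaustive search over small feature combinations
#'
#' Evaluates every `choose(n_features, p)` combination of `p` features
#' (`p` at most 3; larger subsets go through [ga_select()]) by
#' cross-validated fitness and ranks them.
#'
#' @inheritParams cv_fitness
#' @param p Combination size, 1..3.
#' @param features Candidate feature indices (defaults to all 27).
#' @return data.frame ranked by descending fitness with columns
#'   `combo` (list of integer vectors), `key`, `fitness`.
#' @export
exhaustive_search <- function(matrix, p, spec = nn_spec(),
                              n_repeats = 5L, k = 5L, seed = 1L,
                              features = seq_len(27L)) {
  p <- assert_count(p, "p")
  if (p > 3L) stopf("p > 3: use ga_select() for larger combinations")
  combos <- utils::combn(features, p, simplify = FALSE)
  fitness <- vapply(seq_along(combos), function(ii) {
    as.numeric(cv_fitness(matrix, combos[[ii]], spec = spec,
                          n_repeats = n_repeats, k = k,
                          seed = child_seed(seed, ii)))
  }, numeric(1))
  out <- data.frame(key = vapply(combos, combo_key, character(1)),
                    fitness = fitness, stringsAsFactors = FALSE)
  out$combo <- combos
  out <- out[order(-out$fitness), c("combo", "key", "fitness")]
  rownames(out) <- NULL
  out
}

#' Genetic-algorithm search for the best p-feature combination
#'
#' Evolutionary programming over feature subsets of size `p`: a pool of
#' `pool_size` distinct random combinations is evaluated by
#' cross-validated fitness; each generation every parent is
#' point-mutated (one feature swapped) into a son not evaluated before,
#' the sons are evaluated, and the `pool_size` fittest of parents plus
#' sons form the next generation. Because parents survive selection,
#' the best (and mean) pool fitness is non-decreasing in generation.
#' The search stops at the generation budget or when the best fitness
#' has not changed over `convergence_window` generations. Every
#' evaluated combination is archived; no combination is evaluated
#' twice. A parent with no unevaluated neighbour passes unchanged.
#'
#' @inheritParams cv_fitness
#' @param p Combination size (requires `choose(n_features, p)` >
#'   `pool_size`).
#' @param pool_size Number of combinations per generation.
#' @param generations Maximum generations.
#' @param convergence_window Stop after this many generations without
#'   improvement of the best fitness.
#' @param features Candidate feature indices.
#' @return A list of class `ga_state`: `pool` (final ranked pool),
#'   `archive` (every evaluated combination), `best_trace`,
#'   `mean_trace`, `generations_run`, `chosen` (best combination).
#' @export
ga_select <- function(matrix, p, spec = nn_spec(), pool_size = 300L,
                      generations = 15L, n_repeats = 5L, k = 5L,
                      seed = 1L, convergence_window = 5L,
                      features = seq_len(27L)) {
  p <- assert_count(p, "p")
  pool_size <- assert_count(pool_size, "pool_size")
  if (choose(length(features), p) <= pool_size) {
    stopf("choose(%d, %d) must exceed pool_size", length(features), p)
  }

  archive <- new.env(parent = emptyenv())
  eval_counter <- 0L
  evaluate <- function(combo) {
    eval_counter <<- eval_counter + 1L
    fit <- as.numeric(cv_fitness(matrix, combo, spec = spec,
                                 n_repeats = n_repeats, k = k,
                                 seed = child_seed(seed, eval_counter)))
    assign(combo_key(combo), list(combo = sort(combo), fitness = fit),
           envir = archive)
    fit
  }

  with_seed(seed, {
    ## distinct random initial combinations
    pool <- list()
    while (length(pool) < pool_size) {
      cand <- sort(sample(features, p))
      if (is.null(pool[[combo_key(cand)]])) pool[[combo_key(cand)]] <- cand
    }
    pool <- unname(pool)
    fitness <- vapply(pool, evaluate, numeric(1))

    best_trace <- max(fitness)
    mean_trace <- mean(fitness)
    gens_run <- 0L
    for (g in seq_len(generations)) {
      sons <- list(); son_fit <- numeric(0)
      for (parent in pool) {
        son <- mutate_combo(parent, features, archive)
        if (is.null(son)) next # archive exhausted around this parent
        sons[[length(sons) + 1L]] <- son
        son_fit <- c(son_fit, evaluate(son))
      }
      all_combos <- c(pool, sons)
      all_fit <- c(fitness, son_fit)
      keep <- order(-all_fit)[seq_len(min(pool_size, length(all_fit)))]
      pool <- all_combos[keep]
      fitness <- all_fit[keep]
      gens_run <- g
      best_trace <- c(best_trace, max(fitness))
      mean_trace <- c(mean_trace, mean(fitness))
      w <- convergence_window
      if (length(best_trace) > w &&
          diff(range(utils::tail(best_trace, w + 1L))) == 0) break
    }

    arch <- eapply(archive, identity)
    archive_df <- data.frame(
      key = names(arch),
      fitness = vapply(arch, function(a) a$fitness, numeric(1)),
      stringsAsFactors = FALSE)
    archive_df$combo <- lapply(arch, function(a) a$combo)
    archive_df <- archive_df[order(-archive_df$fitness), ]
    rownames(archive_df) <- NULL

    ord <- order(-fitness)
    structure(list(
      pool = data.frame(key = vapply(pool[ord], combo_key, character(1)),
                        fitness = fitness[ord],
                        stringsAsFactors = FALSE) |>
        (\(d) { d$combo <- pool[ord]; d })(),
      archive = archive_df[, c("combo", "key", "fitness")],
      best_trace = best_trace, mean_trace = mean_trace,
      generations_run = gens_run, chosen = pool[[which.max(fitness)]],
      p = p, pool_size = pool_size, seed = seed),
      class = "ga_state")
  })
}

## One-feature point mutation avoiding already-evaluated combinations;
## NULL when every neighbour of `parent` is archived.
mutate_combo <- function(parent, features, archive) {
  outside <- setdiff(features, parent)
  slots <- sample(seq_along(parent))
  repl <- sample(outside)
  for (s in slots) {
    for (r in repl) {
      cand <- sort(c(parent[-s], r))
      if (!exists(combo_key(cand), envir = archive)) return(cand)
    }
  }
  NULL
}

#' Feature frequency among the top-ranked combinations
#'
#' Counts, for each registry feature and each combination size `p`, how
#' often the feature appears among the `top_k` best combinations of
#' that size, and records the mean fitness of those top combinations.
#'
#' @param results Named list (names = p values) of ranked result tables
#'   from [exhaustive_search()] or the `archive` of [ga_select()].
#' @param top_k Number of top combinations counted per p.
#' @param n_features Registry size.
#' @return A list with `frequency` (`n_features` x length(results)
#'   matrix), `mean_f1` (per-p mean fitness of the counted models) and
#'   `n_counted` (how many models were available per p).
#' @export
feature_frequency <- function(results, top_k = 10L, n_features = 27L) {
  freq <- matrix(0L, nrow = n_features, ncol = length(results),
                 dimnames = list(feature_names()[seq_len(n_features)],
                                 names(results)))
  mean_f1 <- numeric(length(results))
  n_counted <- integer(length(results))
  for (ii in seq_along(results)) {
    res <- results[[ii]]
    res <- res[order(-res$fitness), ]
    use <- utils::head(res, top_k)
    n_counted[ii] <- nrow(use)
    for (combo in use$combo) {
      freq[combo, ii] <- freq[combo, ii] + 1L
    }
    mean_f1[ii] <- mean(use$fitness)
  }
  names(mean_f1) <- names(results)
  names(n_counted) <- names(results)
  list(frequency = freq, mean_f1 = mean_f1, n_counted = n_counted)
}
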