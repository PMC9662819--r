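test_that("confusion summary matches hand values and edge conventions", {
  perf <- confusion_f1(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perf$recall, 1); expect_equal(perf$precision, 1)
  expect_equal(perf$f1, 1)

  # TP=3, FP=1, FN=1 -> recall = precision = f1 = 0.75
  cf <- confusion_f1(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 0))
  expect_equal(cf$TP, 3); expect_equal(cf$FP, 1); expect_equal(cf$FN, 1)
  expect_equal(cf$recall, 0.75)
  expect_equal(cf$precision, 0.75)
  expect_equal(cf$f1, 0.75)

  # all-negative prediction on positives: 0/0 -> 0 convention
  z <- confusion_f1(c(0, 0, 0), c(1, 0, 1))
  expect_equal(z$f1, 0)
  expect_error(confusion_f1(c(1, 0), c(1, 0, 1)), "length")
})

test_that("training separates separable data and is seed-deterministic", {
  fm <- planted_matrix(400, informative = c(17, 18), effect = 4,
                       sigma = 0.5, seed = 3)
  idx <- seq_len(400)
  tr <- idx[idx %% 2 == 1]; te <- idx[idx %% 2 == 0]
  cf <- train_eval(fm, c(17, 18), nn_spec(), tr, te, seed = 5)
  expect_gte(cf$f1, 0.95)

  cf2 <- train_eval(fm, c(17, 18), nn_spec(), tr, te, seed = 5)
  expect_identical(cf, cf2)
  expect_error(train_eval(fm, c(17, 18), nn_spec(), tr, c(te, tr[1])),
               "overlap")

  one_class <- fm; one_class$label[tr] <- 0L
  expect_error(train_eval(one_class, c(17, 18), nn_spec(), tr, te),
               "single class")
})

test_that("stratified folds partition every sample and balance classes", {
  y <- rep(c(0L, 1L), times = c(80, 20))
  set.seed(4)
  fold <- allohot:::stratified_folds(y, 5)
  expect_setequal(fold, 1:5)
  expect_true(all(table(fold) == 20))
  pos_per_fold <- tapply(y, fold, sum)
  expect_true(max(pos_per_fold) - min(pos_per_fold) <= 1)
})

test_that("cv fitness has set semantics and tracks label permutation", {
  fm <- planted_matrix(200, informative = c(19, 20), effect = 3, seed = 6)
  a <- cv_fitness(fm, c(19, 20), fast_spec(), n_repeats = 2, seed = 7)
  b <- cv_fitness(fm, c(20, 19), fast_spec(), n_repeats = 2, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_length(attr(a, "fold_f1"), 10L)

  # every sample lands in exactly one test fold per repeat: the fold F1s
  # jointly cover n samples per repeat (checked through the partition)
  set.seed(1)
  fold <- allohot:::stratified_folds(fm$label, 5)
  expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))),
               seq_len(200))

  single <- fm; single$label <- 1L
  expect_error(cv_fitness(single, 1:2), "both classes")
})

test_that("exhaustive search counts combinations and finds the signal", {
  fm <- planted_matrix(150, informative = 21, effect = 3, seed = 9)
  res1 <- exhaustive_search(fm, p = 1, spec = nn_spec(epochs = 120),
                            n_repeats = 1, seed = 2)
  expect_equal(nrow(res1), 27L)
  expect_equal(res1$combo[[1]], 21L)  # planted feature tops the ranking

  res2 <- exhaustive_search(fm, p = 2, spec = fast_spec(), n_repeats = 1,
                            seed = 2, features = 1:9)
  expect_equal(nrow(res2), choose(9, 2))
  expect_error(exhaustive_search(fm, p = 4), "ga_select")
})

test_that("GA search respects its invariants on a scaled-down run", {
  fm <- planted_matrix(120, informative = c(3, 9, 17), effect = 2,
                       seed = 10)
  ga <- ga_select(fm, p = 4, spec = fast_spec(), pool_size = 15,
                  generations = 4, n_repeats = 1, seed = 3,
                  features = 1:20)
  expect_true(all(diff(ga$best_trace) >= 0))
  expect_equal(nrow(ga$pool), 15L)
  expect_false(anyDuplicated(ga$archive$key) > 0)
  expect_true(all(lengths(ga$archive$combo) == 4L))
  expect_error(ga_select(fm, p = 2, pool_size = 400), "exceed")
})

test_that("point mutations change exactly one feature and avoid the archive", {
  arch <- new.env(parent = emptyenv())
  parent <- c(2L, 5L, 9L)
  set.seed(8)
  for (r in 1:20) {
    son <- allohot:::mutate_combo(parent, 1:12, arch)
    expect_length(son, 3L)
    expect_equal(length(setdiff(son, parent)), 1L)
    expect_equal(length(setdiff(parent, son)), 1L)
    assign(allohot:::combo_key(son), TRUE, envir = arch)
  }
  # all 27 one-step neighbours archived -> parent has nowhere to go
  for (drop in 1:3) for (add in setdiff(1:12, parent)) {
    assign(allohot:::combo_key(sort(c(parent[-drop], add))), TRUE,
           envir = arch)
  }
  expect_null(allohot:::mutate_combo(parent, 1:12, arch))
})

test_that("feature frequency conserves counts per combination size", {
  fake <- function(combos, fits) {
    data.frame(key = vapply(combos, allohot:::combo_key, character(1)),
               fitness = fits) |>
      (\(d) { d$combo <- combos; d })()
  }
  results <- list(
    "1" = fake(list(1L, 5L, 9L), c(0.9, 0.8, 0.7)),
    "2" = fake(list(c(1L, 5L), c(1L, 9L), c(5L, 9L)), c(0.95, 0.9, 0.85)))
  ff <- feature_frequency(results, top_k = 2)
  expect_equal(unname(colSums(ff$frequency)),
               c(1 * 2, 2 * 2))   # p x models counted
  expect_equal(unname(ff$frequency[1, "2"]), 2L)  # feature 1 in both top-2
  expect_equal(unname(ff$mean_f1["1"]), 0.85)
  expect_equal(unname(ff$n_counted), c(2L, 2L))
})

test_that("random baseline equals the hotspot prevalence", {
  expect_equal(random_baseline(c(rep(1, 20), rep(0, 80))), 0.2)
  expect_equal(random_baseline(rep(1, 5)), 1)
  expect_error(random_baseline(integer(0)), "non-empty")
})
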