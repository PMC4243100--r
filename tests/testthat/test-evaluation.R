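test_that("stratified folds balance classes and are seed-deterministic", {
  y <- rep(c("pos", "neg"), c(20, 40))
  folds <- stratified_folds(y, 10, seed = 3)
  expect_length(folds, 10L)
  # partition: disjoint, covering
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(y))
  # divisible counts: exactly 2 positives and 4 negatives per fold
  for (f in folds) {
    expect_identical(sum(y[f] == "pos"), 2L)
    expect_identical(sum(y[f] == "neg"), 4L)
  }
  expect_identical(stratified_folds(y, 10, seed = 3), folds)
  expect_false(identical(stratified_folds(y, 10, seed = 4), folds))

  # per-class counts differ by at most 1 with non-divisible sizes
  y2 <- rep(c("pos", "neg"), c(7, 11))
  folds2 <- stratified_folds(y2, 4, seed = 1)
  for (cl in c("pos", "neg")) {
    counts <- vapply(folds2, function(f) sum(y2[f] == cl), integer(1))
    expect_lte(max(counts) - min(counts), 1L)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 20)), 4, seed = 1),
               "class 'a'")
})

test_that("standardization is fit on train and applied to test", {
  train <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  test <- cbind(a = c(4, 8), b = c(5, 7))
  std <- standardize_fold(train, test)
  expect_equal(std$train[, "a"], c(-1, 0, 1))
  # constant training feature maps to zeros everywhere
  expect_equal(std$train[, "b"], c(0, 0, 0))
  expect_equal(std$test[, "b"], c(0, 0))
  # test value equal to the training mean maps to 0
  expect_equal(std$test[, "a"], c(0, 2))
  expect_error(standardize_fold(train[1, , drop = FALSE]), "2 instances")
})

test_that("balanced accuracy follows its contingency definition", {
  expect_equal(bacc(tp = 10, tn = 10, fp = 0, fn = 0), 1)
  expect_equal(bacc(tp = 0, tn = 10, fp = 0, fn = 10), 0.5)
  expect_equal(bacc(tp = 5, tn = 8, fp = 2, fn = 5), 0.65)
  expect_true(is.na(bacc(tp = 0, tn = 5, fp = 1, fn = 0)))
  # invariant under swapping the positive/negative convention
  set.seed(1)
  for (i in 1:10) {
    cts <- sample.int(10, 4)
    expect_equal(bacc(cts[1], cts[2], cts[3], cts[4]),
                 bacc(cts[2], cts[1], cts[4], cts[3]))
  }
})

test_that("the registries provide the documented six classifiers and five selectors", {
  cls <- classifier_registry()
  expect_setequal(names(cls),
                  c("svm_linear", "svm_poly", "knn", "logistic", "nbayes", "tree"))
  sel <- selector_registry()
  expect_setequal(names(sel), c("resi", "ranking", "mrmr", "mimr", "cmim"))

  # adapter contract on an easy split
  set.seed(7)
  ytr <- factor(rep(c("a", "b"), each = 10))
  xtr <- cbind(ifelse(ytr == "a", 2, -2) + rnorm(20, sd = 0.3), rnorm(20))
  xte <- cbind(c(2, -2), c(0, 0))
  for (nm in names(cls)) {
    pred <- cls[[nm]](xtr, ytr, xte)
    expect_identical(as.character(pred), c("a", "b"), info = nm)
  }
})

test_that("benchmark produces the expected grid of paired records", {
  ds <- separable_dataset()
  scores <- benchmark(ds, selectors = c("resi", "ranking"),
                      dimensions = c(1, 2), classifiers = "knn",
                      n_reps = 2, n_folds = 2, seed = 5)
  # 2 selectors x 2 dimensions x 1 classifier x 2 reps x 2 folds
  expect_identical(nrow(scores), 16L)
  expect_true(all(scores$bacc >= 0 & scores$bacc <= 1))
  counts <- table(scores$selector, scores$dimension)
  expect_true(all(counts == 4L))

  # perfect planted signal: the top feature separates the classes
  knn_scores <- scores[scores$selector == "resi" & scores$dimension == 1, ]
  expect_equal(mean(knn_scores$bacc), 1)

  # determinism for deterministic classifiers
  again <- benchmark(ds, selectors = c("resi", "ranking"),
                     dimensions = c(1, 2), classifiers = "knn",
                     n_reps = 2, n_folds = 2, seed = 5)
  expect_identical(scores$bacc, again$bacc)
})

test_that("selection sees only training folds (test-set poisoning changes nothing)", {
  ds <- separable_dataset(n = 16, m_noise = 6)
  run <- function(d) {
    attr(benchmark(d, selectors = c("resi", "ranking"), dimensions = 2,
                   classifiers = "knn", n_reps = 1, n_folds = 4, seed = 9),
         "selections")
  }
  base_sel <- run(ds)
  folds <- stratified_folds(ds$labels, 4, seed = 9 + 1)  # rep 1 partition
  set.seed(31)
  for (f in seq_along(folds)) {
    poisoned <- ds
    # replace the test-fold rows with label-independent noise
    poisoned$values[folds[[f]], ] <-
      rnorm(length(folds[[f]]) * ncol(ds$values))
    psel <- run(poisoned)
    expect_identical(psel[[1]][[f]], base_sel[[1]][[f]],
                     info = paste("fold", f))
  }
})

test_that("paired comparison classifies win, tie and loss", {
  expect_identical(wtl_compare(rep(0.8, 10), rep(0.8, 10)), "tie")
  set.seed(2)
  noise <- rnorm(100, sd = 0.001)
  a <- 0.7 + 0.1 + noise
  b <- 0.7 + rnorm(100, sd = 0.001)
  expect_identical(wtl_compare(a, b), "win")
  expect_identical(wtl_compare(b, a), "loss")
  expect_identical(wtl_compare(c(0.5, 0.6), c(0.5, 0.7), alpha = 1e-9), "tie")
  expect_error(wtl_compare(1:3, 1:4), "same length")
})

test_that("the W/T/L summary conserves comparisons across cells", {
  ds <- separable_dataset()
  scores <- benchmark(ds, selectors = c("resi", "ranking"),
                      dimensions = c(1, 2), classifiers = c("knn", "nbayes"),
                      n_reps = 3, n_folds = 2, seed = 2)
  wtl <- wtl_summary(scores)
  expect_identical(nrow(wtl), 2L)  # two ordered pairs
  # one dataset x two classifiers = 2 cells per ordered pair
  expect_true(all(wtl$comparisons == 2L))
  expect_identical(wtl$wins + wtl$ties + wtl$losses, wtl$comparisons)
  # antisymmetry of the ordered pairs
  expect_identical(wtl$wins[1], wtl$losses[2])
  expect_identical(wtl$losses[1], wtl$wins[2])
})
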