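# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Stratified cross-validation folds
#'
#' Partitions instances into `n_folds` disjoint folds preserving the class
#' proportions: within each class the (shuffled) instances are dealt
#' round-robin, so per-class counts across folds differ by at most one.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param labels class label per instance.
#' @param n_folds number of folds; every class must have at least
#'   `n_folds` instances.
#' @param seed integer seed.
#' @return List of `n_folds` integer index vectors (sorted, disjoint,
#'   jointly covering all instances).
#' @export
stratified_folds <- function(labels, n_folds, seed) {
  f <- factor(labels)
  counts <- table(f)
  too_small <- names(counts)[counts < n_folds]
  if (length(too_small)) {
    stop("class '", too_small[1L], "' has fewer instances (",
         counts[too_small[1L]], ") than folds (", n_folds, ")")
  }
  assignment <- integer(length(f))
  with_seed(seed, {
    for (lev in levels(f)) {
      idx <- which(f == lev)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(k) sort(which(assignment == k)))
}

#' Within-fold feature standardization
#'
#' Transforms each training feature to zero mean and unit sample standard
#' deviation, and maps the test fold with the *training* means and SDs --
#' the leakage-free protocol.  A training feature with zero SD maps to
#' all-zeros in both sets.
#'
#' @param train,test numeric matrices with the same columns (test may be
#'   `NULL`).
#' @return List with standardized `train` and `test`.
#' @export
standardize_fold <- function(train, test = NULL) {
  if (nrow(train) < 2L) stop("training set needs at least 2 instances")
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  zero <- !is.finite(sd) | sd == 0
  sd[zero] <- 1
  tr <- sweep(sweep(train, 2L, mu), 2L, sd, "/")
  tr[, zero] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(test, 2L, mu), 2L, sd, "/")
    te[, zero] <- 0
  }
  list(train = tr, test = te)
}

#' Balanced accuracy from contingency counts
#'
#' `0.5 * (TP/(TP+FN) + TN/(TN+FP))` -- the mean of sensitivity and
#' specificity, insensitive to class imbalance (an all-one-class predictor
#' scores 0.5).
#'
#' @param tp,tn,fp,fn non-negative counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return Balanced accuracy in `[0, 1]`; `NA` when a class is absent
#'   from the test fold.
#' @export
bacc <- function(tp, tn, fp, fn) {
  pos <- tp + fn
  neg <- tn + fp
  if (pos == 0L || neg == 0L) return(NA_real_)
  0.5 * (tp / pos + tn / neg)
}

# BACC directly from label vectors
bacc_from_labels <- function(truth, predicted, positive) {
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  bacc(tp = sum(truth_pos & pred_pos),
       tn = sum(!truth_pos & !pred_pos),
       fp = sum(!truth_pos & pred_pos),
       fn = sum(truth_pos & !pred_pos))
}

#' The default classifier registry
#'
#' The six classifier configurations used by the benchmarking protocol,
#' each exposed through the adapter contract
#' `function(train_x, train_y, test_x) -> predicted labels`:
#'
#' * `svm_linear` -- linear-kernel SVM with cost 1 ([e1071::svm()]),
#' * `svm_poly`   -- polynomial-kernel SVM (SMO-style solver, cost 1),
#' * `knn`        -- k-nearest neighbours with `k = 3` ([class::knn()],
#'   `use.all = TRUE` for deterministic distance ties),
#' * `logistic`   -- logistic regression ([stats::glm()]),
#' * `nbayes`     -- Gaussian naive Bayes ([e1071::naiveBayes()]),
#' * `tree`       -- a C4.5-style decision tree ([rpart::rpart()]).
#'
#' @return Named list of classifier adapter functions.
#' @export
classifier_registry <- function() {
  list(
    svm_linear = function(train_x, train_y, test_x) {
      fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = 1,
                        scale = FALSE)
      stats::predict(fit, test_x)
    },
    svm_poly = function(train_x, train_y, test_x) {
      fit <- e1071::svm(train_x, train_y, kernel = "polynomial", cost = 1,
                        scale = FALSE)
      stats::predict(fit, test_x)
    },
    knn = function(train_x, train_y, test_x) {
      class::knn(train_x, test_x, train_y, k = 3, use.all = TRUE)
    },
    logistic = function(train_x, train_y, test_x) {
      df <- as.data.frame(train_x)
      names(df) <- paste0("V", seq_len(ncol(train_x)))
      df$.y <- train_y
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial())
      )
      nd <- as.data.frame(test_x)
      names(nd) <- paste0("V", seq_len(ncol(test_x)))
      p <- suppressWarnings(stats::predict(fit, nd, type = "response"))
      factor(levels(train_y)[1L + (p > 0.5)], levels = levels(train_y))
    },
    nbayes = function(train_x, train_y, test_x) {
      fit <- e1071::naiveBayes(train_x, train_y)
      suppressWarnings(stats::predict(fit, test_x))
    },
    tree = function(train_x, train_y, test_x) {
      df <- as.data.frame(train_x)
      names(df) <- paste0("V", seq_len(ncol(train_x)))
      df$.y <- train_y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 4,
                                                         cp = 0.01))
      nd <- as.data.frame(test_x)
      names(nd) <- paste0("V", seq_len(ncol(test_x)))
      stats::predict(fit, nd, type = "class")
    }
  )
}

#' The default selector registry
#'
#' Feature-selection adapters with the contract
#' `function(train_x, train_y, n) -> ordered feature indices`, used by
#' [benchmark()]: `resi`, `ranking` (absolute t-statistic), and the
#' mutual-information criteria `mrmr`, `mimr`, `cmim` (over MDL-discretised
#' training features).
#'
#' @param k,mu,epsilon RESI parameters passed through to [resi()].
#' @return Named list of selector adapter functions.
#' @export
selector_registry <- function(k = 3, mu = 0.66, epsilon = 0.1) {
  mk_mi <- function(method) {
    force(method)
    function(train_x, train_y, n) {
      mi_select(train_x, train_y, method = method, max_features = n)$selected
    }
  }
  list(
    resi = function(train_x, train_y, n) {
      resi(train_x, train_y, k = k, mu = mu, epsilon = epsilon,
           max_features = n)$selected
    },
    ranking = function(train_x, train_y, n) {
      rank_t(train_x, train_y, max_features = n)$selected
    },
    mrmr = mk_mi("mrmr"),
    mimr = mk_mi("mimr"),
    cmim = mk_mi("cmim")
  )
}

#' Repeated stratified cross-validation benchmark
#'
#' The full measurement protocol: for every repetition a fresh stratified
#' fold partition is drawn; within every fold the features are
#' standardized on the training instances only ([standardize_fold()]),
#' every selector is run on the training fold only, its ranking is
#' truncated at each requested dimension, every classifier is trained on
#' the selected training columns and scored by balanced accuracy on the
#' held-out fold.  All `(selector, dimension, classifier)` cells share the
#' same fold partition within a repetition, so scores are paired.
#'
#' @param ds an [expression_dataset()].
#' @param selectors named list of selector adapters
#'   (`function(train_x, train_y, n) -> ordered indices`) or a character
#'   vector of [selector_registry()] names.
#' @param dimensions integer vector of selected-dimension values to sweep
#'   (default the benchmark sweep 1..80).
#' @param classifiers named list of classifier adapters or a character
#'   vector of [classifier_registry()] names.
#' @param n_reps,n_folds repetitions and folds (default 10 x 10).
#' @param seed integer seed; repetition `r` uses `seed + r` for its fold
#'   partition.
#' @param dataset_name label stored in the output (useful when several
#'   data sets are pooled for [wtl_summary()]).
#' @return A `score_table` data frame with columns `dataset`, `selector`,
#'   `dimension`, `classifier`, `repetition`, `fold`, `bacc`, plus
#'   attribute `"selections"` (per repetition/fold/selector, the selected
#'   feature indices).  A fold whose test set misses a class scores `NA`.
#' @export
benchmark <- function(ds, selectors, dimensions = default_dimensions(),
                      classifiers = "knn", n_reps = 10, n_folds = 10,
                      seed = 1, dataset_name = "dataset") {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(selectors)) selectors <- selector_registry()[selectors]
  if (is.character(classifiers)) classifiers <- classifier_registry()[classifiers]
  if (is.null(names(selectors)) || any(names(selectors) == "")) {
    stop("selectors must be named")
  }
  if (is.null(names(classifiers)) || any(names(classifiers) == "")) {
    stop("classifiers must be named")
  }
  dimensions <- sort(unique(as.integer(dimensions)))
  if (max(dimensions) > ncol(ds$values)) {
    stop("largest dimension exceeds the number of features")
  }

  y <- ds$labels
  pos <- ds$positive
  records <- vector("list", n_reps * n_folds)
  selections <- vector("list", n_reps)
  ri <- 0L

  for (rep_i in seq_len(n_reps)) {
    folds <- stratified_folds(y, n_folds, seed + rep_i)
    selections[[rep_i]] <- vector("list", n_folds)
    for (fold_i in seq_len(n_folds)) {
      test_idx <- folds[[fold_i]]
      train_idx <- setdiff(seq_along(y), test_idx)
      std <- standardize_fold(ds$values[train_idx, , drop = FALSE],
                              ds$values[test_idx, , drop = FALSE])
      ytr <- droplevels(y[train_idx])
      yte <- y[test_idx]

      sel_here <- lapply(selectors, function(sf) {
        sf(std$train, ytr, max(dimensions))
      })
      selections[[rep_i]][[fold_i]] <- sel_here

      rows <- list()
      for (sname in names(selectors)) {
        sel <- sel_here[[sname]]
        if (length(sel) < max(dimensions)) {
          warning(sprintf(
            "selector '%s' returned %d features (< %d); larger dimensions use the available prefix",
            sname, length(sel), max(dimensions)))
        }
        for (dim_i in dimensions) {
          cols <- sel[seq_len(min(dim_i, length(sel)))]
          xtr <- std$train[, cols, drop = FALSE]
          xte <- std$test[, cols, drop = FALSE]
          for (cname in names(classifiers)) {
            pred <- classifiers[[cname]](xtr, ytr, xte)
            score <- bacc_from_labels(as.character(yte), as.character(pred), pos)
            rows[[length(rows) + 1L]] <- data.frame(
              dataset = dataset_name, selector = sname, dimension = dim_i,
              classifier = cname, repetition = rep_i, fold = fold_i,
              bacc = score, stringsAsFactors = FALSE)
          }
        }
      }
      ri <- ri + 1L
      records[[ri]] <- do.call(rbind, rows)
    }
  }

  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "selections") <- selections
  class(out) <- c("score_table", class(out))
  out
}

#' The benchmark dimension sweep
#'
#' The standard selected-dimension grid from 1 to 80.
#' @return Integer vector.
#' @export
default_dimensions <- function() {
  c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 12L, 15L, 18L, 20L, 30L, 40L, 50L,
    60L, 70L, 80L)
}

#' Paired comparison of two score vectors
#'
#' Two-sided paired t-test on the differences at level `alpha`: `"win"`
#' for the first method when `p < alpha` with a positive mean difference,
#' `"loss"` when negative, `"tie"` otherwise.  Degenerate all-equal pairs
#' are a tie; a constant non-zero difference is a win/loss by sign.
#'
#' @param scores_a,scores_b equal-length paired score vectors (length
#'   at least 2).
#' @param alpha significance level (default 0.05).
#' @return `"win"`, `"tie"` or `"loss"` (from the first method's
#'   perspective).
#' @export
wtl_compare <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have the same length")
  }
  if (length(scores_a) < 2L) stop("need at least 2 paired scores")
  ok <- !is.na(scores_a) & !is.na(scores_b)
  d <- scores_a[ok] - scores_b[ok]
  if (length(d) < 2L) return("tie")
  if (all(d == 0)) return("tie")
  if (stats::sd(d) == 0) return(if (mean(d) > 0) "win" else "loss")
  tt <- stats::t.test(d)
  if (tt$p.value >= alpha) return("tie")
  if (mean(d) > 0) "win" else "loss"
}

#' Win/tie/loss summary over (dataset, classifier) cells
#'
#' Summarises a [benchmark()] score table (or several, row-bound) into
#' per-method-pair win/tie/loss counts: for every ordered pair of
#' selectors and every `(dataset, classifier)` cell, the paired scores are
#' compared with [wtl_compare()].  The pairing unit is the repetition mean
#' (BACC averaged over folds and dimensions within a repetition), which
#' reduces within-repetition dependence; set `pairing = "fold"` to pair
#' the individual fold scores instead.
#'
#' @param scores a `score_table` data frame.
#' @param alpha significance level (default 0.05).
#' @param pairing `"repetition"` (default) or `"fold"`.
#' @return A data frame of class `wtl_summary` with one row per ordered
#'   selector pair: `method_a`, `method_b`, `wins`, `ties`, `losses`,
#'   `comparisons` (`= wins + ties + losses`, the number of cells).
#' @export
wtl_summary <- function(scores, alpha = 0.05,
                        pairing = c("repetition", "fold")) {
  pairing <- match.arg(pairing)
  methods <- unique(scores$selector)
  cells <- unique(scores[, c("dataset", "classifier")])
  out <- list()
  for (a in methods) {
    for (b in methods) {
      if (a == b) next
      w <- t <- l <- 0L
      for (ci in seq_len(nrow(cells))) {
        sub <- scores[scores$dataset == cells$dataset[ci] &
                        scores$classifier == cells$classifier[ci], ]
        va <- paired_scores(sub[sub$selector == a, ], pairing)
        vb <- paired_scores(sub[sub$selector == b, ], pairing)
        res <- wtl_compare(va, vb, alpha)
        if (res == "win") w <- w + 1L
        else if (res == "loss") l <- l + 1L
        else t <- t + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        method_a = a, method_b = b, wins = w, ties = t, losses = l,
        comparisons = w + t + l, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "pairing") <- pairing
  class(res) <- c("wtl_summary", class(res))
  res
}

# one paired score per unit, ordered by unit id
paired_scores <- function(sub, pairing) {
  if (pairing == "repetition") {
    agg <- stats::aggregate(bacc ~ repetition, data = sub, FUN = mean,
                            na.rm = TRUE, na.action = NULL)
    agg$bacc[order(agg$repetition)]
  } else {
    sub <- sub[order(sub$repetition, sub$fold, sub$dimension), ]
    agg <- stats::aggregate(
      bacc ~ repetition + fold, data = sub, FUN = mean,
      na.rm = TRUE, na.action = NULL)
    agg$bacc[order(agg$repetition, agg$fold)]
  }
}
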