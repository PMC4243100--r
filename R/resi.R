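#' Fit the RESI feature selection
#'
#' The two-stage forward search for redundant feature selection on binary
#' expression data:
#'
#' 1. *Irrelevant-feature removal*: every feature with `|t| < epsilon`
#'    (two-sample t-statistic against the label) is dropped.
#' 2. *Redundant-feature elimination*: the first feature is the surviving
#'    one with the largest `|t|`; each subsequent feature maximises the
#'    merit `|t| - mean(REMI(candidate; selected))`, where REMI is the
#'    instance-level redundancy of [remi()] computed from per-feature
#'    blur masks ([purity_profile()]).
#'
#' Unlike mutual-information redundancy penalties, REMI compares *which
#' instances* each feature fails to discriminate, so a feature whose
#' numerical values resemble a selected one is still admitted when its
#' predictive power covers different instances -- and an exact duplicate is
#' maximally penalised as soon as its source is selected.
#'
#' Purity profiles are computed once per surviving feature and cached, so
#' the greedy loop costs one mask intersection per step; selecting 80
#' features from a 60 x 2000 matrix takes a few seconds on one CPU.
#'
#' All argmax ties break towards the lower feature index; the algorithm is
#' fully deterministic.
#'
#' @param x an [expression_dataset()], or a numeric matrix (instances in
#'   rows) with `y` supplied.
#' @param y binary labels (ignored when `x` is an expression dataset).
#' @param k neighbourhood size for the purity computation (default 3).
#' @param mu blur/clear discernment threshold (default 0.66; with `k = 3`
#'   a purity of 2/3 is clear-discerned).
#' @param epsilon relevance cutoff on `|t|` for stage 1 (default 0.1).
#'   Note the cutoff is applied to the data as given; on standardized
#'   expression values the default removes only near-null features.
#' @param max_features stop after this many selections (default 80).
#' @param min_merit optional early stop: terminate when the best candidate
#'   merit falls below this value (default `NULL`, disabled).
#' @return An object of classes `resi` and `feature_ranking`; a list with
#'   `selected` (feature indices into the input matrix, in selection
#'   order), `feature_ids`, `merits` (per-step score: `|t|` for the seed,
#'   the REMI merit thereafter), `abs_t` (of the selected features),
#'   `removed_irrelevant` (stage-1 drop count) and `params`.
#' @examples
#' sim <- generate_expression(synthetic_spec(n = 40, n_irrelevant = 20, seed = 1))
#' fit <- resi(sim$dataset, max_features = 5)
#' print(fit)
#' @seealso [rank_t()] for the pure `|t|` ranking baseline, [mi_select()]
#'   for the mutual-information comparators.
#' @export
resi <- function(x, y = NULL, k = 3, mu = 0.66, epsilon = 0.1,
                 max_features = 80, min_merit = NULL) {
  d <- as_xy(x, y)
  if (k < 1L) stop("k must be >= 1")
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (max_features < 1L) stop("max_features must be >= 1")
  if (nrow(d$x) <= k) {
    stop("insufficient instances: purity with k = ", k,
         " needs at least ", k + 1L, " instances")
  }

  m <- ncol(d$x)
  tstat <- t_statistics(d$x, d$y)
  abs_t <- abs(tstat)

  keep <- which(abs_t >= epsilon)
  if (length(keep) == 0L) {
    stop(sprintf(
      "no relevant features: all %d features have |t| < epsilon = %g (max |t| = %g)",
      m, epsilon, max(abs_t)))
  }

  # blur masks cached for every surviving feature
  blur <- matrix(FALSE, nrow(d$x), length(keep))
  for (j in seq_along(keep)) {
    p <- neighborhood_purity(d$x[, keep[j]], d$y, k)
    blur[, j] <- p <= mu
  }
  blur_counts <- colSums(blur)

  at <- abs_t[keep]
  n_cand <- length(keep)
  selected <- integer(0)      # positions within 'keep'
  merits <- numeric(0)
  penalty_sum <- numeric(n_cand)   # running sum of REMI(candidate; selected)
  available <- rep(TRUE, n_cand)

  seed <- argmax_tol(at)  # lowest index on (near-)ties
  selected <- seed
  merits <- at[seed]
  available[seed] <- FALSE

  add_penalty <- function(penalty_sum, s) {
    # REMI(candidate; s) = |blur_cand & blur_s| / |blur_cand|, 0 when the
    # candidate has no blur instance
    overlap <- as.vector(crossprod(blur, blur[, s]))
    r <- ifelse(blur_counts > 0, overlap / pmax(blur_counts, 1L), 0)
    penalty_sum + r
  }
  penalty_sum <- add_penalty(penalty_sum, seed)

  while (length(selected) < max_features && any(available)) {
    merit <- at - penalty_sum / length(selected)
    merit[!available] <- -Inf
    best <- argmax_tol(merit)
    if (!is.null(min_merit) && merit[best] < min_merit) break
    selected <- c(selected, best)
    merits <- c(merits, merit[best])
    available[best] <- FALSE
    penalty_sum <- add_penalty(penalty_sum, best)
  }

  idx <- keep[selected]
  new_feature_ranking(
    method = "resi",
    selected = idx,
    feature_ids = colnames(d$x)[idx],
    merits = merits,
    abs_t = abs_t[idx],
    removed_irrelevant = m - length(keep),
    params = list(k = k, mu = mu, epsilon = epsilon,
                  max_features = max_features, min_merit = min_merit),
    n = nrow(d$x), m = m,
    extra_class = "resi"
  )
}

#' Rank features by absolute t-statistic
#'
#' The ranking baseline: features sorted by decreasing `|t|` with no
#' redundancy correction, truncated to `max_features`.  Ties break towards
#' the lower feature index.
#'
#' @inheritParams resi
#' @param max_features number of top features to keep (default all).
#' @return A `feature_ranking` object; `merits` holds the `|t|` values.
#' @export
rank_t <- function(x, y = NULL, max_features = Inf) {
  d <- as_xy(x, y)
  abs_t <- abs(t_statistics(d$x, d$y))
  ord <- order(-abs_t)                       # stable: ties -> lower index
  ord <- ord[seq_len(min(length(ord), max_features))]
  new_feature_ranking(
    method = "ranking",
    selected = ord,
    feature_ids = colnames(d$x)[ord],
    merits = abs_t[ord],
    abs_t = abs_t[ord],
    removed_irrelevant = 0L,
    params = list(max_features = max_features),
    n = nrow(d$x), m = ncol(d$x)
  )
}

# argmax with a numeric tie tolerance: candidates within tol of the
# maximum count as tied, and the lowest index wins, so selection orders are
# stable when algebraically equal merits differ only in floating-point
# round-off
argmax_tol <- function(v, tol = 1e-9) {
  m <- max(v)
  if (!is.finite(m)) return(which.max(v))
  which(v >= m - tol)[1L]
}

# normalise (x, y) / expression_dataset input to a matrix + factor pair
as_xy <- function(x, y) {
  if (inherits(x, "expression_dataset")) {
    return(list(x = x$values, y = x$labels))
  }
  if (is.null(y)) stop("y must be supplied when x is a plain matrix")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  list(x = x, y = factor(y))
}

new_feature_ranking <- function(method, selected, feature_ids, merits, abs_t,
                                removed_irrelevant, params, n, m,
                                extra_class = character()) {
  structure(
    list(method = method, selected = selected, feature_ids = feature_ids,
         merits = merits, abs_t = abs_t,
         removed_irrelevant = removed_irrelevant,
         params = params, n = n, m = m),
    class = c(extra_class, "feature_ranking")
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("Feature selection by '%s': %d of %d features (n = %d instances)\n",
              x$method, length(x$selected), x$m, x$n))
  if (x$removed_irrelevant > 0) {
    cat(sprintf("  stage 1 removed %d irrelevant features\n", x$removed_irrelevant))
  }
  top <- utils::head(seq_along(x$selected), 10L)
  cat("  top features:\n")
  for (i in top) {
    cat(sprintf("    %2d. %-12s merit %8.4f\n", i, x$feature_ids[i], x$merits[i]))
  }
  if (length(x$selected) > 10L) cat("    ...\n")
  invisible(x)
}

#' @export
summary.feature_ranking <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(method = object$method, params = object$params,
                 removed_irrelevant = object$removed_irrelevant,
                 table = df),
            class = "summary.feature_ranking")
}

#' @export
print.summary.feature_ranking <- function(x, ...) {
  cat(sprintf("Method: %s\n", x$method))
  if (length(x$params)) {
    pars <- vapply(x$params, function(p) {
      if (is.null(p)) "disabled" else paste(format(p), collapse = ",")
    }, character(1))
    cat("Parameters:", paste(names(pars), pars, sep = " = ", collapse = ", "), "\n")
  }
  if (x$removed_irrelevant > 0) {
    cat("Irrelevant features removed:", x$removed_irrelevant, "\n")
  }
  print(x$table)
  invisible(x)
}

#' @export
as.data.frame.feature_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$selected),
             feature = x$feature_ids,
             index = x$selected,
             merit = x$merits,
             abs_t = x$abs_t,
             stringsAsFactors = FALSE)
}

#' @export
plot.feature_ranking <- function(x, ...) {
  plot(seq_along(x$merits), x$merits, type = "b", pch = 16,
       xlab = "selection step", ylab = "merit",
       main = sprintf("%s merit path", x$method), ...)
  invisible(x)
}
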