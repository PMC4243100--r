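#' Neighbourhood purity of each instance on one feature
#'
#' For every instance `u`, the fraction of its `k` nearest neighbour
#' instances *on this single feature* that carry the same class label as
#' `u`.  Neighbours are the `k` instances `v != u` with the smallest
#' `|x[v] - x[u]|`; the instance itself is excluded from its own
#' neighbourhood (the kNN-classifier convention), and distance ties are
#' broken towards the lower instance index so the result is deterministic.
#'
#' A purity close to 1 means the feature locally discriminates the
#' instance's class well; purity is always a multiple of `1/k`.
#'
#' @param x numeric vector of feature values, one per instance.
#' @param labels class label per instance (any two-valued vector).
#' @param k neighbourhood size; requires `length(x) >= k + 1`.
#' @return Numeric vector of purities in `[0, 1]`.
#' @seealso [discern()], [remi()], [purity_profile()].
#' @export
neighborhood_purity <- function(x, labels, k) {
  n <- length(x)
  if (length(labels) != n) stop("x and labels must have the same length")
  if (k < 1L) stop("k must be a positive integer")
  if (n <= k) {
    stop("insufficient instances: need at least k + 1 = ", k + 1L, ", got ", n)
  }
  labels <- as.integer(factor(labels))
  same <- integer(n)
  for (u in seq_len(n)) {
    d <- abs(x - x[u])
    d[u] <- Inf
    nb <- order(d)[seq_len(k)]  # order() is stable: ties -> lower index
    same[u] <- sum(labels[nb] == labels[u])
  }
  same / k
}

#' Blur/clear discernment of instances
#'
#' An instance is *clear-discerned* by a feature when its neighbourhood
#' purity strictly exceeds the threshold `mu`, and *blur-discerned*
#' otherwise (purity `<= mu`).  With the default `k = 3`, `mu = 0.66`, a
#' purity of `2/3` is clear and `1/3` is blur.
#'
#' @param purities purity vector from [neighborhood_purity()].
#' @param mu discernment threshold in `(0, 1)`.
#' @return Logical vector, `TRUE` where the instance is blur-discerned.
#' @export
discern <- function(purities, mu) {
  if (any(purities < 0 | purities > 1)) stop("purities must lie in [0, 1]")
  purities <= mu
}

#' Purity profile of a feature
#'
#' Convenience wrapper bundling [neighborhood_purity()] and [discern()]:
#' the carrier of a feature's "predictive power distribution".
#'
#' @inheritParams neighborhood_purity
#' @inheritParams discern
#' @return A list of class `purity_profile` with elements `purities`,
#'   `blur` (logical mask), `k` and `mu`.
#' @export
purity_profile <- function(x, labels, k = 3, mu = 0.66) {
  p <- neighborhood_purity(x, labels, k)
  structure(list(purities = p, blur = discern(p, mu), k = k, mu = mu),
            class = "purity_profile")
}

#' @export
print.purity_profile <- function(x, ...) {
  cat(sprintf("Purity profile (k = %d, mu = %g): %d/%d instances blur-discerned\n",
              x$k, x$mu, sum(x$blur), length(x$blur)))
  invisible(x)
}

#' REMI: redundancy measured on instances
#'
#' The fraction of the instances blur-discerned on feature `p` that are
#' also blur-discerned on feature `q`.  `remi(p, q) = 0` means every
#' instance that `p` fails to discriminate is handled by `q` -- the two
#' predictive powers are fully complementary; `remi(p, q) = 1` means `q`
#' adds nothing on `p`'s problem instances, i.e. `q` is redundant to `p`.
#'
#' Note the asymmetry: the first argument supplies the denominator.  In
#' the merit function ([j_remi()]) the *candidate* feature is the first
#' argument, so the penalty is the fraction of the candidate's blur
#' instances already blurred on each selected feature.
#'
#' When the first feature has no blur-discerned instance the ratio is
#' undefined; the package defines it as 0 (no redundancy penalty for a
#' feature that clear-discerns every instance).
#'
#' @param blur_p,blur_q logical blur masks of equal length (see
#'   [discern()]).
#' @return A number in `[0, 1]`.
#' @export
remi <- function(blur_p, blur_q) {
  if (length(blur_p) != length(blur_q)) {
    stop("blur masks must have the same length")
  }
  denom <- sum(blur_p)
  if (denom == 0L) return(0)
  sum(blur_p & blur_q) / denom
}

#' Two-sample t-statistic of one feature against a binary label
#'
#' `(mean_1 - mean_2) / sqrt(var_1/n_1 + var_2/n_2)` with sample (n-1)
#' variances -- the unequal-variance (Welch) form, used as the relevance
#' measure of a feature: large `|t|` means well-separated class centroids
#' relative to the within-class spread.  The sign follows the factor level
#' order of `labels`; only `|t|` is used downstream.
#'
#' Degenerate cases: equal means with zero pooled variance give 0; unequal
#' means with zero variance give signed infinity (maximal relevance).
#'
#' @inheritParams neighborhood_purity
#' @return A single (possibly infinite) number.
#' @export
t_statistic <- function(x, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly 2 classes")
  if (any(table(f) < 2L)) stop("each class needs at least 2 instances")
  x1 <- x[f == levels(f)[1L]]
  x2 <- x[f == levels(f)[2L]]
  num <- mean(x1) - mean(x2)
  den <- sqrt(stats::var(x1) / length(x1) + stats::var(x2) / length(x2))
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

# vectorised t-statistics over the columns of a matrix
t_statistics <- function(values, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly 2 classes")
  i1 <- f == levels(f)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 instances")
  m1 <- colMeans(values[i1, , drop = FALSE])
  m2 <- colMeans(values[!i1, , drop = FALSE])
  v1 <- colSums(sweep(values[i1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(values[!i1, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  num <- m1 - m2
  den <- sqrt(v1 / n1 + v2 / n2)
  t <- num / den
  t[den == 0 & num == 0] <- 0
  t[den == 0 & num != 0] <- sign(num[den == 0 & num != 0]) * Inf
  unname(t)
}

#' Merit of a candidate feature given the selected set
#'
#' `|t|` of the candidate minus the mean REMI of the candidate to the
#' already-selected features: relevance rewarded, instance-level
#' redundancy penalised.
#'
#' @param candidate_abs_t absolute t-statistic of the candidate.
#' @param remi_to_selected vector of `remi(candidate, s)` values, one per
#'   selected feature; must be non-empty (the first feature is seeded by
#'   `|t|` alone).
#' @return The merit score.
#' @export
j_remi <- function(candidate_abs_t, remi_to_selected) {
  if (length(remi_to_selected) < 1L) {
    stop("the selected set is empty: the first feature is chosen by |t| alone")
  }
  candidate_abs_t - mean(remi_to_selected)
}
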