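#' Entropy of a discrete variable (bits)
#'
#' Plug-in estimate from empirical frequencies.
#'
#' @param a vector of discrete codes (any type coercible to factor).
#' @return Non-negative entropy in bits.
#' @export
entropy_bits <- function(a) {
  p <- table(a)
  p <- p[p > 0] / length(a)
  -sum(p * log2(p))
}

#' Mutual information of two discrete variables (bits)
#'
#' Plug-in estimate `sum p(a,b) log2[p(a,b) / (p(a) p(b))]` from the
#' empirical joint frequencies.
#'
#' @param a,b equal-length vectors of discrete codes.
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have the same length")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  prod <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / prod[nz]))
}

#' Conditional mutual information given a class label (bits)
#'
#' `I(a; b | y) = sum_y p(y) I(a; b | Y = y)` with the plug-in estimator
#' applied within each class stratum.
#'
#' @inheritParams mutual_information
#' @param y stratifying (class) variable of the same length.
#' @return Non-negative conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(a, b, y) {
  if (length(a) != length(b) || length(a) != length(y)) {
    stop("a, b and y must have the same length")
  }
  y <- factor(y)
  out <- 0
  for (lev in levels(y)) {
    i <- y == lev
    out <- out + mean(i) * mutual_information(a[i], b[i])
  }
  out
}

# integer codes of the paired variable (a, b); used for joint MI terms
joint_code <- function(a, b) {
  as.integer(interaction(a, b, drop = TRUE))
}

#' Symmetrical uncertainty of two discrete variables
#'
#' `SU(a, b) = 2 I(a; b) / (H(a) + H(b))`, a normalised mutual information
#' in `[0, 1]`; 0 when both entropies vanish.
#'
#' @inheritParams mutual_information
#' @return Symmetrical uncertainty in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(a, b) {
  h <- entropy_bits(a) + entropy_bits(b)
  if (h == 0) return(0)
  2 * mutual_information(a, b) / h
}

#' CFS merit of a feature subset
#'
#' The correlation-based subset merit
#' `k * r_cf / sqrt(k + k (k - 1) * r_ff)`, where `r_cf` is the mean
#' feature-class correlation and `r_ff` the mean feature-feature
#' correlation over the subset, both measured by symmetrical uncertainty
#' on discretised features.  Rewarding class correlation and penalising
#' inter-feature correlation, it decreases when a duplicated feature is
#' added to the subset.
#'
#' @param selected integer indices of the subset (at least one).
#' @param codes matrix of discrete feature codes, instances in rows.
#' @param y binary labels.
#' @return The subset merit (a single number).
#' @export
cfs_merit <- function(selected, codes, y) {
  k <- length(selected)
  if (k < 1L) stop("the subset must contain at least one feature")
  r_cf <- mean(vapply(selected, function(j) {
    symmetrical_uncertainty(codes[, j], y)
  }, numeric(1)))
  if (k == 1L) return(r_cf)
  pairs <- utils::combn(selected, 2L)
  r_ff <- mean(apply(pairs, 2L, function(p) {
    symmetrical_uncertainty(codes[, p[1L]], codes[, p[2L]])
  }))
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}
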