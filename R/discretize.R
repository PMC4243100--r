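#' Fayyad-Irani MDL discretization of one feature
#'
#' Recursive entropy-minimisation binning with the minimum-description-
#' length stopping rule.  Candidate cut points are midpoints between
#' adjacent distinct values whose examples carry differing class labels;
#' the boundary minimising the class entropy of the induced partition is
#' accepted only when its information gain exceeds
#' `log2(N - 1)/N + Delta/N`, where
#' `Delta = log2(3^c - 2) - (c*Ent(S) - c1*Ent(S1) - c2*Ent(S2))` and `c`,
#' `c1`, `c2` count the classes present in the set and the two halves.
#' Accepted halves are split recursively.  A feature for which no cut is
#' accepted discretises to a single bin (empty `cut_points`) and carries
#' no information about the label.
#'
#' @param x numeric feature values.
#' @param y class labels (binary in this package's use, but the rule is
#'   general).
#' @return A list of class `discretized_feature` with `cut_points`
#'   (sorted thresholds, possibly empty) and `bins` (integer codes;
#'   `bins[u]` is the number of cut points strictly below `x[u]`).
#' @export
mdl_discretize <- function(x, y) {
  if (length(x) < 2L) stop("need at least 2 instances")
  y <- as.integer(factor(y))
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cuts <- mdl_cuts(xs, ys)
  structure(list(cut_points = sort(cuts), bins = apply_cuts(x, cuts)),
            class = "discretized_feature")
}

#' Apply fixed cut points to values
#'
#' Bins values against previously learned thresholds: code = number of cut
#' points strictly below the value.  Used to carry a training-fold
#' discretization onto a test fold.
#'
#' @param x numeric values.
#' @param cut_points sorted thresholds (possibly empty).
#' @return Integer bin codes in `0:length(cut_points)`.
#' @export
apply_cuts <- function(x, cut_points) {
  if (length(cut_points) == 0L) return(integer(length(x)))
  as.integer(rowSums(outer(x, sort(cut_points), FUN = ">")))
}

#' @export
print.discretized_feature <- function(x, ...) {
  cat(sprintf("MDL discretization: %d cut point(s)", length(x$cut_points)))
  if (length(x$cut_points)) {
    cat(" at", paste(signif(x$cut_points, 6), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# entropy in bits of a label vector
ent_bits <- function(y) {
  p <- tabulate(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# recursive MDL cut search on value-sorted data
mdl_cuts <- function(xs, ys) {
  n <- length(ys)
  if (n < 2L) return(numeric(0))

  # candidate boundaries: between adjacent *distinct* values whose
  # examples include differing labels
  vals <- unique(xs)
  if (length(vals) < 2L) return(numeric(0))
  # index of last occurrence of each distinct value in the sorted vector
  ends <- cumsum(rle(xs)$lengths)
  cand <- integer(0)
  for (b in seq_len(length(vals) - 1L)) {
    i <- ends[b]
    left_labs <- ys[xs == vals[b]]
    right_labs <- ys[xs == vals[b + 1L]]
    if (length(unique(c(left_labs, right_labs))) > 1L) cand <- c(cand, i)
  }
  if (length(cand) == 0L) return(numeric(0))

  e_all <- ent_bits(ys)
  best <- NULL
  best_e <- Inf
  for (i in cand) {
    e_split <- (i / n) * ent_bits(ys[seq_len(i)]) +
      ((n - i) / n) * ent_bits(ys[(i + 1L):n])
    if (e_split < best_e) {
      best_e <- e_split
      best <- i
    }
  }

  gain <- e_all - best_e
  y1 <- ys[seq_len(best)]
  y2 <- ys[(best + 1L):n]
  c_all <- length(unique(ys))
  delta <- log2(3^c_all - 2) -
    (c_all * e_all - length(unique(y1)) * ent_bits(y1) -
       length(unique(y2)) * ent_bits(y2))
  threshold <- log2(n - 1) / n + delta / n
  if (gain <= threshold) return(numeric(0))

  cut <- (xs[best] + xs[best + 1L]) / 2
  c(mdl_cuts(xs[seq_len(best)], y1),
    cut,
    mdl_cuts(xs[(best + 1L):n], y2))
}
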