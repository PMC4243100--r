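#' Greedy forward selection with mutual-information merit functions
#'
#' The classical redundancy-aware comparators, all run in the same greedy
#' forward-search harness: the first feature maximises the relevance
#' `I(X; Y)`; each later step maximises the chosen criterion over the
#' remaining candidates (argmax ties break towards the lower feature
#' index).  Writing `rel = I(Xp; Y)`, `mi_i = I(Xp; Xi)` and
#' `cmi_i = I(Xp; Xi | Y)` for a candidate `Xp` against each selected
#' feature `Xi`:
#'
#' * `mifs`:  `rel - beta * sum(mi_i)` (`beta` must be given; no default
#'   is assumed).
#' * `mrmr`:  `rel - mean(mi_i)` -- MIFS with `beta = 1/(p-1)` at step `p`.
#' * `mifsu`: `rel - beta * sum(I(Xi;Y)/H(Xi) * mi_i)`.
#' * `mimr`:  `rel - mean(mi_i - cmi_i)`; the three-way interaction
#'   `I(Xi; Xp; Y) = I(Xp; Xi) - I(Xp; Xi | Y)` replaces plain MI.
#' * `jmi`:   `sum_i I({Xp, Xi}; Y)` (joint MI with each selected
#'   feature); produces the same selection order as `mimr`.
#' * `cmim`:  `rel - max_i(mi_i - cmi_i)` -- the worst pairwise
#'   interaction instead of the average.
#' * `if`:    `min_i [I({Xp, Xi}; Y) - I(Xi; Y)]` (informative
#'   fragments); identical scores to `cmim` by the chain rule.
#'
#' Continuous input is discretised per feature with [mdl_discretize()];
#' features for which no cut is accepted carry `I(X; Y) = 0` and are
#' excluded as irrelevant.  Supply `discretize = FALSE` when `x` already
#' holds discrete codes.
#'
#' @inheritParams resi
#' @param method criterion name (see above).
#' @param max_features number of features to select.
#' @param beta redundancy weight for `mifs` / `mifsu`; required for those
#'   methods, ignored otherwise.
#' @param discretize apply MDL discretization to each feature first
#'   (default `TRUE`).
#' @return A `feature_ranking` object (see [resi()]); `merits` holds the
#'   criterion score at each step (relevance `I(X; Y)` for the first).
#' @export
mi_select <- function(x, y = NULL,
                      method = c("mrmr", "mifs", "mifsu", "mimr", "jmi",
                                 "cmim", "if"),
                      max_features = 80, beta = NULL, discretize = TRUE) {
  method <- match.arg(method)
  if (method %in% c("mifs", "mifsu") && is.null(beta)) {
    stop("method '", method, "' requires an explicit beta")
  }
  d <- as_xy(x, y)
  m <- ncol(d$x)
  yf <- factor(d$y)

  if (discretize) {
    codes <- matrix(0L, nrow(d$x), m)
    for (j in seq_len(m)) {
      codes[, j] <- mdl_discretize(d$x[, j], yf)$bins
    }
  } else {
    codes <- d$x
    storage.mode(codes) <- "integer"
  }
  colnames(codes) <- colnames(d$x)

  rel <- vapply(seq_len(m), function(j) mutual_information(codes[, j], yf),
                numeric(1))
  keep <- which(rel > 1e-12)
  if (length(keep) == 0L) {
    stop("no relevant features: every feature has I(X; Y) = 0 after discretization")
  }

  at <- rel[keep]
  n_cand <- length(keep)
  available <- rep(TRUE, n_cand)
  selected <- integer(0)
  merits <- numeric(0)

  h_feat <- vapply(keep, function(j) entropy_bits(codes[, j]), numeric(1))

  # per-candidate accumulators, updated when a feature enters the set
  sum_mi <- numeric(n_cand)       # sum of I(Xp; Xi)
  sum_wmi <- numeric(n_cand)      # sum of I(Xi;Y)/H(Xi) * I(Xp; Xi)
  sum_inter <- numeric(n_cand)    # sum of I(Xp;Xi) - I(Xp;Xi|Y)
  max_inter <- rep(-Inf, n_cand)  # max of the same
  sum_joint <- numeric(n_cand)    # sum of I({Xp, Xi}; Y)
  min_frag <- rep(Inf, n_cand)    # min of I({Xp, Xi}; Y) - I(Xi; Y)

  seed <- argmax_tol(at)
  selected <- seed
  merits <- at[seed]
  available[seed] <- FALSE

  update <- function(s) {
    cs <- codes[, keep[s]]
    for (p in which(available)) {
      cp <- codes[, keep[p]]
      mi_ps <- mutual_information(cp, cs)
      sum_mi[p] <<- sum_mi[p] + mi_ps
      w <- if (h_feat[s] > 0) at[s] / h_feat[s] else 0
      sum_wmi[p] <<- sum_wmi[p] + w * mi_ps
      if (method %in% c("mimr", "cmim")) {
        inter <- mi_ps - conditional_mutual_information(cp, cs, yf)
        sum_inter[p] <<- sum_inter[p] + inter
        max_inter[p] <<- max(max_inter[p], inter)
      }
      if (method %in% c("jmi", "if")) {
        jrel <- mutual_information(joint_code(cp, cs), yf)
        sum_joint[p] <<- sum_joint[p] + jrel
        min_frag[p] <<- min(min_frag[p], jrel - at[s])
      }
    }
  }
  update(seed)

  while (length(selected) < max_features && any(available)) {
    p1 <- length(selected)  # p - 1
    merit <- switch(method,
      mifs  = at - beta * sum_mi,
      mrmr  = at - sum_mi / p1,
      mifsu = at - beta * sum_wmi,
      mimr  = at - sum_inter / p1,
      cmim  = at - max_inter,
      jmi   = sum_joint,
      "if"  = min_frag
    )
    merit[!available] <- -Inf
    best <- argmax_tol(merit)
    selected <- c(selected, best)
    merits <- c(merits, merit[best])
    available[best] <- FALSE
    update(best)
  }

  idx <- keep[selected]
  new_feature_ranking(
    method = method,
    selected = idx,
    feature_ids = colnames(codes)[idx],
    merits = merits,
    abs_t = rel[idx],
    removed_irrelevant = m - length(keep),
    params = list(max_features = max_features, beta = beta,
                  discretize = discretize),
    n = nrow(codes), m = m
  )
}
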