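#' Specification of a synthetic expression dataset
#'
#' Describes a microarray-like dataset with planted feature roles, the
#' regime the package's methods target (tens to hundreds of instances,
#' thousands of features, binary and possibly imbalanced classes):
#'
#' * *relevant* features: independent `Normal(+/- effect_size/2, 1)` by
#'   class -- effect sizes are in within-class SD units so the expected
#'   `|t|` is analytic;
#' * *duplicate* features: a planted relevant feature plus
#'   `Normal(0, noise_sd)` noise (`noise_sd = 0` gives exact copies with
#'   identical t-statistics and blur masks);
#' * *complementary* pairs `(f, g)`: `f` separates the classes perfectly
#'   (clusters at `+/- separation/2`) on a designated stratified half of
#'   the instances and is `Normal(0, 1)` noise on the other half, `g` the
#'   reverse -- each member discriminates a different half of the
#'   instance space, so their instance-level redundancy ([remi()]) is
#'   zero although both are strongly relevant;
#' * *irrelevant* features: `Normal(0, 1)`, independent of the label.
#'
#' Defaults plant the package's reference recovery problem: 60 instances
#' (21/39 class split), 2 relevant features of effect size 1.2, one exact
#' duplicate of the first relevant feature, one complementary pair with
#' clusters at +/-4 SD, and 200 irrelevant features.
#'
#' @param n number of instances.
#' @param class_ratio fraction of instances in the positive (minority)
#'   class.
#' @param n_relevant number of independent relevant features.
#' @param effect_size class mean shift of relevant features, in SD units.
#' @param duplicate_blocks list of blocks, each a list with `source`
#'   (index of the relevant feature copied), `copies` and `noise_sd`.
#' @param n_complementary_pairs number of complementary feature pairs.
#' @param separation cluster separation of a complementary member on its
#'   designated half, in SD units.
#' @param n_irrelevant number of pure-noise features.
#' @param seed integer seed; generation is bit-reproducible.
#' @return A validated list of class `synthetic_spec`.
#' @seealso [generate_expression()]
#' @export
synthetic_spec <- function(n = 60, class_ratio = 0.35,
                           n_relevant = 2, effect_size = 1.2,
                           duplicate_blocks = list(
                             list(source = 1, copies = 1, noise_sd = 0)),
                           n_complementary_pairs = 1, separation = 8,
                           n_irrelevant = 200, seed = 1) {
  n_pos <- round(n * class_ratio)
  n_neg <- n - n_pos
  if (n_pos < 2L || n_neg < 2L) {
    stop("infeasible spec: each class needs at least 2 instances (got ",
         n_pos, "/", n_neg, ")")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  for (b in duplicate_blocks) {
    if (is.null(b$source) || b$source < 1 || b$source > n_relevant) {
      stop("duplicate block source must index a relevant feature")
    }
    if (is.null(b$copies) || b$copies < 1) stop("duplicate block needs copies >= 1")
    if (is.null(b$noise_sd) || b$noise_sd < 0) stop("noise_sd must be >= 0")
  }
  structure(list(n = n, class_ratio = class_ratio, n_pos = n_pos,
                 n_neg = n_neg, n_relevant = n_relevant,
                 effect_size = effect_size,
                 duplicate_blocks = duplicate_blocks,
                 n_complementary_pairs = n_complementary_pairs,
                 separation = separation, n_irrelevant = n_irrelevant,
                 seed = seed),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  n_dup <- sum(vapply(x$duplicate_blocks, function(b) b$copies, numeric(1)))
  cat(sprintf(
    "Synthetic spec: %d instances (%d/%d), %d features (%d relevant + %d duplicate + %d complementary + %d irrelevant), seed %d\n",
    x$n, x$n_pos, x$n_neg,
    x$n_relevant + n_dup + 2L * x$n_complementary_pairs + x$n_irrelevant,
    x$n_relevant, n_dup, 2L * x$n_complementary_pairs, x$n_irrelevant,
    x$seed))
  invisible(x)
}

#' Generate a synthetic expression dataset with known feature roles
#'
#' Realises a [synthetic_spec()]: draws the labels, the planted feature
#' blocks and the noise features, and returns the dataset together with a
#' ground-truth table so downstream tests can assert on feature *roles*
#' rather than column indices.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`,
#'   a data frame with one row per feature: `feature` (id), `role`
#'   (`"relevant"`, `"duplicate"`, `"complementary"`, `"irrelevant"`),
#'   `source` (id of the copied feature, duplicates only) and `pair`
#'   (pair index, complementary members only).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    labels <- rep(c("case", "control"), c(spec$n_pos, spec$n_neg))
    labels <- labels[sample.int(n)]
    is_pos <- labels == "case"
    shift <- ifelse(is_pos, spec$effect_size / 2, -spec$effect_size / 2)

    cols <- list(); ids <- character(0)
    role <- character(0); src <- character(0); pair <- integer(0)
    push <- function(x, id, r, s = NA_character_, p = NA_integer_) {
      cols[[length(cols) + 1L]] <<- x
      ids <<- c(ids, id); role <<- c(role, r)
      src <<- c(src, s); pair <<- c(pair, p)
    }

    rel_values <- list()
    for (j in seq_len(spec$n_relevant)) {
      x <- stats::rnorm(n) + shift
      rel_values[[j]] <- x
      push(x, paste0("REL", j), "relevant")
    }

    for (bi in seq_along(spec$duplicate_blocks)) {
      b <- spec$duplicate_blocks[[bi]]
      for (ci in seq_len(b$copies)) {
        x <- rel_values[[b$source]] + stats::rnorm(n, 0, b$noise_sd)
        push(x, sprintf("DUP%d.%d", bi, ci), "duplicate",
             s = paste0("REL", b$source))
      }
    }

    for (pi in seq_len2(spec$n_complementary_pairs)) {
      # stratified half: each member separates the classes on its half
      half <- logical(n)
      for (cl in c(TRUE, FALSE)) {
        idx <- which(is_pos == cl)
        half[idx[sample.int(length(idx), floor(length(idx) / 2))]] <- TRUE
      }
      sep <- spec$separation / 2
      f <- ifelse(half, ifelse(is_pos, sep, -sep), stats::rnorm(n))
      g <- ifelse(!half, ifelse(is_pos, sep, -sep), stats::rnorm(n))
      push(f, paste0("CMPa", pi), "complementary", p = pi)
      push(g, paste0("CMPb", pi), "complementary", p = pi)
    }

    for (j in seq_len2(spec$n_irrelevant)) {
      push(stats::rnorm(n), paste0("IRR", j), "irrelevant")
    }

    values <- do.call(cbind, cols)
    colnames(values) <- ids
    rownames(values) <- paste0("S", seq_len(n))
    ds <- expression_dataset(values, labels)
    truth <- data.frame(feature = ids, role = role, source = src,
                        pair = pair, stringsAsFactors = FALSE)
    list(dataset = ds, truth = truth)
  })
}

# seq_len that tolerates 0 without surprises in for-loops
seq_len2 <- function(k) seq_len(max(0L, as.integer(k)))
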