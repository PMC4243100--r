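#' Construct an expression dataset
#'
#' The universal input container of the package: a numeric matrix of `n`
#' instances (samples) by `m` features (genes) together with a binary class
#' label per instance.  Labels are kept as a two-level factor; the smaller
#' class is designated the *positive* class, the convention used throughout
#' for sensitivity/specificity and balanced accuracy, so that sensitivity is
#' always reported on the minority class in imbalanced data.
#'
#' @param values numeric matrix, instances in rows, features in columns.
#' @param labels vector of length `nrow(values)` with exactly two distinct
#'   values (each class must contain at least two instances).
#' @param feature_ids,instance_ids optional unique identifiers; default to
#'   the dimnames of `values`, or `F1..Fm` / `S1..Sn` when absent.
#' @param impute if `TRUE`, missing cells are replaced by the mean of the
#'   non-missing entries of the same feature (the preprocessing applied to
#'   public microarray sets with scattered missing spots).  With the default
#'   `FALSE`, missing values are an error.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the `n x m` matrix, dimnames set), `labels` (factor) and
#'   `positive` (the label designated positive).
#' @seealso [load_dataset()] for delimited-file input, [validate_dataset()].
#' @export
expression_dataset <- function(values, labels,
                               feature_ids = NULL, instance_ids = NULL,
                               impute = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(m))
  }
  if (is.null(instance_ids)) {
    instance_ids <- rownames(values)
    if (is.null(instance_ids)) instance_ids <- paste0("S", seq_len(n))
  }
  dimnames(values) <- list(as.character(instance_ids), as.character(feature_ids))

  if (impute) values <- impute_feature_means(values)

  labels <- factor(as.character(labels))
  if (nlevels(labels) > 2L) {
    stop("unsupported task: expected a binary label, found ", nlevels(labels),
         " levels (", paste(levels(labels), collapse = ", "), ")")
  }
  counts <- table(labels)
  # minority class is 'positive'; deterministic tie-break on level order
  positive <- names(counts)[which.min(counts)]

  ds <- structure(
    list(values = values, labels = labels, positive = positive),
    class = "expression_dataset"
  )
  issues <- validate_dataset(ds)
  if (length(issues)) {
    stop("invalid expression dataset:\n  - ", paste(issues, collapse = "\n  - "))
  }
  ds
}

#' Validate an expression dataset
#'
#' Reports (rather than raises) violations of the container's invariants:
#' a numeric matrix without missing values, exactly two label classes with
#' at least two instances each, unique feature and instance identifiers of
#' the right length.
#'
#' @param ds an [expression_dataset()].
#' @return Character vector of violation messages; empty when `ds` is valid.
#' @export
validate_dataset <- function(ds) {
  issues <- character()
  v <- ds$values
  if (!is.matrix(v) || !is.numeric(v)) {
    return("values must be a numeric matrix")
  }
  if (anyNA(v)) issues <- c(issues, "values contain missing entries")
  if (length(ds$labels) != nrow(v)) {
    issues <- c(issues, "label length does not match the number of instances")
  }
  lev <- levels(droplevels(factor(ds$labels)))
  if (length(lev) != 2L) {
    issues <- c(issues, sprintf("expected 2 label classes, found %d", length(lev)))
  } else {
    counts <- table(factor(ds$labels))
    small <- names(counts)[counts < 2L]
    for (cl in small) {
      issues <- c(issues, sprintf("class '%s' has fewer than 2 instances", cl))
    }
  }
  fid <- colnames(v)
  iid <- rownames(v)
  dup <- unique(fid[duplicated(fid)])
  if (length(dup)) {
    issues <- c(issues, sprintf("duplicate feature_ids: %s", paste(dup, collapse = ", ")))
  }
  dup <- unique(iid[duplicated(iid)])
  if (length(dup)) {
    issues <- c(issues, sprintf("duplicate instance_ids: %s", paste(dup, collapse = ", ")))
  }
  issues
}

# replace NA cells by the feature (column) mean over non-missing entries;
# a feature with no observed value at all is an error
impute_feature_means <- function(values) {
  nas <- which(colSums(is.na(values)) > 0L)
  for (j in nas) {
    x <- values[, j]
    obs <- !is.na(x)
    if (!any(obs)) {
      stop("feature '", colnames(values)[j], "' has no observed values")
    }
    values[!obs, j] <- mean(x[obs])
  }
  values
}

#' Read an expression dataset from delimited text
#'
#' Reads a CSV/TSV expression matrix with one header line.  Both shipping
#' orientations are supported and must be named explicitly -- silent
#' transposition is the classic microarray bug, so nothing is guessed:
#'
#' * `orientation = "instances"`: instances in rows; the first column holds
#'   instance ids and `label` names the column carrying the class label.
#' * `orientation = "features"`: features in rows; the first column holds
#'   feature ids, remaining columns are instances, and `label` names the row
#'   (by its id in the first column) carrying the class label.
#'
#' Missing cells (empty string or `NA`) are imputed with the feature mean
#' over the non-missing entries.
#'
#' @param path file path.
#' @param orientation `"instances"` or `"features"` (see above).
#' @param label name of the label column (instances-in-rows) or label row id
#'   (features-in-rows).
#' @param sep field separator; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(path, orientation = c("instances", "features"),
                         label, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      na.strings = c("", "NA"), check.names = FALSE,
                      colClasses = "character", comment.char = ""),
    error = function(e) stop("parse error in '", path, "': ", conditionMessage(e))
  )
  if (ncol(tab) < 2L) stop("parse error in '", path, "': fewer than 2 columns")

  ids <- as.character(tab[[1L]])
  body <- tab[, -1L, drop = FALSE]

  if (orientation == "instances") {
    if (!label %in% colnames(body)) {
      stop("label column '", label, "' not found in '", path, "'")
    }
    labels <- as.character(body[[label]])
    feat <- body[, setdiff(colnames(body), label), drop = FALSE]
    values <- as_numeric_matrix(feat, path)
    rownames(values) <- ids
    expression_dataset(values, labels, impute = TRUE)
  } else {
    if (!label %in% ids) {
      stop("label row '", label, "' not found in '", path, "'")
    }
    lab_row <- which(ids == label)[1L]
    labels <- as.character(unlist(body[lab_row, ], use.names = FALSE))
    feat <- body[-lab_row, , drop = FALSE]
    values <- t(as_numeric_matrix(feat, path))
    colnames(values) <- ids[-lab_row]
    rownames(values) <- colnames(body)
    expression_dataset(values, labels, impute = TRUE)
  }
}

as_numeric_matrix <- function(df, path) {
  m <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    x <- df[[j]]
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      stop("parse error in '", path, "': non-numeric value '", x[which(bad)[1L]],
           "' at data line ", which(bad)[1L])
    }
    m[, j] <- suppressWarnings(as.numeric(x))
  }
  m
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [load_dataset()]; values are written with full double
#' precision (17 significant digits) so a load/write/load cycle
#' round-trips.
#'
#' @inheritParams load_dataset
#' @param ds an [expression_dataset()].
#' @export
write_dataset <- function(ds, path, orientation = c("instances", "features"),
                          label = "class", sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  v <- ds$values
  if (orientation == "instances") {
    out <- data.frame(id = rownames(v),
                      stats::setNames(as.data.frame(apply(v, 2, fmt)), colnames(v)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[[label]] <- as.character(ds$labels)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    tv <- t(v)
    out <- data.frame(id = c(label, rownames(tv)),
                      rbind(as.character(ds$labels), apply(tv, 2, fmt)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- c("id", rownames(v))
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.expression_dataset <- function(x, ...) {
  counts <- table(x$labels)
  cat(sprintf("Expression dataset: %d instances x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  classes: %s (positive class: '%s')\n",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
              x$positive))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)
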