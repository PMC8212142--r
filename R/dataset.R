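#' Labeled dataset container
#'
#' Bundles a samples-by-features numeric matrix with integer class labels
#' `1..K`. Features are assumed (not forced) to be standardized; the
#' evaluation pipeline takes care of train-fitted z-scoring. The last class in
#' `class_names` is the pivot class of the softmax parameterization: only the
#' first `K - 1` classes carry weight vectors, so relabeling changes the
#' encoding.
#'
#' @param features numeric matrix, N x M, finite entries.
#' @param labels integer vector of length N with values in `1..n_classes`,
#'   or a factor (levels define `class_names`).
#' @param n_classes number of classes K >= 2; defaults to `max(labels)` or the
#'   number of factor levels.
#' @param class_names character vector of length K.
#' @param require_all_classes error if a class in `1..K` has no samples
#'   (default `TRUE`). Degenerate datasets with absent classes are still
#'   encodable (the class simply contributes no `b_k` mass), so single-point
#'   fixtures may disable the check.
#' @return An object of class `labeled_dataset` with fields `features`,
#'   `labels`, `n_classes`, `class_names`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(1:2, 5))
#' d$n_classes
#' @export
labeled_dataset <- function(features, labels, n_classes = NULL,
                            class_names = NULL,
                            require_all_classes = TRUE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(labels)
  }
  labels <- as.integer(labels)
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("features must have at least one row and one column", call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("features contain non-finite entries", call. = FALSE)
  }
  if (length(labels) != nrow(features)) {
    stop("length(labels) must equal nrow(features)", call. = FALSE)
  }
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(class_names)) length(class_names) else
      max(labels)
  }
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least two classes (K >= 2)", call. = FALSE)
  if (any(labels < 1L | labels > n_classes)) {
    stop("labels must lie in 1..n_classes", call. = FALSE)
  }
  missing_cls <- setdiff(seq_len(n_classes), unique(labels))
  if (isTRUE(require_all_classes) && length(missing_cls) > 0L) {
    stop("every class must occur at least once; missing: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  if (length(class_names) != n_classes) {
    stop("class_names must have length n_classes", call. = FALSE)
  }
  structure(
    list(features = features, labels = labels, n_classes = n_classes,
         class_names = as.character(class_names)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, K = %d\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  tab <- table(factor(x$labels, levels = seq_len(x$n_classes),
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Subset a labeled dataset by sample index
#'
#' Keeps `n_classes`/`class_names` fixed even if a class drops out of the
#' subset (callers such as cross-validation rely on stable class indexing);
#' validity of the subset for encoding is re-checked at encode time.
#'
#' @param dataset a `labeled_dataset`.
#' @param idx integer sample indices.
#' @return A list with the same fields as `labeled_dataset` (unvalidated
#'   subset; class `labeled_dataset`).
#' @export
dataset_subset <- function(dataset, idx) {
  structure(
    list(features = dataset$features[idx, , drop = FALSE],
         labels = dataset$labels[idx],
         n_classes = dataset$n_classes,
         class_names = dataset$class_names),
    class = "labeled_dataset"
  )
}

# Deterministic sub-seed derivation: every random draw in a multi-stage run
# descends from one master seed through (stream, index) pairs. LCG-style
# mixing, kept below 2^31 so it is a valid R seed on all platforms.
derive_seed <- function(master, stream, index = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + 12345 + 1000003 * as.numeric(stream)) %% m
  x <- (x * 48271 + 7919 * as.numeric(index)) %% m
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

round_half_up <- function(x) floor(x + 0.5)
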