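#' Stratified train/test split plan
#'
#' Repeatedly splits samples into train/test without replacement, stratified
#' by class: per class, `round_half_up(train_fraction * class_size)` samples
#' go to train, the rest to test. Deterministic given `seed`.
#'
#' @param labels integer class labels.
#' @param n_splits number of independent splits (default 100).
#' @param train_fraction fraction of each class assigned to train
#'   (default 0.8).
#' @param seed integer seed.
#' @return A `split_plan`: list with `train` and `test` (lists of index
#'   vectors), `n_splits`, `train_fraction`, `seed`.
#' @export
make_splits <- function(labels, n_splits = 100L, train_fraction = 0.8,
                        seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  classes <- as.integer(names(tab))
  train <- vector("list", n_splits)
  test <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    tr <- integer(0)
    with_seed(derive_seed(seed, 400L, s), {
      for (cls in classes) {
        idx <- which(labels == cls)
        n_tr <- round_half_up(train_fraction * length(idx))
        n_tr <- max(1L, min(length(idx) - 1L, n_tr))
        tr <- c(tr, sample(idx, n_tr))
      }
    })
    train[[s]] <- sort(tr)
    test[[s]] <- setdiff(seq_along(labels), tr)
  }
  structure(list(train = train, test = test, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Train-fitted z-scoring applied to train and test
#'
#' Column means and standard deviations (denominator `N - 1`) are computed on
#' the training rows only and applied to both matrices; columns constant in
#' train become all-zero in both. No test statistic enters the fit.
#'
#' @param train_X,test_X numeric matrices with matching columns.
#' @return List with `train_Z`, `test_Z`, `means`, `sds`.
#' @export
zscore_fit_apply <- function(train_X, test_X) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  means <- colMeans(train_X)
  sds <- apply(train_X, 2L, stats::sd)
  safe <- ifelse(sds > 0, sds, 1)
  train_Z <- sweep(sweep(train_X, 2L, means), 2L, safe, "/")
  test_Z <- sweep(sweep(test_X, 2L, means), 2L, safe, "/")
  zero_cols <- which(sds == 0)
  if (length(zero_cols) > 0L) {
    train_Z[, zero_cols] <- 0
    test_Z[, zero_cols] <- 0
  }
  list(train_Z = train_Z, test_Z = test_Z, means = means, sds = sds)
}

#' Train-fitted PCA with test projection
#'
#' Loadings come from the singular value decomposition of the (re-)centered
#' training matrix, ordered by decreasing variance; the sign of each
#' component is fixed so its largest-magnitude loading is positive. Test rows
#' are centered with the training means and projected with the training
#' loadings — the test set never enters the fit.
#'
#' @param train_Z,test_Z numeric matrices with matching columns (typically
#'   the output of [zscore_fit_apply()]).
#' @param n_components number of components, at most `min(N_train, M)`.
#' @return List with `train_PCs`, `test_PCs`, `loadings` (M x n_components),
#'   `explained_variance`, `center`.
#' @export
pca_fit_project <- function(train_Z, test_Z, n_components) {
  train_Z <- as.matrix(train_Z); test_Z <- as.matrix(test_Z)
  n_components <- as.integer(n_components)
  if (n_components > min(nrow(train_Z), ncol(train_Z))) {
    stop(sprintf("n_components (%d) exceeds min(N_train, M) = %d",
                 n_components, min(nrow(train_Z), ncol(train_Z))),
         call. = FALSE)
  }
  center <- colMeans(train_Z)
  Xc <- sweep(train_Z, 2L, center)
  sv <- svd(Xc, nu = 0, nv = n_components)
  V <- sv$v
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(train_PCs = Xc %*% V,
       test_PCs = sweep(test_Z, 2L, center) %*% V,
       loadings = V,
       explained_variance = sv$d[seq_len(n_components)]^2 /
         (nrow(train_Z) - 1),
       center = center)
}

#' Stratified subsamples of a training set
#'
#' For training-fraction sweeps: draws `n_replicates` class-balanced
#' subsamples of the given training indices, each keeping
#' `round_half_up(fraction * class_size)` samples per class, without
#' replacement. The test set is untouched by construction.
#'
#' @param train_indices integer indices of the full training set.
#' @param labels class labels for all samples (indexed by `train_indices`).
#' @param fraction fraction in (0, 1] of each class to keep.
#' @param n_replicates number of independent subsamples (default 50).
#' @param seed integer seed.
#' @return List of `n_replicates` index vectors (subsets of
#'   `train_indices`).
#' @export
subsample_training <- function(train_indices, labels, fraction,
                               n_replicates = 50L, seed = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  lab <- labels[train_indices]
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    keep <- integer(0)
    with_seed(derive_seed(seed, 500L, r), {
      for (cls in sort(unique(lab))) {
        idx <- train_indices[lab == cls]
        n_keep <- round_half_up(fraction * length(idx))
        if (n_keep < 1L) {
          stop(sprintf("fraction %.3g empties class %s", fraction, cls),
               call. = FALSE)
        }
        keep <- c(keep, sample(idx, n_keep))
      }
    })
    out[[r]] <- sort(keep)
  }
  out
}

balanced_accuracy <- function(y_true, y_pred, n_classes = max(y_true)) {
  recalls <- vapply(seq_len(n_classes), function(k) {
    n_k <- sum(y_true == k)
    if (n_k == 0L) return(NA_real_)
    sum(y_pred == k & y_true == k) / n_k
  }, numeric(1L))
  if (anyNA(recalls)) {
    warning("class absent from y_true; its recall excluded", call. = FALSE)
  }
  mean(recalls, na.rm = TRUE)
}

# Mann-Whitney AUC with mid-rank tie handling; p = score of the positive
# class.
binary_auc <- function(truth_pos, p) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(y_true, y_pred, positive) {
  tp <- sum(y_pred == positive & y_true == positive)
  fp <- sum(y_pred == positive & y_true != positive)
  fn <- sum(y_pred != positive & y_true == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Classification metrics
#'
#' Computes accuracy, balanced accuracy (unweighted mean of per-class
#' recall), ROC AUC, and F1. For two classes, AUC uses the probability of the
#' positive class and F1 is the positive-class F1, the positive class being
#' class 2 (the second listed); for K > 2 both are macro-averaged
#' one-vs-rest.
#'
#' @param y_true integer labels `1..K`.
#' @param y_pred predicted labels.
#' @param y_proba N x K probability matrix (rows sum to 1); required for AUC.
#' @param n_classes K (default: max of `y_true`).
#' @return Named list: `accuracy`, `balanced_accuracy`, `auc`, `f1`.
#' @export
compute_metrics <- function(y_true, y_pred, y_proba = NULL,
                            n_classes = max(y_true)) {
  stopifnot(length(y_true) == length(y_pred))
  acc <- mean(y_true == y_pred)
  bal <- balanced_accuracy(y_true, y_pred, n_classes)
  if (n_classes == 2L) {
    auc <- if (is.null(y_proba)) NA_real_ else
      binary_auc(y_true == 2L, y_proba[, 2L])
    f1 <- f1_score(y_true, y_pred, positive = 2L)
  } else {
    auc <- if (is.null(y_proba)) NA_real_ else
      mean(vapply(seq_len(n_classes), function(k)
        binary_auc(y_true == k, y_proba[, k]), numeric(1L)), na.rm = TRUE)
    f1 <- mean(vapply(seq_len(n_classes), function(k)
      f1_score(y_true, y_pred, positive = k), numeric(1L)))
  }
  list(accuracy = acc, balanced_accuracy = bal, auc = auc, f1 = f1)
}

#' Paired classifier comparison with Wilcoxon signed-rank tests
#'
#' Two-sided Wilcoxon signed-rank tests on per-split metric values for every
#' classifier pair, Bonferroni-corrected by the number of pairs within each
#' metric, corrected p capped at 1. Identical vectors (all differences zero)
#' report p = 1.
#'
#' @param report a tidy data frame with columns `classifier`, `split`,
#'   `metric`, `value` (as produced by [run_experiment()]), or an
#'   `evaluation_report`.
#' @return Data frame with columns `metric`, `classifier_a`, `classifier_b`,
#'   `p_raw`, `p_bonferroni`.
#' @export
compare_classifiers <- function(report) {
  if (inherits(report, "evaluation_report")) report <- report$per_split
  classifiers <- sort(unique(report$classifier))
  if (length(classifiers) < 2L) {
    stop("need at least two classifiers", call. = FALSE)
  }
  metrics <- unique(report$metric)
  pairs <- utils::combn(classifiers, 2L)
  n_pairs <- ncol(pairs)
  out <- do.call(rbind, lapply(metrics, function(m) {
    sub <- report[report$metric == m, ]
    do.call(rbind, lapply(seq_len(n_pairs), function(p) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      xa <- sub$value[sub$classifier == a][order(sub$split[
        sub$classifier == a])]
      xb <- sub$value[sub$classifier == b][order(sub$split[
        sub$classifier == b])]
      stopifnot(length(xa) == length(xb))
      d <- xa - xb
      p_raw <- if (all(d == 0)) 1 else
        suppressWarnings(stats::wilcox.test(xa, xb, paired = TRUE)$p.value)
      data.frame(metric = m, classifier_a = a, classifier_b = b,
                 p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_pairs),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Train-minus-test overfitting gap
#'
#' @param train_metrics,test_metrics numeric vectors of a per-split metric
#'   (typically balanced accuracy), paired by split.
#' @return List with `gap` (per split), `mean`, `sem`.
#' @export
overfitting_gap <- function(train_metrics, test_metrics) {
  stopifnot(length(train_metrics) == length(test_metrics))
  gap <- train_metrics - test_metrics
  list(gap = gap, mean = mean(gap),
       sem = stats::sd(gap) / sqrt(length(gap)))
}

#' Feature importance from trained Ising models
#'
#' Per feature, the mean of the absolute averaged weight across models (and
#' across the K - 1 class blocks for multiclass), ranked descending with ties
#' broken by feature index. Not defined for RBMs, which are excluded by
#' construction (only weight-matrix models are accepted).
#'
#' @param models a `trained_ising_model` or list of them (e.g. one per
#'   split).
#' @return Data frame with `feature`, `importance`, `rank`, ordered by rank.
#' @export
feature_importance <- function(models) {
  if (inherits(models, "trained_ising_model")) models <- list(models)
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  imp <- rowMeans(vapply(models, function(m) colMeans(abs(
    unclass(m$weights))), numeric(ncol(models[[1L]]$weights))))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = ord, importance = imp[ord],
             rank = seq_along(imp))
}

#' Top features by absolute loading on one component
#'
#' @param loadings M x C loadings matrix (or length-M vector).
#' @param component component index (default 1).
#' @param k number of features to keep (default 44).
#' @return Integer indices of the k largest `|loading|`, descending, ties
#'   broken by feature index.
#' @export
select_top_loading_features <- function(loadings, component = 1L, k = 44L) {
  if (is.matrix(loadings)) loadings <- loadings[, component]
  if (k > length(loadings)) stop("k exceeds the number of features",
                                 call. = FALSE)
  ord <- order(-abs(loadings), seq_along(loadings))
  ord[seq_len(k)]
}
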