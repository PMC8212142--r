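#' Read a feature matrix from CSV/TSV
#'
#' First row is a header of feature names, first column holds sample IDs.
#' The delimiter is auto-detected from the extension (`.tsv`/`.tab` = tab,
#' anything else = comma). Non-numeric cells and duplicate sample IDs are
#' rejected with coordinates in the message.
#'
#' @param path file path.
#' @return Numeric matrix with row names (sample IDs) and column names
#'   (feature names).
#' @export
read_feature_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  X <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | vals[[j]] == "")
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                   ids[bad[1L]], colnames(vals)[j]), call. = FALSE)
    }
    X[, j] <- v
  }
  X
}

#' Write a feature matrix as CSV/TSV
#'
#' Inverse of [read_feature_matrix()] (bitwise round trip for finite
#' doubles: values are printed with 17 significant digits).
#'
#' @param X numeric matrix with row and column names.
#' @param path output path; extension selects the delimiter.
#' @param id_col name of the sample-ID column (default `"sample_id"`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, id_col = "sample_id") {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(rownames(X),
                   apply(X, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(X))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write per-sample class labels
#'
#' Two-column CSV `sample_id,class`.
#'
#' @param path file path.
#' @return `read_labels`: data frame with `sample_id` (character) and
#'   `class` (character).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("labels file needs sample_id,class columns",
                          call. = FALSE)
  data.frame(sample_id = df[[1L]], class = df[[2L]],
             stringsAsFactors = FALSE)
}

#' @rdname read_labels
#' @param labels character or integer class per sample.
#' @param sample_ids character sample IDs.
#' @export
write_labels <- function(labels, sample_ids, path) {
  utils::write.csv(data.frame(sample_id = sample_ids, class = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Validates and fills defaults for [run_experiment()]. All defaults mirror
#' the reference protocol: 1,000 reads, 1,000 sweeps, initial inverse
#' temperature 0.01, final-inverse-temperature grid `{0.03,0.1,0.3,1,3}`,
#' top-20 ensemble averaging, 100 stratified 80/20 splits, 10
#' cross-validation folds. Serializable to JSON via `jsonlite`.
#'
#' @param classifiers character vector among `"sa"`, `"random"`, `"field"`,
#'   `"rbm"`, `"logistic"`, `"lasso"`, `"ridge"`.
#' @param n_splits number of train/test resplits.
#' @param train_fraction train share per split.
#' @param n_pcs principal components retained (`NULL` = no PCA).
#' @param n_reads,n_sweeps,beta_initial,beta_grid,n_keep solver settings.
#' @param cv_folds hyperparameter-tuning folds.
#' @param rbm_hidden,rbm_epochs,rbm_learning_rate RBM settings.
#' @param seed master seed (mandatory).
#' @param output_dir where [run_experiment()] writes artifacts (`NULL` =
#'   nothing written).
#' @return A `run_config` list.
#' @export
run_config <- function(classifiers = c("sa", "random", "field"),
                       n_splits = 100L, train_fraction = 0.8, n_pcs = NULL,
                       n_reads = 1000L, n_sweeps = 1000L,
                       beta_initial = 0.01, beta_grid = beta_final_grid(),
                       n_keep = 20L, cv_folds = 10L, rbm_hidden = 64L,
                       rbm_epochs = 100L, rbm_learning_rate = 0.1,
                       seed, output_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  known <- c("sa", "random", "field", "rbm", "logistic", "lasso", "ridge")
  bad <- setdiff(classifiers, known)
  if (length(bad) > 0L) {
    stop("unknown classifiers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(classifiers = classifiers,
                 n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 n_pcs = if (is.null(n_pcs)) NULL else as.integer(n_pcs),
                 n_reads = as.integer(n_reads),
                 n_sweeps = as.integer(n_sweeps),
                 beta_initial = beta_initial, beta_grid = beta_grid,
                 n_keep = as.integer(n_keep),
                 cv_folds = as.integer(cv_folds),
                 rbm_hidden = as.integer(rbm_hidden),
                 rbm_epochs = as.integer(rbm_epochs),
                 rbm_learning_rate = rbm_learning_rate,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

# Fit one classifier on a prepared (already transformed) training set and
# score train and test. Returns list(train = metrics, test = metrics,
# model = model or NULL).
fit_and_score <- function(clf, train_ds, test_X, test_y, config, seed) {
  K <- train_ds$n_classes
  if (clf %in% c("sa", "random", "field")) {
    model <- fit_ising(train_ds, solver = clf, seed = seed,
                       n_reads = config$n_reads, n_sweeps = config$n_sweeps,
                       beta_initial = config$beta_initial,
                       beta_grid = config$beta_grid, n_keep = config$n_keep,
                       cv_folds = config$cv_folds)
    pr_tr <- class_probabilities(model$weights, train_ds$features)
    pr_te <- class_probabilities(model$weights, test_X)
  } else if (clf == "rbm") {
    model <- rbm_train(train_ds, n_hidden = config$rbm_hidden,
                       learning_rate = config$rbm_learning_rate,
                       n_epochs = config$rbm_epochs, seed = seed)
    pr_tr <- rbm_predict_proba(model, train_ds$features)
    pr_te <- rbm_predict_proba(model, test_X)
  } else {
    model <- fit_baseline(train_ds, method = clf, seed = seed)
    pr_tr <- predict(model, train_ds$features, type = "prob")
    pr_te <- predict(model, test_X, type = "prob")
  }
  yhat_tr <- apply(pr_tr, 1L, which.max)
  yhat_te <- apply(pr_te, 1L, which.max)
  list(train = compute_metrics(train_ds$labels, yhat_tr, pr_tr,
                               n_classes = K),
       test = compute_metrics(test_y, yhat_te, pr_te, n_classes = K),
       model = model)
}

#' Run the full evaluation protocol
#'
#' For each stratified split: z-score fit on train and applied to test,
#' optional train-fitted PCA with test projection, then every requested
#' classifier is fitted on the transformed training data and scored on both
#' splits. Produces a tidy per-(classifier, split, metric) table, a
#' mean-plus/minus-SEM summary, pairwise Wilcoxon/Bonferroni comparisons,
#' per-classifier overfitting gaps, and (when `output_dir` is set) report
#' CSVs, model JSONs and a log of every seed and hyperparameter. Rerunning
#' with an identical config reproduces identical outputs.
#'
#' @param dataset a `labeled_dataset` (untransformed).
#' @param config a [run_config()].
#' @return An `evaluation_report`: list with `per_split` (tidy data frame,
#'   train and test metrics), `summary`, `comparisons`, `gaps`, `models`
#'   (Ising models per classifier per split), `config`.
#' @export
run_experiment <- function(dataset, config) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "run_config"))
  if (!is.null(config$n_pcs)) {
    n_train_min <- min(vapply(
      make_splits(dataset$labels, config$n_splits, config$train_fraction,
                  config$seed)$train, length, integer(1L)))
    if (config$n_pcs > min(n_train_min, ncol(dataset$features))) {
      stop(sprintf("n_pcs (%d) exceeds the rank bound min(N_train, M) = %d",
                   config$n_pcs,
                   min(n_train_min, ncol(dataset$features))),
           call. = FALSE)
    }
  }
  plan <- make_splits(dataset$labels, config$n_splits,
                      config$train_fraction, config$seed)
  rows <- list()
  models <- list()
  for (s in seq_len(config$n_splits)) {
    tr_idx <- plan$train[[s]]; te_idx <- plan$test[[s]]
    z <- zscore_fit_apply(dataset$features[tr_idx, , drop = FALSE],
                          dataset$features[te_idx, , drop = FALSE])
    tr_X <- z$train_Z; te_X <- z$test_Z
    if (!is.null(config$n_pcs)) {
      pc <- pca_fit_project(tr_X, te_X, config$n_pcs)
      tr_X <- pc$train_PCs; te_X <- pc$test_PCs
    }
    tr_ds <- labeled_dataset(tr_X, dataset$labels[tr_idx],
                             dataset$n_classes, dataset$class_names)
    for (clf in config$classifiers) {
      res <- fit_and_score(clf, tr_ds, te_X, dataset$labels[te_idx],
                           config, derive_seed(config$seed, 600L, s))
      for (m in names(res$test)) {
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = clf, split = s, metric = m,
          value = res$test[[m]], train_value = res$train[[m]],
          stringsAsFactors = FALSE)
      }
      if (inherits(res$model, "trained_ising_model")) {
        models[[clf]] <- c(models[[clf]], list(res$model))
      }
    }
  }
  per_split <- do.call(rbind, rows)
  summary_df <- stats::aggregate(value ~ classifier + metric, per_split,
                                 function(v) c(mean = mean(v),
                                               sem = stats::sd(v) /
                                                 sqrt(length(v))))
  summary_df <- do.call(data.frame,
                        c(summary_df[c("classifier", "metric")],
                          list(mean = summary_df$value[, "mean"],
                               sem = summary_df$value[, "sem"])))
  comparisons <- if (length(config$classifiers) >= 2L)
    compare_classifiers(per_split) else NULL
  bal <- per_split[per_split$metric == "balanced_accuracy", ]
  gaps <- do.call(rbind, lapply(split(bal, bal$classifier), function(d) {
    g <- overfitting_gap(d$train_value, d$value)
    data.frame(classifier = d$classifier[1L], gap_mean = g$mean,
               gap_sem = g$sem, stringsAsFactors = FALSE)
  }))
  rownames(gaps) <- NULL
  report <- structure(
    list(per_split = per_split, summary = summary_df,
         comparisons = comparisons, gaps = gaps, models = models,
         config = config),
    class = "evaluation_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d classifiers x %d splits\n",
              length(x$config$classifiers), x$config$n_splits))
  bal <- x$summary[x$summary$metric == "balanced_accuracy", ]
  bal <- bal[order(-bal$mean), ]
  for (i in seq_len(nrow(bal))) {
    cat(sprintf("  %-10s balanced accuracy %.3f +/- %.3f\n",
                bal$classifier[i], bal$mean[i], bal$sem[i]))
  }
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_split, file.path(dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(report$gaps, file.path(dir, "overfitting_gaps.csv"),
                   row.names = FALSE, quote = FALSE)
  for (clf in names(report$models)) {
    for (s in seq_along(report$models[[clf]])) {
      save_ising_model(report$models[[clf]][[s]],
                       file.path(dir, sprintf("model_%s_split%03d.json",
                                              clf, s)))
    }
  }
  cfg <- report$config
  cfg$output_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Training-fraction sweep with a fixed held-out test set
#'
#' One stratified train/test split is drawn once; for each requested
#' fraction, `n_replicates` class-balanced subsamples of the training set
#' are drawn, every classifier is fitted on each subsample (z-scoring and
#' optional PCA re-fitted per subsample), and scored on the untouched test
#' set.
#'
#' @param dataset a `labeled_dataset`.
#' @param config a [run_config()] (`n_splits` is ignored here).
#' @param fractions numeric vector of training fractions in (0, 1].
#' @param n_replicates subsamples per fraction (default 50).
#' @return Tidy data frame: `classifier`, `fraction`, `replicate`, `metric`,
#'   `value` (test), `train_value`.
#' @export
sweep_training_size <- function(dataset, config, fractions,
                                n_replicates = 50L) {
  plan <- make_splits(dataset$labels, 1L, config$train_fraction,
                      config$seed)
  tr_idx <- plan$train[[1L]]; te_idx <- plan$test[[1L]]
  rows <- list()
  for (f in seq_along(fractions)) {
    subs <- subsample_training(tr_idx, dataset$labels, fractions[f],
                               n_replicates,
                               derive_seed(config$seed, 700L, f))
    for (r in seq_along(subs)) {
      z <- zscore_fit_apply(dataset$features[subs[[r]], , drop = FALSE],
                            dataset$features[te_idx, , drop = FALSE])
      tr_X <- z$train_Z; te_X <- z$test_Z
      if (!is.null(config$n_pcs)) {
        pc <- pca_fit_project(tr_X, te_X, config$n_pcs)
        tr_X <- pc$train_PCs; te_X <- pc$test_PCs
      }
      tr_ds <- labeled_dataset(tr_X, dataset$labels[subs[[r]]],
                               dataset$n_classes, dataset$class_names)
      for (clf in config$classifiers) {
        res <- fit_and_score(clf, tr_ds, te_X, dataset$labels[te_idx],
                             config,
                             derive_seed(config$seed, 800L + f, r))
        for (m in names(res$test)) {
          rows[[length(rows) + 1L]] <- data.frame(
            classifier = clf, fraction = fractions[f], replicate = r,
            metric = m, value = res$test[[m]],
            train_value = res$train[[m]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
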