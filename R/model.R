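#' Softmax class probabilities from a weight matrix
#'
#' With `K - 1` weight vectors `w_k` (rows of `weights`) and the K-th class as
#' pivot: `Pr(k) = exp(w_k' x) / (1 + sum_k' exp(w_k' x))` for `k < K` and
#' `Pr(K) = 1 / (1 + sum_k' exp(w_k' x))`. Computed with the max-subtraction
#' trick, so probabilities are finite, strictly positive, and sum to one for
#' any finite scores.
#'
#' @param weights a `(K - 1) x M` weight matrix.
#' @param x length-M numeric vector, or an N x M matrix of rows.
#' @return A length-K probability vector, or an N x K matrix if `x` is a
#'   matrix.
#' @examples
#' class_probabilities(matrix(1, 1, 1), 1)  # c(0.731..., 0.268...)
#' @export
class_probabilities <- function(weights, x) {
  W <- as.matrix(weights)
  if (is.matrix(x)) {
    if (ncol(x) != ncol(W)) stop("dimension mismatch", call. = FALSE)
    scores <- cbind(x %*% t(W), 0)         # N x K, pivot column zero
  } else {
    if (length(x) != ncol(W)) stop("dimension mismatch", call. = FALSE)
    scores <- matrix(c(W %*% x, 0), nrow = 1L)
  }
  mx <- apply(scores, 1L, max)
  ex <- exp(scores - mx)
  P <- ex / rowSums(ex)
  if (!is.matrix(x)) as.numeric(P) else P
}

# Negative log likelihood from an explicit probability table.
# P: N x K matrix of class probabilities; y: labels 1..K.
# A zero probability for an observed class yields +Inf, not an error.
#' Negative log likelihood from a probability table
#'
#' `-sum_i log P[i, y_i]` in nats. Returns `Inf` (not an error) when an
#' observed class has probability zero; returns exactly 0 when every observed
#' class has probability 1.
#'
#' @param P N x K probability matrix (rows sum to 1).
#' @param y integer labels in `1..K`.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
nll_from_prob <- function(P, y) {
  P <- as.matrix(P)
  if (nrow(P) != length(y)) stop("dimension mismatch", call. = FALSE)
  p_true <- P[cbind(seq_along(y), y)]
  0 - sum(log(p_true))   # 0 - x avoids signed zero for a perfect model
}

#' Negative log likelihood of a dataset under softmax weights
#'
#' @param weights a `(K - 1) x M` weight matrix.
#' @param dataset a `labeled_dataset` with matching M and K.
#' @return Non-negative scalar in nats (`Inf` if an observed class has
#'   probability zero).
#' @export
negative_log_likelihood <- function(weights, dataset) {
  P <- class_probabilities(weights, dataset$features)
  nll_from_prob(P, dataset$labels)
}

#' Average a low-energy spin ensemble into classifier weights
#'
#' Deduplicates the solver's configurations, keeps the `n_keep` lowest-energy
#' ones, and then greedily builds an averaging set: starting from the single
#' lowest-energy configuration, each next configuration (ascending energy) is
#' added iff the element-wise mean of the enlarged set strictly lowers the
#' exact negative log likelihood on the training data. The objective for this
#' test is the exact likelihood, not the quadratic Ising surrogate: low
#' surrogate energy does not imply the best classification, which is why
#' higher-energy reads can still help.
#'
#' @param result a `solver_result`.
#' @param dataset the training `labeled_dataset`.
#' @param n_keep ensemble size cap (default 20).
#' @return A `trained_ising_model` with fields `weights` (entries in
#'   `[-1, 1]`), `solver_name`, `beta_final_selected`, `n_averaged`,
#'   `training_nll`, `class_names`.
#' @export
postprocess_average <- function(result, dataset, n_keep = 20L) {
  if (length(result$energies) == 0L) stop("empty solver result",
                                          call. = FALSE)
  M <- ncol(dataset$features)
  K <- dataset$n_classes
  S <- result$configurations
  keep <- !duplicated(S)
  S <- S[keep, , drop = FALSE]
  S <- S[seq_len(min(nrow(S), n_keep)), , drop = FALSE]

  acc_sum <- S[1L, ]
  n_acc <- 1L
  best_nll <- negative_log_likelihood(spins_to_weights(acc_sum, M, K),
                                      dataset)
  if (nrow(S) > 1L) {
    for (r in 2L:nrow(S)) {
      cand_sum <- acc_sum + S[r, ]
      cand_nll <- negative_log_likelihood(
        spins_to_weights(cand_sum / (n_acc + 1L), M, K), dataset)
      if (cand_nll < best_nll) {
        acc_sum <- cand_sum
        n_acc <- n_acc + 1L
        best_nll <- cand_nll
      }
    }
  }
  new_trained_ising_model(
    weights = spins_to_weights(acc_sum / n_acc, M, K),
    solver_name = result$solver_name, beta_final_selected = NULL,
    n_averaged = n_acc, training_nll = best_nll,
    class_names = dataset$class_names)
}

new_trained_ising_model <- function(weights, solver_name,
                                    beta_final_selected, n_averaged,
                                    training_nll, class_names) {
  structure(
    list(weights = weights, solver_name = solver_name,
         beta_final_selected = beta_final_selected,
         n_averaged = as.integer(n_averaged), training_nll = training_nll,
         class_names = class_names),
    class = "trained_ising_model"
  )
}

#' @export
print.trained_ising_model <- function(x, ...) {
  cat(sprintf(
    "<trained_ising_model> solver = %s, %d configuration(s) averaged,\n",
    x$solver_name, x$n_averaged))
  cat(sprintf("  training NLL = %.4f%s\n", x$training_nll,
              if (!is.null(x$beta_final_selected))
                sprintf(", beta_final = %g", x$beta_final_selected) else ""))
  invisible(x)
}

#' Predict class labels from softmax weights
#'
#' Argmax of [class_probabilities()] per row; ties break toward the lowest
#' class index.
#'
#' @param weights a `(K - 1) x M` weight matrix.
#' @param X N x M feature matrix (or a single length-M vector).
#' @return Integer labels in `1..K`.
#' @export
predict_labels <- function(weights, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  P <- class_probabilities(weights, X)
  apply(P, 1L, which.max)   # which.max takes the first maximum: lowest index
}

#' @export
predict.trained_ising_model <- function(object, newdata,
                                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (type == "prob") class_probabilities(object$weights, newdata)
  else predict_labels(object$weights, newdata)
}

#' Fit an Ising classifier
#'
#' Pipeline: encode the training data, rescale coefficients to `[-1, 1]`,
#' produce a low-energy spin ensemble with the chosen solver, and average the
#' ensemble with [postprocess_average()]. For the SA solver the final inverse
#' temperature is tuned by stratified k-fold cross-validation on the training
#' data (scoring mean validation balanced accuracy; ties go to the smaller
#' `beta_final`). Field has no hyperparameters and no randomness; Random and
#' SA are deterministic given `seed`.
#'
#' @param dataset training `labeled_dataset`.
#' @param solver one of `"sa"`, `"random"`, `"field"`.
#' @param seed integer master seed (required for `"sa"` and `"random"`).
#' @param n_reads reads per solve (default 1000).
#' @param n_sweeps SA sweeps (default 1000).
#' @param beta_initial SA initial inverse temperature (default 0.01).
#' @param beta_grid SA candidate final inverse temperatures (default
#'   [beta_final_grid()]); a length-1 grid skips cross-validation.
#' @param n_keep ensemble size for postprocessing (default 20).
#' @param cv_folds cross-validation folds (default 10); reduced with a
#'   warning when the smallest class has fewer members.
#' @param intercept append a constant-1 feature before encoding.
#' @return A `trained_ising_model`.
#' @export
fit_ising <- function(dataset, solver = c("sa", "random", "field"),
                      seed = 1L, n_reads = 1000L, n_sweeps = 1000L,
                      beta_initial = 0.01, beta_grid = beta_final_grid(),
                      n_keep = 20L, cv_folds = 10L, intercept = FALSE) {
  solver <- match.arg(solver)
  beta_sel <- NULL
  if (solver == "sa" && length(beta_grid) > 1L) {
    beta_sel <- cv_select_beta(dataset, seed, n_reads, n_sweeps,
                               beta_initial, beta_grid, n_keep, cv_folds,
                               intercept)
  } else if (solver == "sa") {
    beta_sel <- beta_grid[1L]
  }
  model <- fit_ising_once(dataset, solver, seed, n_reads, n_sweeps,
                          beta_initial, beta_sel, n_keep, intercept)
  model$beta_final_selected <- beta_sel
  model
}

# One encode -> scale -> solve -> postprocess pass with fixed hyperparameters.
fit_ising_once <- function(dataset, solver, seed, n_reads, n_sweeps,
                           beta_initial, beta_final, n_keep, intercept) {
  problem <- scale_to_unit(encode_ising(dataset, intercept = intercept))
  result <- switch(
    solver,
    field = solve_field(problem),
    random = solve_random(problem, n_reads = n_reads,
                          seed = derive_seed(seed, 101L)),
    sa = solve_sa(problem,
                  anneal_schedule(n_sweeps = n_sweeps,
                                  beta_initial = beta_initial,
                                  beta_final = beta_final),
                  n_reads = n_reads, seed = derive_seed(seed, 102L)))
  ds_enc <- if (isTRUE(intercept)) {
    labeled_dataset(cbind(dataset$features, intercept = 1), dataset$labels,
                    dataset$n_classes, dataset$class_names)
  } else dataset
  postprocess_average(result, ds_enc, n_keep = n_keep)
}

# Stratified k-fold assignment: within each class, samples are permuted and
# dealt round-robin to folds. Deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

cv_select_beta <- function(dataset, seed, n_reads, n_sweeps, beta_initial,
                           beta_grid, n_keep, cv_folds, intercept) {
  min_class <- min(table(dataset$labels))
  if (min_class < cv_folds) {
    warning(sprintf(
      "smallest class has %d members; reducing cross-validation folds from %d to %d",
      min_class, cv_folds, min_class), call. = FALSE)
    cv_folds <- min_class
  }
  fold <- stratified_folds(dataset$labels, cv_folds,
                           derive_seed(seed, 201L))
  scores <- vapply(seq_along(beta_grid), function(b) {
    accs <- vapply(seq_len(cv_folds), function(f) {
      tr <- dataset_subset(dataset, which(fold != f))
      va <- dataset_subset(dataset, which(fold == f))
      m <- fit_ising_once(tr, "sa", derive_seed(seed, 300L + b, f),
                          n_reads, n_sweeps, beta_initial, beta_grid[b],
                          n_keep, intercept)
      Xva <- va$features
      if (isTRUE(intercept)) Xva <- cbind(Xva, 1)
      balanced_accuracy(va$labels, predict_labels(m$weights, Xva),
                        n_classes = dataset$n_classes)
    }, numeric(1L))
    mean(accs)
  }, numeric(1L))
  # ties resolve to the smallest beta (least aggressive optimization)
  beta_grid[which.max(scores)]
}

#' Save / load a trained Ising model as JSON
#'
#' @param model a `trained_ising_model`.
#' @param path file path.
#' @return `save_ising_model` returns `path` invisibly; `load_ising_model`
#'   returns the model.
#' @export
save_ising_model <- function(model, path) {
  obj <- list(weights = unclass(model$weights),
              class_names = model$class_names,
              solver = model$solver_name,
              beta_final = model$beta_final_selected,
              n_averaged = model$n_averaged,
              training_nll = model$training_nll)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_ising_model
#' @export
load_ising_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_trained_ising_model(
    weights = weight_matrix(matrix(obj$weights,
                                   nrow = NROW(obj$weights),
                                   ncol = NCOL(obj$weights))),
    solver_name = obj$solver, beta_final_selected = obj$beta_final,
    n_averaged = obj$n_averaged, training_nll = obj$training_nll,
    class_names = obj$class_names)
}
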