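#' Train a classification RBM by one-step contrastive divergence
#'
#' A restricted Boltzmann machine whose visible layer is the concatenation of
#' the feature units and a one-hot block of label units. The joint energy is
#' `E(v, e, h) = -b'v - d'e - c'h - v'Wh - e'Uh` with binary hidden units.
#' Features are min-max rescaled to `[0, 1]` on the training data and used as
#' Bernoulli activation probabilities. Training follows CD-1: hidden units
#' are sampled as Bernoulli (binarized) in the positive phase; the negative
#' phase reconstructs feature units as sigmoid probabilities and label units
#' as a softmax, then recomputes hidden probabilities. Updates are applied
#' per minibatch (default size 32). Deterministic given `seed`.
#'
#' @param dataset training `labeled_dataset`.
#' @param n_hidden hidden units H (default 64).
#' @param learning_rate step size (default 0.1).
#' @param n_epochs full passes over the data (default 100).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed.
#' @return An `rbm_model`: weights `W` (M x H), `U` (K x H), biases
#'   `visible_bias`, `label_bias`, `hidden_bias`, the training min/max used
#'   for rescaling, and the hyperparameters.
#' @export
rbm_train <- function(dataset, n_hidden = 64L, learning_rate = 0.1,
                      n_epochs = 100L, batch_size = 32L, seed = 1L) {
  X <- dataset$features
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite input", call. = FALSE)
  K <- dataset$n_classes
  M <- ncol(X)
  H <- as.integer(n_hidden)
  if (H < 1L) stop("n_hidden must be >= 1", call. = FALSE)

  feat_min <- apply(X, 2L, min)
  feat_max <- apply(X, 2L, max)
  rng <- pmax(feat_max - feat_min, .Machine$double.eps)
  V <- sweep(sweep(X, 2L, feat_min), 2L, rng, "/")
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_len(nrow(X)), dataset$labels)] <- 1

  with_seed(seed, {
    sc <- 1 / sqrt(M + K + H)
    W <- matrix(stats::runif(M * H, -sc, sc), M, H)
    U <- matrix(stats::runif(K * H, -sc, sc), K, H)
    b <- numeric(M); d <- numeric(K); cb <- numeric(H)

    n <- nrow(V)
    for (epoch in seq_len(as.integer(n_epochs))) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = as.integer(batch_size))
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        v0 <- V[idx, , drop = FALSE]
        e0 <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        h0_prob <- plogis(sweep(v0 %*% W + e0 %*% U, 2L, cb, "+"))
        h0 <- (matrix(stats::runif(nb * H), nb, H) < h0_prob) * 1
        # negative phase: mean-field visibles, softmax labels, then hiddens
        v1 <- plogis(sweep(h0 %*% t(W), 2L, b, "+"))
        e1_sc <- sweep(h0 %*% t(U), 2L, d, "+")
        e1 <- exp(e1_sc - apply(e1_sc, 1L, max))
        e1 <- e1 / rowSums(e1)
        h1_prob <- plogis(sweep(v1 %*% W + e1 %*% U, 2L, cb, "+"))
        lr <- learning_rate / nb
        W <- W + lr * (crossprod(v0, h0_prob) - crossprod(v1, h1_prob))
        U <- U + lr * (crossprod(e0, h0_prob) - crossprod(e1, h1_prob))
        b <- b + lr * colSums(v0 - v1)
        d <- d + lr * colSums(e0 - e1)
        cb <- cb + lr * colSums(h0_prob - h1_prob)
      }
    }
    structure(
      list(visible_hidden_weights = W, label_hidden_weights = U,
           visible_bias = b, label_bias = d, hidden_bias = cb,
           feat_min = feat_min, feat_range = rng,
           class_names = dataset$class_names,
           hyperparams = list(n_hidden = H, learning_rate = learning_rate,
                              n_epochs = as.integer(n_epochs),
                              batch_size = as.integer(batch_size),
                              cd_k = 1L, seed = as.integer(seed))),
      class = "rbm_model")
  })
}

#' @export
print.rbm_model <- function(x, ...) {
  cat(sprintf(
    "<rbm_model> %d visible + %d label units, %d hidden units\n",
    length(x$visible_bias), length(x$label_bias), length(x$hidden_bias)))
  invisible(x)
}

# Free energy of (features v in [0,1], one-hot label e_k):
# F = -b'v - d_k - sum_h log(1 + exp(c_h + (W'v + U[k,])_h))
rbm_free_energy <- function(model, v) {
  act <- model$hidden_bias + as.numeric(crossprod(
    model$visible_hidden_weights, v))
  base <- -sum(model$visible_bias * v)
  vapply(seq_along(model$label_bias), function(k) {
    a <- act + model$label_hidden_weights[k, ]
    # log(1 + exp(a)) computed stably
    soft <- ifelse(a > 30, a, log1p(exp(a)))
    base - model$label_bias[k] - sum(soft)
  }, numeric(1L))
}

#' Class probabilities from a classification RBM
#'
#' For each class k, the label block is clamped to the one-hot vector `e_k`
#' and the unnormalized score `exp(-F(x, e_k))` is computed from the free
#' energy with hidden units summed out; scores are normalized over k. This
#' equals the exact conditional `Pr(label | features)` under the model.
#' Inputs are rescaled with the training min-max and clipped to `[0, 1]`.
#'
#' @param model an `rbm_model`.
#' @param x length-M feature vector (original scale), or an N x M matrix.
#' @return Length-K probability vector (or N x K matrix).
#' @export
rbm_predict_proba <- function(model, x) {
  M <- length(model$visible_bias)
  if (is.matrix(x)) {
    if (ncol(x) != M) stop("dimension mismatch", call. = FALSE)
    return(t(apply(x, 1L, function(r) rbm_predict_proba(model, r))))
  }
  if (length(x) != M) stop("dimension mismatch", call. = FALSE)
  v <- pmin(pmax((x - model$feat_min) / model$feat_range, 0), 1)
  fe <- rbm_free_energy(model, v)
  sc <- exp(-(fe - min(fe)))
  sc / sum(sc)
}

#' @export
predict.rbm_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  P <- rbm_predict_proba(object, newdata)
  if (type == "prob") P else apply(P, 1L, which.max)
}

#' Save / load an RBM model as JSON
#'
#' @param model an `rbm_model`.
#' @param path file path.
#' @return `save_rbm_model` returns `path` invisibly; `load_rbm_model`
#'   returns the model.
#' @export
save_rbm_model <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_rbm_model
#' @export
load_rbm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$visible_hidden_weights <- as.matrix(obj$visible_hidden_weights)
  obj$label_hidden_weights <- as.matrix(obj$label_hidden_weights)
  structure(obj, class = "rbm_model")
}
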