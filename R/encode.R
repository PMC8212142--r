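#' Encode a labeled dataset as an Ising problem
#'
#' Builds the quadratic spin objective obtained from a second-order expansion
#' of the softmax negative log likelihood around zero weights. With K classes
#' and M features the problem has `D = M * (K - 1)` spin variables, laid out
#' block-major: block k (k = 1..K-1) holds the weight vector of class k, the
#' K-th class being the softmax pivot.
#'
#' The coefficients are, with sums running over training examples i:
#' * linear block k: `b_k + h`, where `b_k = -sum_{i: y_i = k} x_i` and
#'   `h = (1/K) sum_i x_i`;
#' * intra-block pair (m < n): `2 * J'[m, n]` with
#'   `J' = (K-1)/(2 K^2) * sum_i x_i x_i^T` (each unordered pair appears twice
#'   in the quadratic form `w_k^T J' w_k`);
#' * inter-block pair (block j < block k, features m, n):
#'   `-2 * J''[m, n]` with `J'' = 1/(2 K^2) * sum_i x_i x_i^T` (the
#'   double sum over ordered class pairs visits each unordered pair twice);
#' * the diagonal of `J'` is constant under spins in `{-1, +1}` (`w^2 = 1`)
#'   and is folded into `offset`, keeping the quadratic strictly pairwise.
#'
#' An optional intercept appends a constant-1 feature column before encoding.
#'
#' @param dataset a [labeled_dataset()].
#' @param intercept logical; append a constant-1 feature column (default
#'   `FALSE`).
#' @return An object of class `ising_problem`: list with `linear` (length D),
#'   `quadratic` (D x D, strictly upper triangular), `offset`, `n_features`,
#'   `n_classes`.
#' @examples
#' fx <- worked_fixture()
#' p <- encode_ising(fx$dataset)
#' p$linear    # -0.5
#' p$offset    # 0.125
#' @export
encode_ising <- function(dataset, intercept = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$features
  if (isTRUE(intercept)) X <- cbind(X, intercept = 1)
  y <- dataset$labels
  K <- dataset$n_classes
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  # an absent class contributes no b_k mass; the objective stays well defined
  M <- ncol(X)
  D <- M * (K - 1L)

  h_vec <- colSums(X) / K
  gram <- crossprod(X)                       # sum_i x_i x_i^T
  Jp <- (K - 1) / (2 * K^2) * gram
  Jpp <- 1 / (2 * K^2) * gram

  linear <- numeric(D)
  quadratic <- matrix(0, D, D)
  for (k in seq_len(K - 1L)) {
    rows <- which(y == k)
    b_k <- -colSums(X[rows, , drop = FALSE])
    blk <- ((k - 1L) * M + 1L):(k * M)
    linear[blk] <- b_k + h_vec
    # intra-block: w_k' J' w_k -> 2 J'[m,n] per unordered pair, diag to offset
    intra <- 2 * Jp
    intra[lower.tri(intra, diag = TRUE)] <- 0
    quadratic[blk, blk] <- intra
  }
  if (K > 2L) {
    for (j in seq_len(K - 2L)) {
      for (k in (j + 1L):(K - 1L)) {
        bj <- ((j - 1L) * M + 1L):(j * M)
        bk <- ((k - 1L) * M + 1L):(k * M)
        quadratic[bj, bk] <- -2 * Jpp
      }
    }
  }
  offset <- (K - 1) * sum(diag(Jp))
  new_ising_problem(linear, quadratic, offset, M, K)
}

new_ising_problem <- function(linear, quadratic, offset, n_features,
                              n_classes) {
  D <- length(linear)
  quadratic <- as.matrix(quadratic)
  if (!all(dim(quadratic) == c(D, D))) {
    stop("quadratic must be D x D", call. = FALSE)
  }
  if (any(quadratic[lower.tri(quadratic, diag = TRUE)] != 0)) {
    stop("quadratic must be strictly upper triangular", call. = FALSE)
  }
  if (any(!is.finite(linear)) || any(!is.finite(quadratic)) ||
      !is.finite(offset)) {
    stop("non-finite coefficients", call. = FALSE)
  }
  if (D != n_features * (n_classes - 1L)) {
    stop("D must equal n_features * (n_classes - 1)", call. = FALSE)
  }
  structure(
    list(linear = as.numeric(linear), quadratic = quadratic,
         offset = as.numeric(offset), n_features = as.integer(n_features),
         n_classes = as.integer(n_classes)),
    class = "ising_problem"
  )
}

#' @export
print.ising_problem <- function(x, ...) {
  D <- length(x$linear)
  cat(sprintf(
    "<ising_problem> D = %d spins (M = %d features, K = %d classes)\n",
    D, x$n_features, x$n_classes))
  cat(sprintf("  max |h| = %.4g, max |J| = %.4g, offset = %.4g\n",
              max(abs(x$linear)), max(abs(x$quadratic)), x$offset))
  invisible(x)
}

#' Ising energy of a spin configuration
#'
#' `E(s) = sum_i h_i s_i + sum_{i<j} J_ij s_i s_j + offset`.
#'
#' @param problem an `ising_problem`.
#' @param spins numeric vector of -1/+1 of length D.
#' @return The scalar energy.
#' @export
ising_energy <- function(problem, spins) {
  spins <- as.numeric(spins)
  D <- length(problem$linear)
  if (length(spins) != D) {
    stop(sprintf("spin configuration has length %d, expected %d",
                 length(spins), D), call. = FALSE)
  }
  if (any(spins != 1 & spins != -1)) {
    stop("spins must be -1 or +1", call. = FALSE)
  }
  sum(problem$linear * spins) + sum(problem$quadratic * tcrossprod(spins)) +
    problem$offset
}

# Energies of many configurations (rows of S); shares the exact per-row
# arithmetic of ising_energy so SolverResult energies match it bitwise.
ising_energy_many <- function(problem, S) {
  apply(S, 1L, function(s) ising_energy(problem, s))
}

#' Rescale an Ising problem so all coefficients lie in \[-1, 1\]
#'
#' Divides linear and quadratic coefficients (and the offset) by
#' `c = max(|h|, |J|)` when `c > 0`, mimicking the automatic scaling of
#' annealing hardware. Positive rescaling preserves the full energy ordering,
#' hence the argmin.
#'
#' @param problem an `ising_problem`.
#' @return A scaled `ising_problem` (unchanged if all coefficients are zero).
#' @export
scale_to_unit <- function(problem) {
  cmax <- max(max(abs(problem$linear)), max(abs(problem$quadratic)))
  if (cmax == 0) return(problem)
  new_ising_problem(problem$linear / cmax, problem$quadratic / cmax,
                    problem$offset / cmax, problem$n_features,
                    problem$n_classes)
}

#' Number of logical variables needed for M features and K classes
#'
#' The softmax parameterization trains `K - 1` weight vectors of length M, so
#' the spin problem needs `M * (K - 1)` logical variables.
#'
#' @param M number of features (>= 1).
#' @param K number of classes (>= 2).
#' @return Integer `M * (K - 1)`.
#' @examples
#' logical_variable_count(13, 6)  # 65
#' @export
logical_variable_count <- function(M, K) {
  M <- as.integer(M); K <- as.integer(K)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)
  if (is.na(K) || K < 2L) stop("K must be an integer >= 2", call. = FALSE)
  M * (K - 1L)
}

#' Largest feature count fitting a logical-variable capacity
#'
#' Hardware (or any complete-graph budget) admitting `capacity` logical
#' variables supports at most `floor(capacity / (K - 1))` features.
#'
#' @param capacity logical-variable budget (>= K - 1).
#' @param K number of classes (>= 2).
#' @return Integer feature budget.
#' @examples
#' max_features(66, 6)  # 13
#' @export
max_features <- function(capacity, K) {
  capacity <- as.integer(capacity); K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be an integer >= 2", call. = FALSE)
  if (is.na(capacity) || capacity < K - 1L) {
    stop("capacity must be at least K - 1", call. = FALSE)
  }
  capacity %/% (K - 1L)
}

#' Reshape a spin configuration into a per-class weight matrix
#'
#' Block-major layout: row k of the result is spins `[(k-1)M + 1 .. kM]`.
#'
#' @param spins length `M * (K - 1)` vector.
#' @param M number of features.
#' @param K number of classes.
#' @return A `(K - 1) x M` weight matrix (class `weight_matrix`).
#' @export
spins_to_weights <- function(spins, M, K) {
  spins <- as.numeric(spins)
  M <- as.integer(M); K <- as.integer(K)
  if (length(spins) != M * (K - 1L)) {
    stop(sprintf("expected %d spins, got %d", M * (K - 1L), length(spins)),
         call. = FALSE)
  }
  weight_matrix(matrix(spins, nrow = K - 1L, ncol = M, byrow = TRUE))
}

#' Classifier weight matrix
#'
#' `(K - 1) x M` matrix with entries in `[-1, 1]`: raw solver configurations
#' are plus/minus one; ensemble-averaged weights are fractional.
#'
#' @param w numeric matrix.
#' @return `w` with class `weight_matrix`.
#' @export
weight_matrix <- function(w) {
  w <- as.matrix(w)
  storage.mode(w) <- "double"
  if (any(!is.finite(w)) || any(abs(w) > 1 + 1e-12)) {
    stop("weights must be finite and lie in [-1, 1]", call. = FALSE)
  }
  class(w) <- c("weight_matrix", "matrix", "array")
  w
}
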