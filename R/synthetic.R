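#' Specification for a synthetic multi-omics-like dataset
#'
#' Describes the statistical structure the classifier assumes: standardized
#' continuous features, block-constant correlation inside feature blocks
#' (emulating concatenated omics platforms), and class-dependent mean shifts
#' concentrated on a few informative features.
#'
#' @param n_per_class integer vector of K class sizes.
#' @param n_features total features M.
#' @param n_informative number of informative features (<= M).
#' @param effect_size delta: total between-extreme-class mean separation per
#'   informative feature, in noise-sd units (default 2).
#' @param block_sizes integer vector partitioning `1..M` into correlated
#'   blocks (default: one block per feature, i.e. independent features).
#' @param within_block_correlation rho in [0, 1) (default 0).
#' @param seed integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_per_class, n_features, n_informative,
                           effect_size = 2, block_sizes = NULL,
                           within_block_correlation = 0, seed = 1L) {
  if (is.null(block_sizes)) block_sizes <- rep(1L, n_features)
  if (sum(block_sizes) != n_features) {
    stop("block_sizes must partition 1..n_features", call. = FALSE)
  }
  if (n_informative > n_features) {
    stop("n_informative must be <= n_features", call. = FALSE)
  }
  rho <- within_block_correlation
  if (rho < 0 || rho >= 1) stop("need 0 <= rho < 1", call. = FALSE)
  if (length(n_per_class) < 2L) stop("need K >= 2 classes", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 block_sizes = as.integer(block_sizes),
                 within_block_correlation = rho, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a block-correlated multi-omics-like dataset
#'
#' Features follow a factor model giving block-constant correlation `rho`
#' within blocks and independence across blocks:
#' `x_j = sqrt(rho) * g_b + sqrt(1 - rho) * eps_j` with shared per-block
#' factor `g_b`. Class k adds a mean shift `delta * s_j * z_k` to informative
#' feature j, where the planted signs `s_j` are drawn in `{-1, +1}` and the
#' class scores `z_k` are equally spaced from `+1/2` (class 1) down to
#' `-1/2` (class K), so the separation between the extreme classes is
#' `delta` noise-sd units. Columns are then standardized marginally.
#'
#' Metadata attributes on the result: `planted_signs` (length
#' `n_informative`), `informative` (feature indices), `class_shifts`
#' (K x M matrix of pre-standardization means).
#'
#' @param spec a [synthetic_spec()].
#' @return A `labeled_dataset` (samples are ordered by class).
#' @export
make_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- length(spec$n_per_class)
  M <- spec$n_features
  N <- sum(spec$n_per_class)
  rho <- spec$within_block_correlation
  block_id <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  labels <- rep(seq_len(K), spec$n_per_class)

  with_seed(spec$seed, {
    informative <- sort(sample.int(M, spec$n_informative))
    signs <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
    z <- if (K == 2L) c(0.5, -0.5) else (1 - 2 * (seq_len(K) - 1) /
                                           (K - 1)) / 2
    shifts <- matrix(0, K, M)
    shifts[, informative] <- outer(z, spec$effect_size * signs)

    G <- matrix(stats::rnorm(N * length(spec$block_sizes)), N)
    E <- matrix(stats::rnorm(N * M), N, M)
    X <- sqrt(rho) * G[, block_id, drop = FALSE] + sqrt(1 - rho) * E
    X <- X + shifts[labels, , drop = FALSE]
    X <- scale(X)                      # marginal standardization
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    ds <- labeled_dataset(X, labels, n_classes = K)
    attr(ds, "planted_signs") <- signs
    attr(ds, "informative") <- informative
    attr(ds, "class_shifts") <- shifts
    ds
  })
}

#' Two-cluster separable toy dataset
#'
#' Two classes in two dimensions at `(+margin, 0)` (class 1) and
#' `(-margin, 0)` (class 2) plus unit Gaussian noise; class 1 listed first.
#' With a large margin this is linearly separable with probability ~ 1 and a
#' binary weight `w = (+1, *)` classifies perfectly.
#'
#' @param n even total sample count.
#' @param margin half-distance between the class centers (> 0 for signal).
#' @param seed integer seed.
#' @return A `labeled_dataset`.
#' @export
make_separable_toy <- function(n, margin, seed = 1L) {
  if (n %% 2L != 0L) stop("n must be even", call. = FALSE)
  labels <- rep(1:2, each = n / 2L)
  centers <- cbind(ifelse(labels == 1L, margin, -margin), 0)
  X <- with_seed(seed, centers + matrix(stats::rnorm(n * 2L), n, 2L))
  labeled_dataset(X, labels, n_classes = 2L)
}

#' Hand-checkable single-point fixture
#'
#' The smallest nontrivial encoding: one training example `x = 1` of class 1
#' with K = 2. The expected problem has `linear = -0.5` (from
#' `b_1 = -1`, `h = 0.5`), no pair terms, and `offset = 0.125` (the constant
#' diagonal of `J' = 1/8`). Its exhaustive minimum is spin +1 at energy
#' -0.375.
#'
#' @return List with `dataset` (a `labeled_dataset`) and `problem` (the
#'   expected `ising_problem`).
#' @export
worked_fixture <- function() {
  ds <- labeled_dataset(matrix(1, 1, 1), 1L, n_classes = 2L,
                        require_all_classes = FALSE)
  problem <- new_ising_problem(linear = -0.5,
                               quadratic = matrix(0, 1, 1),
                               offset = 0.125, n_features = 1L,
                               n_classes = 2L)
  list(dataset = ds, problem = problem)
}
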