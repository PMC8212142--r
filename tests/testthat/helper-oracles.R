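# Independent oracles used across the suite. These deliberately re-derive
# quantities with the dumbest possible code paths (double loops, full
# enumeration, closed forms) so they share nothing with the implementation.

# Brute-force Ising energy: double loop over all ordered pairs.
oracle_energy <- function(problem, s) {
  D <- length(problem$linear)
  e <- problem$offset
  for (i in seq_len(D)) {
    e <- e + problem$linear[i] * s[i]
    if (i < D) for (j in (i + 1L):D) {
      e <- e + problem$quadratic[i, j] * s[i] * s[j]
    }
  }
  e
}

# All 2^D spin configurations as rows, index 0 first, first spin most
# significant (lexicographic with -1 before +1).
all_configs <- function(D) {
  S <- matrix(-1, 2^D, D)
  for (i in seq_len(2^D)) {
    bits <- as.integer(intToBits(i - 1L))[D:1]
    S[i, ] <- 2 * bits - 1
  }
  S
}

# Exhaustive minimum energy by brute force.
oracle_min_energy <- function(problem) {
  S <- all_configs(length(problem$linear))
  min(apply(S, 1L, function(s) oracle_energy(problem, s)))
}

# Literal term-by-term evaluation of the expanded negative-log-likelihood
# objective for weight rows W ((K-1) x M), summing every b_k, h, J', J''
# contribution with explicit loops.
oracle_expanded_objective <- function(X, y, K, W) {
  M <- ncol(X)
  v <- 0
  for (k in seq_len(K - 1)) {
    for (m in seq_len(M)) {
      b_km <- 0
      for (i in seq_len(nrow(X))) if (y[i] == k) b_km <- b_km - X[i, m]
      h_m <- sum(X[, m]) / K
      v <- v + W[k, m] * (b_km + h_m)
    }
  }
  for (k in seq_len(K - 1)) {
    for (m in seq_len(M)) for (n in seq_len(M)) {
      Jp <- (K - 1) / (2 * K^2) * sum(X[, m] * X[, n])
      v <- v + W[k, m] * Jp * W[k, n]
    }
  }
  for (k in seq_len(K - 1)) for (j in seq_len(K - 1)) {
    if (j == k) next
    for (m in seq_len(M)) for (n in seq_len(M)) {
      Jpp <- 1 / (2 * K^2) * sum(X[, m] * X[, n])
      v <- v - W[j, m] * Jpp * W[k, n]
    }
  }
  v
}

# Closed-form gradient and Hessian of the binomial (K = 2) logistic negative
# log likelihood at w = 0, with class 1 carrying the weight vector:
# L(w) = sum_i log(1 + exp(w'x_i)) - sum_{i: y_i = 1} w'x_i.
oracle_logistic_taylor <- function(X, y) {
  g <- colSums((0.5 - (y == 1)) * X)
  H <- 0.25 * crossprod(X)
  list(gradient = g, hessian = H)
}

# Random small Ising problem with every coefficient drawn N(0, 1).
random_problem <- function(D, seed, density = 1) {
  set.seed(seed)
  lin <- rnorm(D)
  quad <- matrix(0, D, D)
  up <- upper.tri(quad)
  vals <- rnorm(sum(up))
  if (density < 1) vals <- vals * (runif(length(vals)) < density)
  quad[up] <- vals
  isingml:::new_ising_problem(lin, quad, rnorm(1), D, 2L)
}

# Exact conditional label distribution of a classification RBM by summing
# the joint Boltzmann weights over all 2^H hidden states.
oracle_rbm_proba <- function(model, x) {
  v <- pmin(pmax((x - model$feat_min) / model$feat_range, 0), 1)
  K <- length(model$label_bias)
  H <- length(model$hidden_bias)
  scores <- vapply(seq_len(K), function(k) {
    e <- as.numeric(seq_len(K) == k)
    tot <- 0
    for (i in 0:(2^H - 1)) {
      hvec <- as.integer(intToBits(i))[seq_len(H)]
      E <- -sum(model$visible_bias * v) - sum(model$label_bias * e) -
        sum(model$hidden_bias * hvec) -
        as.numeric(t(v) %*% model$visible_hidden_weights %*% hvec) -
        as.numeric(t(e) %*% model$label_hidden_weights %*% hvec)
      tot <- tot + exp(-E)
    }
    tot
  }, numeric(1))
  scores / sum(scores)
}
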