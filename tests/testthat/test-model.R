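test_that("class probabilities follow the pivot softmax", {
  w0 <- weight_matrix(matrix(0, 3, 2))
  expect_equal(class_probabilities(w0, c(1, -2)), rep(0.25, 4))
  w <- weight_matrix(matrix(1, 1, 1))
  p <- class_probabilities(w, 1)
  expect_equal(p, c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))))
  expect_equal(round(p, 5), c(0.73106, 0.26894))
  w3 <- weight_matrix(matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(class_probabilities(w3, c(0, 0)), rep(1 / 3, 3))
  expect_error(class_probabilities(w, c(1, 2)), "dimension")
})

test_that("probabilities are strictly positive and sum to one", {
  set.seed(2)
  for (r in 1:20) {
    K <- sample(2:5, 1)
    M <- sample(1:6, 1)
    W <- weight_matrix(matrix(runif((K - 1) * M, -1, 1), K - 1, M))
    x <- rnorm(M, sd = 3)
    p <- class_probabilities(W, x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("K = 2 probabilities reduce to the logistic function", {
  set.seed(3)
  W <- weight_matrix(matrix(runif(4, -1, 1), 1, 4))
  for (r in 1:10) {
    x <- rnorm(4)
    expect_equal(class_probabilities(W, x)[1],
                 plogis(sum(W * x)), tolerance = 1e-12)
  }
})

test_that("negative log likelihood matches closed forms and handles zeros", {
  # probability-1 table -> exactly zero
  P <- diag(3)[c(1, 2, 3, 1), ]
  expect_identical(nll_from_prob(P, c(1L, 2L, 3L, 1L)), 0)
  # zero probability for an observed class -> +Inf, no error
  expect_identical(nll_from_prob(P, c(2L, 2L, 3L, 1L)), Inf)

  set.seed(4)
  d <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(1:2, 3))
  expect_equal(negative_log_likelihood(weight_matrix(matrix(0, 1, 2)), d),
               6 * log(2), tolerance = 1e-12)
  d3 <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(1:3, 2), 3)
  expect_equal(negative_log_likelihood(weight_matrix(matrix(0, 2, 2)), d3),
               6 * log(3), tolerance = 1e-12)

  d1 <- labeled_dataset(matrix(1, 1, 1), 1L, n_classes = 2,
                        require_all_classes = FALSE)
  expect_equal(negative_log_likelihood(weight_matrix(matrix(1, 1, 1)), d1),
               -log(exp(1) / (1 + exp(1))), tolerance = 1e-12)
  expect_equal(round(negative_log_likelihood(
    weight_matrix(matrix(1, 1, 1)), d1), 5), 0.31326)
})

test_that("prediction takes the argmax with low-index tie-break", {
  d <- matrix(rnorm(10), 5, 2)
  expect_equal(predict_labels(weight_matrix(matrix(0, 1, 2)), d),
               rep(1L, 5))
  expect_equal(predict_labels(weight_matrix(matrix(0, 2, 2)), d),
               rep(1L, 5))
  expect_equal(predict_labels(weight_matrix(matrix(1, 1, 1)),
                              matrix(1)), 1L)
  expect_equal(predict_labels(weight_matrix(matrix(1, 1, 1)),
                              matrix(-1)), 2L)
})

test_that("postprocess_average follows the greedy ascending-energy rule", {
  fx <- worked_fixture()
  p <- encode_ising(fx$dataset)

  one <- solve_field(p)
  m1 <- postprocess_average(one, fx$dataset)
  expect_identical(m1$n_averaged, 1L)
  expect_equal(as.numeric(m1$weights), one$configurations[1, ])

  # duplicates are removed before the greedy scan
  dup <- one
  dup$configurations <- rbind(one$configurations, one$configurations)
  dup$energies <- rep(one$energies, 2)
  m2 <- postprocess_average(dup, fx$dataset)
  expect_identical(m2$n_averaged, 1L)

  expect_error(postprocess_average(
    structure(list(configurations = matrix(0, 0, 1), energies = numeric(0),
                   solver_name = "x"), class = "solver_result"),
    fx$dataset), "empty")
})

test_that("averaging can repair a misclassifying best-energy configuration", {
  # Constructed 2-variable problem: enumerate all configurations, order by a
  # crafted energy so the NLL-optimal single config is NOT first, and check
  # the greedy average strictly lowers the training NLL.
  set.seed(6)
  X <- rbind(c(2, 0.2), c(-2, -0.2), c(1.5, -0.4), c(-1.5, 0.6),
             c(0.1, 2.2), c(-0.4, -2.0))
  y <- c(1L, 2L, 1L, 2L, 1L, 2L)
  d <- labeled_dataset(X, y)
  p <- encode_ising(d)
  S <- all_configs(2)
  nlls <- apply(S, 1, function(s)
    negative_log_likelihood(spins_to_weights(s, 2, 2), d))
  # order configurations so the worst-NLL config carries the lowest energy
  ord <- order(-nlls)
  res <- structure(list(configurations = S[ord, ],
                        energies = sort(apply(S, 1, function(s)
                          ising_energy(p, s))),
                        n_reads = 4L, seed = NA_integer_,
                        solver_name = "crafted"),
                   class = "solver_result")
  m <- postprocess_average(res, d)
  expect_gt(m$n_averaged, 1L)
  expect_lt(m$training_nll, nlls[ord][1])
  expect_true(all(abs(m$weights) <= 1))
  expect_true(any(abs(m$weights) < 1))  # fractional after averaging
})

test_that("averaged training NLL never exceeds the best-energy configuration's", {
  # scaled-down version of the acceptance sweep (which uses 1,000 instances)
  for (seed in 1:50) {
    set.seed(seed)
    n <- 8; M <- 3
    X <- matrix(rnorm(n * M), n, M)
    y <- rep(1:2, length.out = n)
    d <- labeled_dataset(X, y)
    p <- scale_to_unit(encode_ising(d))
    res <- solve_random(p, n_reads = 40, seed = seed)
    m <- postprocess_average(res, d)
    nll_single <- negative_log_likelihood(
      spins_to_weights(res$configurations[1, ], M, 2), d)
    expect_lte(m$training_nll, nll_single)
    expect_equal(m$training_nll, negative_log_likelihood(m$weights, d))
  }
})

test_that("fit_ising is deterministic and skips CV when there is nothing to tune", {
  toy <- make_separable_toy(30, 5, seed = 2)
  f1 <- fit_ising(toy, "field")
  expect_null(f1$beta_final_selected)
  f2 <- fit_ising(toy, "field")
  expect_identical(f1$weights, f2$weights)

  a <- fit_ising(toy, "sa", seed = 3, n_reads = 50, n_sweeps = 50,
                 beta_grid = c(0.3, 3), cv_folds = 3)
  b <- fit_ising(toy, "sa", seed = 3, n_reads = 50, n_sweeps = 50,
                 beta_grid = c(0.3, 3), cv_folds = 3)
  expect_identical(a$weights, b$weights)
  expect_identical(a$beta_final_selected, b$beta_final_selected)
})

test_that("separable data trains to perfect balanced accuracy", {
  toy <- make_separable_toy(40, 10, seed = 7)
  m <- fit_ising(toy, "sa", seed = 1, n_reads = 100, n_sweeps = 200,
                 beta_grid = 3)
  acc <- compute_metrics(toy$labels, predict(m, toy$features),
                         n_classes = 2)$balanced_accuracy
  expect_equal(acc, 1)
})

test_that("few-member classes reduce the fold count with a warning", {
  set.seed(8)
  X <- matrix(rnorm(26), 13, 2)
  y <- c(rep(1L, 10), rep(2L, 3))
  d <- labeled_dataset(X, y)
  expect_warning(
    fit_ising(d, "sa", seed = 1, n_reads = 20, n_sweeps = 20,
              beta_grid = c(0.3, 3), cv_folds = 10),
    "reducing cross-validation folds")
})

test_that("planted signs are recovered on strongly informative features", {
  # scaled down from the acceptance run (20 seeds)
  match_frac <- vapply(1:5, function(seed) {
    d <- make_multiomics(synthetic_spec(c(200, 200), 20, 5,
                                        effect_size = 2, seed = seed))
    m <- fit_ising(d, "sa", seed = seed, n_reads = 200, n_sweeps = 200,
                   beta_grid = 3)
    inf <- attr(d, "informative")
    signs <- attr(d, "planted_signs")
    mean(sign(m$weights[1, inf]) == signs)
  }, numeric(1))
  expect_gte(mean(match_frac), 0.95)
})

test_that("ising model JSON save/load round-trips", {
  toy <- make_separable_toy(20, 5, seed = 3)
  m <- fit_ising(toy, "sa", seed = 2, n_reads = 30, n_sweeps = 30,
                 beta_grid = 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_ising_model(m, f)
  m2 <- load_ising_model(f)
  expect_equal(unclass(m2$weights), unclass(m$weights),
               ignore_attr = TRUE)
  expect_identical(m2$n_averaged, m$n_averaged)
  expect_equal(m2$training_nll, m$training_nll)
  expect_identical(m2$solver_name, m$solver_name)
})
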