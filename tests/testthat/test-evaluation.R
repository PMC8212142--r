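test_that("splits are stratified, exhaustive, disjoint, deterministic", {
  labels <- rep(1:2, each = 5)
  plan <- make_splits(labels, n_splits = 10, train_fraction = 0.8,
                      seed = 1)
  for (s in 1:10) {
    tr <- plan$train[[s]]; te <- plan$test[[s]]
    expect_length(tr, 8L)
    expect_length(te, 2L)
    expect_setequal(c(tr, te), 1:10)
    expect_length(intersect(tr, te), 0L)
    expect_equal(sum(labels[tr] == 1), 4L)
    expect_equal(sum(labels[te] == 1), 1L)
  }
  plan2 <- make_splits(labels, 10, 0.8, seed = 1)
  expect_identical(plan, plan2)
  expect_error(make_splits(c(1, 1, 2), 5, 0.8, 1), "2 members")
})

test_that("test-set membership counts follow the binomial expectation", {
  labels <- rep(1:2, each = 20)
  plan <- make_splits(labels, n_splits = 100, train_fraction = 0.8,
                      seed = 3)
  counts <- table(factor(unlist(plan$test), levels = 1:40))
  # each sample is in test with p = 0.2: expect 20 appearances, sd ~ 4
  expect_true(all(counts >= 20 - 12 & counts <= 20 + 12))
  expect_equal(mean(counts), 20)
})

test_that("z-scoring is train-fitted and handles constant columns", {
  tr <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  te <- cbind(a = c(4, 0), b = c(7, 5))
  z <- zscore_fit_apply(tr, te)
  expect_equal(unname(z$train_Z[, 1]), c(-1, 0, 1))
  expect_equal(unname(z$train_Z[, 2]), c(0, 0, 0))
  expect_equal(unname(z$test_Z[, 2]), c(0, 0))
  expect_equal(unname(z$test_Z[, 1]), (c(4, 0) - 2) / 1)
  set.seed(4)
  tr2 <- matrix(rnorm(50, 3, 2), 10, 5)
  te2 <- matrix(rnorm(25, 3, 2), 5, 5)
  z2 <- zscore_fit_apply(tr2, te2)
  expect_equal(unname(colMeans(z2$train_Z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z2$train_Z, 2, sd)), rep(1, 5),
               tolerance = 1e-12)
  expect_equal(z2$test_Z, sweep(sweep(te2, 2, colMeans(tr2)), 2,
                                apply(tr2, 2, sd), "/"),
               tolerance = 1e-12)
})

test_that("PCA is train-fitted, orthonormal, complete, sign-fixed", {
  set.seed(5)
  tr <- matrix(rnorm(80), 20, 4)
  te <- matrix(rnorm(20), 5, 4)
  pc <- pca_fit_project(tr, te, 4)
  expect_equal(crossprod(pc$loadings), diag(4), tolerance = 1e-10)
  # completeness: all components reconstruct the centered training data
  recon <- pc$train_PCs %*% t(pc$loadings)
  expect_equal(recon, sweep(tr, 2, colMeans(tr)), tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  for (j in 1:4) {
    i <- which.max(abs(pc$loadings[, j]))
    expect_gt(pc$loadings[i, j], 0)
  }
  # projection uses train center and loadings only
  expect_equal(pc$test_PCs,
               sweep(te, 2, colMeans(tr)) %*% pc$loadings,
               tolerance = 1e-12)
  expect_error(pca_fit_project(tr, te, 21), "n_components")

  # two perfectly correlated features: PC1 explains all variance
  x <- rnorm(30)
  tr2 <- cbind(x, 2 * x)
  pc2 <- pca_fit_project(tr2, tr2[1:2, , drop = FALSE], 2)
  expect_equal(pc2$explained_variance[2] / sum(pc2$explained_variance), 0,
               tolerance = 1e-12)
})

test_that("no test statistic enters the fitted transforms (leakage check)", {
  set.seed(6)
  tr <- matrix(rnorm(60), 15, 4)
  te1 <- matrix(rnorm(40), 10, 4)
  te2 <- matrix(rnorm(40, 10, 5), 10, 4)   # wildly different test rows
  z1 <- zscore_fit_apply(tr, te1)
  z2 <- zscore_fit_apply(tr, te2)
  expect_identical(z1$means, z2$means)
  expect_identical(z1$sds, z2$sds)
  expect_identical(z1$train_Z, z2$train_Z)
  p1 <- pca_fit_project(z1$train_Z, z1$test_Z, 3)
  p2 <- pca_fit_project(z2$train_Z, z2$test_Z, 3)
  expect_identical(p1$loadings, p2$loadings)
  expect_identical(p1$train_PCs, p2$train_PCs)
})

test_that("training subsamples are stratified and leave the test set alone", {
  labels <- rep(1:2, each = 50)
  tr_idx <- c(1:40, 51:90)
  subs <- subsample_training(tr_idx, labels, 0.2, n_replicates = 50,
                             seed = 2)
  expect_length(subs, 50L)
  for (s in subs) {
    expect_length(s, 16L)
    expect_equal(sum(labels[s] == 1), 8L)
    expect_true(all(s %in% tr_idx))
  }
  # replicates are distinct draws
  expect_gt(length(unique(vapply(subs, paste, collapse = ",",
                                 character(1)))), 1L)
  full <- subsample_training(tr_idx, labels, 1.0, n_replicates = 3,
                             seed = 2)
  for (s in full) expect_setequal(s, tr_idx)
  expect_error(subsample_training(tr_idx, labels, 0), "fraction")
  expect_error(subsample_training(1:2, labels, 0.01), "empties")
})

test_that("metrics match hand-computed confusion-matrix values", {
  # 3-class fixture, hand-computed:
  # class 1: 4 true, 3 recalled; class 2: 3 true, 2 recalled;
  # class 3: 3 true, 1 recalled
  y_true <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  y_pred <- c(1, 1, 1, 2, 2, 2, 3, 3, 1, 2)
  m <- compute_metrics(y_true, y_pred, n_classes = 3)
  expect_equal(m$accuracy, 6 / 10)
  expect_equal(m$balanced_accuracy, mean(c(3 / 4, 2 / 3, 1 / 3)))
  # macro F1: per-class precision 3/4, 2/4, 1/2; recall 3/4, 2/3, 1/3
  f1 <- mean(c(2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4),
               2 * (2 / 4) * (2 / 3) / (2 / 4 + 2 / 3),
               2 * (1 / 2) * (1 / 3) / (1 / 2 + 1 / 3)))
  expect_equal(m$f1, f1)

  # binary: positive class is class 2
  yt <- c(1, 1, 2, 2, 2)
  yp <- c(1, 2, 2, 2, 1)
  m2 <- compute_metrics(yt, yp, n_classes = 2)
  expect_equal(m2$balanced_accuracy, mean(c(1 / 2, 2 / 3)))
  expect_equal(m2$f1, 2 * 2 / (2 * 2 + 1 + 1))
  # AUC from explicit probabilities: perfect ranking -> 1
  P <- cbind(1 - c(0.1, 0.2, 0.8, 0.9, 0.7), c(0.1, 0.2, 0.8, 0.9, 0.7))
  expect_equal(compute_metrics(yt, yp, P, n_classes = 2)$auc, 1)
  # reversed ranking -> 0
  expect_equal(compute_metrics(yt, yp, 1 - P, n_classes = 2)$auc, 0)

  perf <- compute_metrics(yt, yt, cbind(yt == 1, yt == 2), n_classes = 2)
  expect_equal(unlist(perf), c(accuracy = 1, balanced_accuracy = 1,
                               auc = 1, f1 = 1))
  expect_warning(compute_metrics(c(1, 1), c(1, 2), n_classes = 2),
                 "absent")
})

test_that("uniform random predictions score near chance balanced accuracy", {
  set.seed(7)
  for (K in c(2, 4)) {
    n_per <- 250
    y <- rep(seq_len(K), each = n_per)
    yhat <- sample(seq_len(K), length(y), replace = TRUE)
    # mean of K independent binomial recalls: 4-sigma Monte-Carlo band
    mc_sd <- sqrt((1 / K) * (1 - 1 / K) / n_per / K)
    expect_lt(abs(compute_metrics(y, yhat,
                                  n_classes = K)$balanced_accuracy - 1 / K),
              4 * mc_sd)
  }
})

test_that("classifier comparison applies Wilcoxon + Bonferroni correctly", {
  mk <- function(clf, vals) data.frame(classifier = clf,
                                       split = seq_along(vals),
                                       metric = "balanced_accuracy",
                                       value = vals)
  # identical vectors -> corrected p = 1
  rep1 <- rbind(mk("a", rep(0.8, 20)), mk("b", rep(0.8, 20)))
  cmp <- compare_classifiers(rep1)
  expect_equal(cmp$p_bonferroni, 1)
  # uniform improvement of 0.1 on 50 splits -> tiny p
  set.seed(8)
  base <- runif(50, 0.6, 0.9)
  rep2 <- rbind(mk("a", base + 0.1), mk("b", base))
  expect_lt(compare_classifiers(rep2)$p_raw, 0.001)
  # Bonferroni factor = number of classifier pairs (3 classifiers -> 3)
  rep3 <- rbind(mk("a", base + 0.1), mk("b", base), mk("c", base + 0.05))
  cmp3 <- compare_classifiers(rep3)
  expect_equal(nrow(cmp3), 3L)
  expect_equal(cmp3$p_bonferroni, pmin(1, cmp3$p_raw * 3))
  expect_error(compare_classifiers(mk("a", base)), "two classifiers")
})

test_that("overfitting gap is the paired train-minus-test difference", {
  g0 <- overfitting_gap(rep(0.8, 10), rep(0.8, 10))
  expect_equal(g0$mean, 0)
  expect_equal(g0$sem, 0)
  g <- overfitting_gap(rep(0.9, 10), rep(0.7, 10))
  expect_equal(g$mean, 0.2)
  expect_equal(g$sem, 0)
  set.seed(9)
  tr <- runif(20, 0.8, 1); te <- runif(20, 0.5, 0.9)
  g2 <- overfitting_gap(tr, te)
  expect_equal(g2$mean, mean(tr - te))
  expect_equal(g2$sem, sd(tr - te) / sqrt(20))
})

test_that("feature importance averages |weights| and ranks with index ties", {
  m <- isingml:::new_trained_ising_model(
    weight_matrix(matrix(c(1, -1, 0.2), 1, 3)), "sa", NULL, 1L, 0,
    c("a", "b"))
  fi <- feature_importance(m)
  expect_equal(fi$feature, c(1L, 2L, 3L))
  expect_equal(fi$importance, c(1, 1, 0.2))
  m0 <- isingml:::new_trained_ising_model(
    weight_matrix(matrix(0, 2, 3)), "sa", NULL, 1L, 0, c("a", "b", "c"))
  expect_equal(feature_importance(m0)$importance, rep(0, 3))
  # across models: mean of per-model |weight| means
  m2 <- isingml:::new_trained_ising_model(
    weight_matrix(matrix(c(0, 1, 0.4), 1, 3)), "sa", NULL, 1L, 0,
    c("a", "b"))
  fi2 <- feature_importance(list(m, m2))
  expect_equal(sort(fi2$importance, decreasing = TRUE), fi2$importance)
  expect_equal(fi2$importance[fi2$feature == 2], 1)
})

test_that("planted informative features reach the top importance ranks", {
  hits <- vapply(1:10, function(seed) {
    d <- make_multiomics(synthetic_spec(c(100, 100), 12, 3,
                                        effect_size = 3, seed = seed))
    m <- fit_ising(d, "sa", seed = seed, n_reads = 100, n_sweeps = 100,
                   beta_grid = 3)
    fi <- feature_importance(m)
    all(attr(d, "informative") %in% fi$feature[1:6])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("top-loading feature selection agrees with a full-sort oracle", {
  expect_equal(select_top_loading_features(c(0.9, -0.95, 0.1), k = 2),
               c(2L, 1L))
  set.seed(10)
  for (r in 1:20) {
    v <- rnorm(15)
    k <- sample(1:15, 1)
    oracle <- order(-abs(v), seq_along(v))[seq_len(k)]
    expect_identical(select_top_loading_features(v, k = k), oracle)
  }
  L <- cbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(select_top_loading_features(L, component = 2, k = 1), 2L)
  expect_error(select_top_loading_features(c(1, 2), k = 3), "k exceeds")
})
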