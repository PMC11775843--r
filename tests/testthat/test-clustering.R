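# two well-separated planted 2-D Gaussians used across several tests
planted_two <- function(n = 20000, seed = 13) {
  set.seed(seed)
  n1 <- round(0.6 * n)
  x <- rbind(
    MASS::mvrnorm(n1, c(0, 0), matrix(c(1, 0.3, 0.3, 0.8), 2)),
    MASS::mvrnorm(n - n1, c(6, 5), matrix(c(0.7, -0.2, -0.2, 1.2), 2)))
  list(x = x, labels = rep(1:2, c(n1, n - n1)),
       means = rbind(c(0, 0), c(6, 5)), weights = c(0.6, 0.4))
}

test_that("EM recovers planted two-component mixture parameters", {
  p <- planted_two()
  fit <- fit_gmm(p$x, 2, seed = 1, n_restarts = 4)
  ord <- order(fit$means[, 1])
  expect_lt(max(abs(fit$means[ord, ] - p$means)), 0.1)
  expect_lt(max(abs(fit$weights[ord] - p$weights)), 0.02)
})

test_that("a single component reduces to the sample moments", {
  set.seed(3)
  x <- MASS::mvrnorm(2000, c(1, -2), matrix(c(2, 0.5, 0.5, 1), 2))
  fit <- fit_gmm(x, 1, seed = 1, n_restarts = 1)
  expect_equal(as.numeric(fit$means), colMeans(x), tolerance = 1e-6)
  expect_equal(fit$covs[[1]], cov(x) * (nrow(x) - 1) / nrow(x),
               tolerance = 1e-3)
  expect_equal(fit$weights, 1)
})

test_that("EM log-likelihood traces are monotone non-decreasing", {
  set.seed(5)
  for (i in 1:5) {
    x <- rbind(MASS::mvrnorm(300, rnorm(2, sd = 2), random_cov(2)),
               MASS::mvrnorm(300, rnorm(2, sd = 2), random_cov(2)))
    fit <- fit_gmm(x, sample(2:4, 1), seed = i, n_restarts = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("EM agrees with an independent mixture implementation", {
  p <- planted_two(n = 5000)
  fit <- fit_gmm(p$x, 2, seed = 2, n_restarts = 4)
  mc <- mclust::Mclust(p$x, G = 2, modelNames = "VVV", verbose = FALSE)
  # same clustering up to label permutation
  expect_gt(mclust::adjustedRandIndex(
    endotyper:::hard_assign(fit, p$x), mc$classification), 0.99)
  # same mean log-likelihood to EM tolerance
  expect_equal(fit$loglik, mc$loglik / nrow(p$x), tolerance = 1e-3)
})

test_that("posterior responsibilities are normalized probabilities", {
  p <- planted_two(n = 2000)
  fit <- fit_gmm(p$x, 2, seed = 1, n_restarts = 2)
  resp <- posterior_probs(fit, p$x)
  expect_true(all(resp >= 0 & resp <= 1))
  expect_lt(max(abs(rowSums(resp) - 1)), 1e-9)
  # symmetric midpoint between identical-covariance equal-weight components
  params <- endotyper:::new_mixture_params(
    2, c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
    list(diag(2), diag(2)))
  mid <- posterior_probs(params, rbind(c(0, 0)))
  expect_equal(as.numeric(mid), c(0.5, 0.5))
  # a point at one mean with the other component far away
  far <- endotyper:::new_mixture_params(
    2, c(0.5, 0.5), rbind(c(0, 0), c(20, 0)),
    list(diag(2), diag(2)))
  expect_gt(posterior_probs(far, rbind(c(0, 0)))[1, 1], 0.99)
})

test_that("cluster indices match hand-computed values", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(x, labels), 200)
  expect_equal(davies_bouldin(x, labels), 0.1)
  # translation invariance / count invariance
  expect_equal(calinski_harabasz(x + 100, labels), 200)
  expect_equal(davies_bouldin(rbind(x, x), c(labels, labels)), 0.1)
  # degenerate cases
  expect_error(calinski_harabasz(x, rep(1, 4)), "at least 2")
  expect_error(calinski_harabasz(matrix(c(1, 1, 2, 2), ncol = 1),
                                 c(1, 1, 2, 2)), "zero")
  expect_error(davies_bouldin(matrix(c(0, 1, 0, 1), ncol = 1),
                              c(1, 1, 2, 2)), "coincident")
})

test_that("indices agree with brute-force evaluation on random instances", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 2), ncol = 2)
    labels <- sample(rep(seq_len(k), length.out = n))
    expect_equal(calinski_harabasz(x, labels), oracle_ch(x, labels),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(x, labels), oracle_db(x, labels),
                 tolerance = 1e-9)
  }
})

test_that("cluster-count selection recovers planted component counts", {
  set.seed(19)
  centers <- rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7))
  for (k_true in 2:3) {
    x <- do.call(rbind, lapply(seq_len(k_true), function(j)
      MASS::mvrnorm(700, centers[j, ], diag(2) * 0.5)))
    ks <- select_k(x, 2:6, seed = k_true, n_restarts = 3)
    expect_equal(ks$selected, k_true)
    expect_true(ks$agreement)
  }
  expect_error(select_k(matrix(rnorm(100), ncol = 2), k_range = 1:3),
               "2..10")
})

test_that("k-means agrees with the mixture model on separated clusters", {
  p <- planted_two(n = 6000)
  fit <- fit_gmm(p$x, 2, seed = 4, n_restarts = 3)
  km <- fit_kmeans(p$x, 2, seed = 4, n_restarts = 3)
  expect_gt(mclust::adjustedRandIndex(
    endotyper:::hard_assign(fit, p$x), km$labels), 0.9)
  # k = 1 closed form
  km1 <- fit_kmeans(p$x, 1, seed = 1)
  expect_equal(as.numeric(km1$centers), colMeans(p$x), tolerance = 1e-9)
  # determinism
  km2 <- fit_kmeans(p$x, 2, seed = 4, n_restarts = 3)
  expect_identical(km$labels, km2$labels)
})

test_that("mixture fitting validates k against the sample size", {
  x <- matrix(rnorm(60), ncol = 2)
  expect_error(fit_gmm(x, 0), "k")
  expect_error(fit_gmm(x, 4), "k")  # 4 > 30/10
})
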