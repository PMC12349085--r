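test_that("k-means handles the degenerate and planted cases", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  k1 <- kmeans_cluster(x, 1, seed = 1)
  expect_equal(unique(k1$labels), 1L)
  expect_equal(k1$diagnostics$inertia,
               sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)

  kn <- kmeans_cluster(x, nrow(x), seed = 1)
  expect_equal(kn$diagnostics$inertia, 0, tolerance = 1e-10)
  expect_error(kmeans_cluster(x, 99), "exceeds")

  # two blobs separated by 10 sd: perfect recovery
  blobs <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
                 matrix(rnorm(60, 10, 1), 30, 2))
  truth <- rep(1:2, each = 30)
  km <- kmeans_cluster(blobs, 2, seed = 3)
  expect_equal(match_labels(km$labels, truth)$agreement, 1)

  # deterministic given the seed
  expect_identical(kmeans_cluster(blobs, 2, seed = 5)$labels,
                   kmeans_cluster(blobs, 2, seed = 5)$labels)
})

test_that("Ward clustering matches a Lance-Williams oracle on 4 points", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  w <- ward_cluster(x, 2)
  expect_equal(match_labels(w$labels, c(1, 1, 2, 2))$agreement, 1)

  # independent ward.D2 recursion: D(ij,k)^2 =
  # ((n_i+n_k) d_ik^2 + (n_j+n_k) d_jk^2 - n_k d_ij^2) / (n_i+n_j+n_k)
  d <- as.matrix(dist(x))
  # step 1: merge {1,2} at height d(1,2) = 1; step 2: {3,4} at 1
  h1 <- d[1, 2]
  h2 <- d[3, 4]
  d2_12_3 <- ((1 + 1) * d[1, 3]^2 + (1 + 1) * d[2, 3]^2 - 1 * d[1, 2]^2) / 3
  d2_12_4 <- ((1 + 1) * d[1, 4]^2 + (1 + 1) * d[2, 4]^2 - 1 * d[1, 2]^2) / 3
  d2_final <- ((2 + 1) * d2_12_3 + (2 + 1) * d2_12_4 - 2 * d[3, 4]^2) / 4
  h3 <- sqrt(d2_final)
  expect_equal(sort(w$diagnostics$merge_heights), sort(c(h1, h2, h3)),
               tolerance = 1e-10)

  expect_true(all(diff(w$diagnostics$merge_heights) >= -1e-10))
  singletons <- ward_cluster(x, 4)
  expect_equal(sort(unique(singletons$labels)), 1:4)

  set.seed(9)
  pairs <- rbind(matrix(rnorm(4, 0, 0.01), 2, 2),
                 matrix(rnorm(4, 5, 0.01), 2, 2))
  wp <- ward_cluster(pairs, 2)
  expect_equal(match_labels(wp$labels, c(1, 1, 2, 2))$agreement, 1)
})

test_that("label matching is exact for permuted labels and calibrated for noise", {
  truth <- rep(1:3, each = 10)
  perm <- c(3L, 1L, 2L)[truth]
  m <- match_labels(perm, truth)
  expect_equal(m$agreement, 1)

  single <- match_labels(c(rep(1, 7), rep(2, 3)), rep(1, 10))
  expect_equal(single$agreement, 0.7)  # max predicted cluster share

  set.seed(14)
  n <- 4000
  rnd <- match_labels(sample(1:2, n, replace = TRUE),
                      sample(1:2, n, replace = TRUE))
  expect_equal(rnd$agreement, 0.5, tolerance = 0.05)
})

test_that("mixture free-parameter counts match hand counts (d = 2, k = 2)", {
  expect_equal(gmm_n_params("EII", 2, 2), 2 * 2 + 2 - 1 + 1)        # 6
  expect_equal(gmm_n_params("EEE", 2, 2), 2 * 2 + 2 - 1 + 3)        # 8
  expect_equal(gmm_n_params("EEV", 2, 2),
               2 * 2 + 2 - 1 + (3 + (2 - 1) * 1))                   # 9
  expect_equal(gmm_n_params("VVV", 2, 2), 2 * 2 + 2 - 1 + 2 * 3)    # 11
  # EEV general form: d(d+1)/2 shared + (k-1) d(d-1)/2 extra rotations
  for (d in 2:4) for (k in 1:3) {
    expect_equal(gmm_n_params("EEV", k, d),
                 (k - 1) + k * d + d * (d + 1) / 2 +
                   (k - 1) * d * (d - 1) / 2)
  }
})

test_that("single-component BIC equals the analytic Gaussian MLE formula", {
  set.seed(16)
  x <- matrix(rnorm(200 * 3), 200, 3)
  fit <- xrfmorph:::gmm_fit(x, 1, "VVV", n_init = 1, seed = 1)
  n <- nrow(x); d <- ncol(x)
  S_mle <- cov(x) * (n - 1) / n
  ll <- -n / 2 * (d * log(2 * pi) + determinant(S_mle)$modulus[1] + d)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  p <- d + d * (d + 1) / 2
  expect_equal(fit$bic, 2 * ll - p * log(n), tolerance = 1e-6)
})

test_that("BIC selects one component for single-Gaussian data", {
  set.seed(18)
  x <- matrix(rnorm(400), 200, 2)
  res <- gmm_cluster_bic(x, k_range = 1:2, seed = 2)
  expect_equal(res$k, 1L)
  expect_equal(unname(rowSums(res$posterior)), rep(1, 200),
               tolerance = 1e-10)
})

test_that("EM log-likelihood is non-decreasing for every family", {
  set.seed(20)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  for (fam in c("EII", "EEE", "EEV", "VVV")) {
    fit <- xrfmorph:::gmm_fit(x, 2, fam, n_init = 2, seed = 3)
    expect_true(all(diff(fit$ll_trace) >= -1e-8 * (1 + abs(fit$loglik))),
                info = fam)
  }
})

test_that("EEV beats VVV by BIC on data generated under the EEV constraint", {
  set.seed(22)
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sig <- function(a) rot(a) %*% diag(c(4, 1)) %*% t(rot(a))
  rmvn <- function(n, mu, S) {
    sweep(matrix(rnorm(2 * n), n, 2) %*% chol(S), 2, mu, `+`)
  }
  x <- rbind(rmvn(200, c(-6, 0), sig(0)), rmvn(200, c(6, 0), sig(pi / 3)))
  res <- gmm_cluster_bic(x, k_range = 2, families = c("EEV", "VVV"),
                         seed = 4)
  tab <- res$bic_table
  expect_gte(tab$bic[tab$family == "EEV"], tab$bic[tab$family == "VVV"])
})

test_that("the in-package EM agrees with an independent mixture implementation", {
  set.seed(24)
  x <- rbind(matrix(rnorm(160, 0, 1), 80, 2),
             sweep(matrix(rnorm(160, 0, 1), 80, 2) %*%
                     chol(matrix(c(4, 1.5, 1.5, 2), 2, 2)), 2,
                   c(8, 8), `+`))
  ours <- xrfmorph:::gmm_fit(x, 2, "EEV", n_init = 4, seed = 5)
  withr::local_package("mclust")
  mc <- mclust::Mclust(x, G = 2, modelNames = "EEV", verbose = FALSE)
  # same BIC convention (2 loglik - p log n); well separated clusters, so
  # both EMs should find the same optimum
  expect_equal(ours$df, mclust::nMclustParams("EEV", d = 2, G = 2))
  expect_equal(ours$loglik, mc$loglik, tolerance = 1e-3)
  expect_equal(ours$bic, as.numeric(mc$BIC), tolerance = 1e-2)
  expect_equal(match_labels(max.col(ours$posterior), mc$classification)
               $agreement, 1)
})

test_that("GMM separates the planted sediment-like gradient group where k-means may not", {
  # two populations: one elongated along a gradient, one compact
  set.seed(26)
  t_grad <- runif(120)
  grad <- cbind(-4 + 14 * t_grad, -3 + 9 * t_grad) +
    matrix(rnorm(240, 0, 0.6), 120, 2)
  compact <- matrix(rnorm(160, 0, 0.8), 80, 2)
  compact <- sweep(compact, 2, c(7, -3), `+`)
  x <- rbind(grad, compact)
  truth <- rep(1:2, c(120, 80))
  g <- gmm_cluster_bic(x, k_range = 2, seed = 6)
  expect_gte(match_labels(g$labels, truth)$agreement, 0.95)
})
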