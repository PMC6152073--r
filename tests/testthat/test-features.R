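test_that("bi-gram vector has 400 entries and handles degenerate lengths", {
  p <- gen_pssm(12, seed = 1)
  v <- bigram_features(p)
  expect_length(v, 400L)
  expect_identical(attr(v, "protein_id"), p$protein_id)

  p1 <- pssm(matrix(1, 1, 20), "single")
  expect_identical(unname(as.vector(bigram_features(p1))), rep(0, 400L))

  # uniform entries c over L rows give (L-1) c^2 everywhere
  pu <- pssm(matrix(0.5, 3, 20), "uniform", normalization = "sigmoid")
  expect_equal(unname(as.vector(bigram_features(pu))), rep(0.5, 400L))
})

test_that("vectorized bi-gram computation matches the brute-force oracle", {
  p <- normalize_pssm(gen_pssm(5, seed = 42), "sigmoid")
  expect_equal(unname(as.vector(bigram_features(p))),
               bigram_oracle(p$scores), tolerance = 1e-12)
})

test_that("bi-gram flattening is row-major over (from, to) transitions", {
  # put mass only on transition A(1) -> R(2): rows (e1, e2)
  m <- matrix(0, 2, 20); m[1, 1] <- 1; m[2, 2] <- 1
  v <- as.vector(bigram_features(pssm(m, "ar")))
  expect_identical(which(v != 0), 2L)         # u = 20*(1-1) + 2
  # and R(2) -> A(1) lands at u = 20*(2-1) + 1
  m2 <- matrix(0, 2, 20); m2[1, 2] <- 1; m2[2, 1] <- 1
  expect_identical(which(as.vector(bigram_features(pssm(m2, "ra"))) != 0), 21L)
})

test_that("bi-gram features scale quadratically and commute with column permutation", {
  p <- normalize_pssm(gen_pssm(8, seed = 9), "sigmoid")
  v <- as.vector(bigram_features(p))
  p3 <- pssm(3 * p$scores, "scaled")
  expect_equal(as.vector(bigram_features(p3)), 9 * v, tolerance = 1e-10)

  perm <- withr::with_seed(4, sample(20L))
  pp <- pssm(p$scores[, perm], "permuted")
  vp <- as.vector(bigram_features(pp))
  u_of <- function(m, n) 20L * (m - 1L) + n
  for (m in c(1L, 7L, 20L)) for (n in c(2L, 13L)) {
    expect_equal(vp[u_of(m, n)], v[u_of(perm[m], perm[n])], tolerance = 1e-12)
  }
})

test_that("PCA reduces dimension, orders variance, and is orthonormal", {
  X <- withr::with_seed(10, matrix(rnorm(60 * 8), 60, 8))
  pm <- fit_pca(X, 5)
  expect_identical(dim(transform_pca(pm, X)), c(60L, 5L))
  expect_true(all(diff(pm$explained_variance) <= 1e-12))
  expect_equal(pm$components %*% t(pm$components), diag(5), tolerance = 1e-8)
})

test_that("PCA recovers an exact low-dimensional affine subspace", {
  basis <- withr::with_seed(2, qr.Q(qr(matrix(rnorm(10 * 3), 10, 3))))
  Z <- withr::with_seed(3, matrix(rnorm(40 * 3), 40, 3))
  X <- Z %*% t(basis) + rep(1, 40) %o% runif(10)
  pm <- fit_pca(X, 3)
  Xr <- transform_pca(pm, X) %*% pm$components + rep(1, 40) %o% pm$mean
  expect_equal(Xr, X, tolerance = 1e-8)
})

test_that("PCA matches the closed-form eigendecomposition on toy data", {
  # 2-d data with covariance ~ diag(9, 1): first axis dominates
  X <- withr::with_seed(5, cbind(3 * rnorm(4000), rnorm(4000)))
  pm <- fit_pca(X, 2)
  expect_equal(abs(pm$components[1, ]), c(1, 0), tolerance = 1e-2)
  # sign convention: largest-magnitude loading positive
  expect_true(pm$components[1, which.max(abs(pm$components[1, ]))] > 0)

  # direct covariance eigendecomposition oracle, up to per-component sign
  Y <- withr::with_seed(6, matrix(rnorm(20 * 5), 20, 5))
  pm2 <- fit_pca(Y, 2)
  eg <- eigen(stats::cov(Y), symmetric = TRUE)
  for (j in 1:2) {
    dot <- sum(pm2$components[j, ] * eg$vectors[, j])
    expect_equal(abs(dot), 1, tolerance = 1e-8)
    expect_equal(pm2$explained_variance[j], eg$values[j], tolerance = 1e-8)
  }
})

test_that("PCA transform centers the data and preserves geometry at full rank", {
  X <- withr::with_seed(7, matrix(rnorm(30 * 4), 30, 4))
  pm <- fit_pca(X, 4)
  expect_equal(drop(transform_pca(pm, matrix(pm$mean, 1))), rep(0, 4),
               tolerance = 1e-12)
  Z <- transform_pca(pm, X)
  expect_equal(as.matrix(dist(Z)), as.matrix(dist(X)), tolerance = 1e-8)
  Xr <- Z %*% pm$components + rep(1, 30) %o% pm$mean
  expect_equal(Xr, X, tolerance = 1e-6)
})

test_that("PCA errors are informative", {
  X <- matrix(rnorm(10 * 5), 10, 5)
  expect_error(fit_pca(X[1:4, ], 4), "lower n_components")
  expect_error(fit_pca(X, 10), "n_components")
  expect_error(fit_pca(X, 0), "n_components")
  pm <- fit_pca(X, 2)
  expect_error(transform_pca(pm, matrix(0, 2, 4)), "does not match")
})

test_that("feature CSV and PCA JSON round-trip", {
  X <- withr::with_seed(8, matrix(rnorm(6 * 4), 6, 4))
  ids <- sprintf("p%02d", 1:6)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(X, ids, csv)
  back <- read_feature_csv(csv)
  expect_identical(back$ids, ids)
  expect_equal(unname(back$X), X, tolerance = 1e-12)

  pm <- fit_pca(X, 2)
  js <- withr::local_tempfile(fileext = ".json")
  write_pca_json(pm, js)
  pm2 <- read_pca_json(js)
  expect_equal(pm2$components, pm$components, tolerance = 1e-12)
  expect_equal(transform_pca(pm2, X), transform_pca(pm, X), tolerance = 1e-10)
})
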