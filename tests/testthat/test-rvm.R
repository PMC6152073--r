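test_that("kernel values match their closed forms", {
  kp <- kernel_spec("poly2", 1)
  expect_equal(kernel_value(kp, rep(0, 3), rep(0, 3)), 1)
  expect_equal(kernel_value(kp, c(1, 1), c(1, 1)), 9)       # (1 + 2)^2
  expect_equal(kernel_value(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  kr <- kernel_spec("rbf", 2)
  expect_equal(kernel_value(kr, c(1, 5), c(1, 5)), 1)
  expect_equal(kernel_value(kr, c(0, 0), c(2, 0)), exp(-4 / 8))
  expect_error(kernel_value(kp, 1:2, 1:3), "same dimension")
  expect_error(kernel_spec("poly2", 0), "positive")
})

test_that("design matrix has the bias column and matches the entrywise oracle", {
  k <- kernel_spec("poly2", 1)
  X <- withr::with_seed(1, matrix(rnorm(8), 4, 2))
  B <- withr::with_seed(2, matrix(rnorm(6), 3, 2))
  phi <- design_matrix(k, X, B)
  expect_identical(dim(phi), c(4L, 4L))
  expect_equal(phi, design_oracle(k, X, B), tolerance = 1e-12)

  expect_identical(dim(design_matrix(k, X)), c(4L, 5L))     # N x (N+1)
  expect_equal(design_matrix(k, matrix(0, 1, 2)), matrix(c(1, 1), 1))
  expect_error(design_matrix(k, X[0, , drop = FALSE]), "non-empty")

  for (kn in c("linear", "rbf")) {
    ks <- kernel_spec(kn, 1.5)
    expect_equal(design_matrix(ks, X, B), design_oracle(ks, X, B),
                 tolerance = 1e-12)
  }
})

test_that("posterior matches the dense textbook evaluation", {
  phi <- withr::with_seed(3, matrix(rnorm(12), 3, 4))
  t <- c(0, 1, 1)
  alpha <- c(0.5, 1, 2, 0.1)
  post <- rvm_posterior(phi, t, alpha, sigma2 = 0.3)
  oracle <- posterior_oracle(phi, t, alpha, 0.3)
  expect_equal(post$Sigma, oracle$Sigma, tolerance = 1e-8)
  expect_equal(post$u, oracle$u, tolerance = 1e-8)
  # defining equations hold directly
  A <- diag(alpha)
  expect_equal(post$Sigma %*% (crossprod(phi) / 0.3 + A), diag(4),
               tolerance = 1e-8)
})

test_that("posterior limits: infinite precision kills weights, flat prior interpolates", {
  phi <- withr::with_seed(4, matrix(rnorm(9), 3, 3))
  t <- c(1, 0, 1)
  u_inf <- rvm_posterior(phi, t, rep(1e12, 3), 1)$u
  expect_equal(u_inf, rep(0, 3), tolerance = 1e-6)

  u_flat <- rvm_posterior(phi, t, rep(0, 3), 1e-8)$u
  expect_equal(drop(phi %*% u_flat), t, tolerance = 1e-6)
})

test_that("with equal fixed alpha the posterior mean is the ridge solution", {
  for (seed in 1:5) {
    phi <- withr::with_seed(seed, matrix(rnorm(24), 6, 4))
    t <- withr::with_seed(seed + 100, rbinom(6, 1, 0.5))
    a <- 0.7; s2 <- 0.4
    u <- rvm_posterior(phi, t, rep(a, 4), s2)$u
    lambda <- a * s2
    u_ridge <- solve(crossprod(phi) + lambda * diag(4), crossprod(phi, t))
    expect_equal(u, drop(u_ridge), tolerance = 1e-8)
  }
})

test_that("RVM separates blobs sparsely with valid internal state", {
  d <- blob_data(20, seed = 7)            # n = 40, centers (-3,-3)/(3,3)
  m <- rvm_fit(d$X, d$labels)
  expect_true(m$converged)
  expect_identical(rvm_classify(m, d$X), d$labels)
  expect_lt(nrow(m$relevance_vectors), nrow(d$X))
  expect_true(all(m$gamma >= 0 & m$gamma <= 1))
  expect_gt(m$sigma2_final, 0)
  expect_true(all(m$alpha_final < rvm_control()$alpha_prune))
})

test_that("log evidence is non-decreasing across accepted iterations", {
  d <- blob_data(20, seed = 7)
  m <- rvm_fit(d$X, d$labels)
  expect_gt(length(m$evidence), 3)
  expect_true(all(diff(m$evidence) >= -1e-6))
  # also on less separated data
  d2 <- gen_two_class_features(15, 3, separation = 2, seed = 21)
  m2 <- suppressWarnings(rvm_fit(d2$X, d2$labels))
  expect_true(all(diff(m2$evidence) >= -1e-6))
})

test_that("duplicated training points leave the decision unchanged", {
  d <- blob_data(20, seed = 7)
  m1 <- rvm_fit(d$X, d$labels)
  m2 <- rvm_fit(rbind(d$X, d$X), c(d$labels, d$labels))
  # duplicates sharpen the Gaussian evidence, so scores shift slightly;
  # the decision function is stable and classifications identical
  expect_lt(max(abs(rvm_predict(m1, d$X) - rvm_predict(m2, d$X))), 0.05)
  expect_identical(rvm_classify(m1, d$X), rvm_classify(m2, d$X))
})

test_that("pruned model predicts like the unpruned model with pinned alphas", {
  d <- blob_data(20, seed = 7)
  m <- rvm_fit(d$X, d$labels)
  prune <- rvm_control()$alpha_prune
  # rebuild the full-basis posterior with pruned alphas pinned at the
  # prune threshold and surviving alphas at their converged values
  alpha_full <- rep(prune, nrow(d$X) + 1L)
  active <- c(if (m$has_bias) 1L, m$rv_index + 1L)
  alpha_full[active] <- m$alpha_final
  phi <- design_matrix(m$kernel, d$X, d$X)
  post <- rvm_posterior(phi, d$labels, alpha_full, m$sigma2_final)
  y_pinned <- drop(phi %*% post$u)
  expect_equal(rvm_predict(m, d$X), y_pinned, tolerance = 1e-4)
})

test_that("one iteration with fixed alpha reduces to the posterior", {
  d <- blob_data(10, seed = 7)
  n <- nrow(d$X)
  ctl <- rvm_control(max_iter = 1, tol = 1e-3, init_sigma2 = 0.025)
  m <- suppressWarnings(rvm_fit(d$X, d$labels, control = ctl))
  phi <- design_matrix(kernel_spec("poly2", 1), d$X, d$X)
  post <- rvm_posterior(phi, d$labels, rep(1 / n, n + 1L), 0.025)
  expect_equal(c(m$bias, m$weights), post$u, tolerance = 1e-10)
  # and the posterior itself agrees with the dense oracle at this scale
  oracle <- posterior_oracle(phi, d$labels, rep(1 / n, n + 1L), 0.025)
  expect_equal(post$u, oracle$u, tolerance = 1e-5)
  expect_identical(m$n_iter, 1L)
  expect_false(m$converged)
})

test_that("fitting is deterministic and input checks fire", {
  d <- blob_data(10, seed = 7)
  m1 <- rvm_fit(d$X, d$labels)
  m2 <- rvm_fit(d$X, d$labels)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$evidence, m2$evidence)

  expect_error(rvm_fit(d$X, rep(1, nrow(d$X))), "single class")
  expect_error(rvm_fit(d$X[1, , drop = FALSE], 1), "at least 2")
  expect_error(rvm_fit(d$X, c(2, rep(0, nrow(d$X) - 1))), "0/1")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(rvm_fit(Xna, d$labels), "NA/Inf")
})

test_that("prediction expands the kernel weight sum and thresholds correctly", {
  k <- kernel_spec("poly2", 1)
  rv <- matrix(c(0, 0, 1, 1, -1, 2), 3, 2, byrow = TRUE)
  w <- c(0.3, -0.2, 0.5)
  m <- rvm_model(k, rv, w, bias = 0.1)
  x <- c(0.5, -0.5)
  manual <- 0.1 + sum(w * vapply(1:3, function(j)
    kernel_value(k, x, rv[j, ]), numeric(1)))
  expect_equal(rvm_predict(m, x), manual, tolerance = 1e-12)

  m0 <- rvm_model(k, rv, rep(0, 3), bias = 0)
  expect_equal(rvm_predict(m0, matrix(rnorm(8), 4, 2)), rep(0, 4))
  mb <- rvm_model(k, matrix(0, 0, 2), numeric(0), bias = 0.7)
  expect_equal(rvm_predict(mb, matrix(rnorm(6), 3, 2)), rep(0.7, 3))

  # threshold semantics: label 1 iff score >= threshold
  for (sc in list(c(0.2, 0), c(0.5, 1), c(0.9, 1))) {
    mm <- rvm_model(k, matrix(0, 0, 1), numeric(0), bias = sc[1])
    expect_identical(rvm_classify(mm, matrix(0, 1, 1)), as.integer(sc[2]))
  }
  m_t0 <- rvm_model(k, matrix(0, 0, 1), numeric(0), bias = 0.2, threshold = 0)
  expect_identical(rvm_classify(m_t0, matrix(0, 2, 1)), c(1L, 1L))
  # thresholding is a pure composition of predict and >=
  d <- blob_data(10, seed = 7)
  mf <- rvm_fit(d$X, d$labels)
  expect_identical(rvm_classify(mf, d$X),
                   as.integer(rvm_predict(mf, d$X) >= mf$threshold))
  expect_error(rvm_predict(mf, matrix(0, 2, 5)), "dimension")
})

test_that("RVM JSON serialization round-trips predictions", {
  d <- blob_data(15, seed = 12)
  m <- rvm_fit(d$X, d$labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_rvm_json(m, path)
  m2 <- read_rvm_json(path)
  expect_equal(rvm_predict(m2, d$X), rvm_predict(m, d$X), tolerance = 1e-12)
  expect_identical(m2$kernel$name, m$kernel$name)
  expect_equal(m2$threshold, m$threshold)
})
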