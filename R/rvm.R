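#' Kernel specification
#'
#' Kernels available for the relevance vector machine. `poly2` is the
#' inhomogeneous degree-2 polynomial \eqn{(1 + x \cdot z / w)^2} (the
#' pipeline default, width w = 1); `linear` is the plain dot product;
#' `rbf` is the Gaussian \eqn{\exp(-\|x-z\|^2 / (2 w^2))}.
#'
#' @param name one of `"poly2"`, `"linear"`, `"rbf"`.
#' @param width positive kernel width (default 1).
#' @return object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(name = c("poly2", "linear", "rbf"), width = 1) {
  name <- match.arg(name)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("'width' must be a single positive number")
  structure(list(name = name, width = as.numeric(width)), class = "kernel_spec")
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param k a `"kernel_spec"`.
#' @param x,z numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_value <- function(k, x, z) {
  stopifnot(inherits(k, "kernel_spec"))
  if (length(x) != length(z))
    stop("kernel inputs must have the same dimension (", length(x),
         " vs ", length(z), ")")
  switch(k$name,
         linear = sum(x * z),
         poly2  = (1 + sum(x * z) / k$width)^2,
         rbf    = exp(-sum((x - z)^2) / (2 * k$width^2)))
}

# Gram matrix K[i, j] = k(X[i, ], B[j, ]), vectorized.
kernel_matrix <- function(k, X, B) {
  X <- as.matrix(X); B <- as.matrix(B)
  if (ncol(X) != ncol(B))
    stop("kernel inputs must have the same dimension (", ncol(X),
         " vs ", ncol(B), ")")
  G <- tcrossprod(X, B)
  switch(k$name,
         linear = G,
         poly2  = (1 + G / k$width)^2,
         rbf    = {
           d2 <- outer(rowSums(X^2), rowSums(B^2), "+") - 2 * G
           exp(-pmax(d2, 0) / (2 * k$width^2))
         })
}

#' Kernel design matrix with bias column
#'
#' Builds the n x (m+1) design matrix whose first column is all ones (the
#' bias basis function) and whose (i, j+1) entry is k(x_i, b_j) for basis
#' points b_j (the training inputs, during fitting).
#'
#' @param k a `"kernel_spec"`.
#' @param X n x d query inputs.
#' @param B m x d basis inputs (defaults to `X`).
#' @return numeric matrix of dimension n x (m+1).
#' @export
design_matrix <- function(k, X, B = X) {
  X <- as.matrix(X); B <- as.matrix(B)
  if (nrow(X) < 1L || nrow(B) < 1L)
    stop("design_matrix requires non-empty inputs")
  cbind(1, kernel_matrix(k, X, B))
}

#' RVM training configuration
#'
#' @param init_alpha initial weight-precision: the rule `"1/N"` (default,
#'   every alpha starts at 1/number-of-training-samples) or a single
#'   positive number.
#' @param init_sigma2 initial noise variance; `NULL` (default) uses
#'   `max(0.1 * var(t), 1e-3)`, keeping the variance update active from a
#'   non-degenerate start.
#' @param max_iter maximum number of hyperparameter iterations.
#' @param alpha_prune basis functions with alpha above this are pruned
#'   each iteration (default 1e12).
#' @param tol convergence tolerance on max |delta log alpha| (default 1e-3).
#' @return object of class `"rvm_control"`.
#' @export
rvm_control <- function(init_alpha = "1/N", init_sigma2 = NULL,
                        max_iter = 1000L, alpha_prune = 1e12, tol = 1e-3) {
  if (!(identical(init_alpha, "1/N") ||
        (is.numeric(init_alpha) && length(init_alpha) == 1L && init_alpha > 0)))
    stop("'init_alpha' must be the rule \"1/N\" or a positive number")
  if (!is.null(init_sigma2) && (!is.numeric(init_sigma2) || init_sigma2 <= 0))
    stop("'init_sigma2' must be NULL or a positive number")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (!is.numeric(alpha_prune) || alpha_prune <= 0) stop("'alpha_prune' must be > 0")
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  structure(list(init_alpha = init_alpha, init_sigma2 = init_sigma2,
                 max_iter = max_iter, alpha_prune = alpha_prune, tol = tol),
            class = "rvm_control")
}

#' Posterior over RVM weights at fixed hyperparameters
#'
#' For the Gaussian-likelihood model with design matrix phi, 0/1 targets
#' t, weight precisions alpha and noise variance sigma2, the weight
#' posterior is Gaussian with
#' \deqn{\Sigma = (\sigma^{-2}\phi^\top\phi + A)^{-1}, \quad
#'       u = \sigma^{-2}\Sigma\phi^\top t, \quad A = diag(\alpha).}
#' Computed via a Cholesky solve; a jitter of 1e-10 * trace/m is added
#' once on near-singular systems before failing.
#'
#' @param phi n x m design matrix.
#' @param t numeric target vector of length n.
#' @param alpha non-negative precision vector of length m.
#' @param sigma2 positive noise variance.
#' @return list with `Sigma` (m x m posterior covariance) and `u`
#'   (posterior mean weights).
#' @export
rvm_posterior <- function(phi, t, alpha, sigma2) {
  phi <- as.matrix(phi)
  t <- as.numeric(t)
  m <- ncol(phi)
  if (length(t) != nrow(phi)) stop("length(t) must equal nrow(phi)")
  if (length(alpha) != m) stop("length(alpha) must equal ncol(phi)")
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  H <- crossprod(phi) / sigma2
  diag(H) <- diag(H) + alpha
  R <- tryCatch(chol(H), error = function(e) {
    jit <- 1e-10 * sum(diag(H)) / m
    tryCatch(chol(H + diag(jit, m)), error = function(e2)
      stop("posterior system numerically singular beyond jitter tolerance ",
           "(reciprocal condition ~ ", format(rcond(H), digits = 3), ")"))
  })
  Sigma <- chol2inv(R)
  u <- drop(Sigma %*% crossprod(phi, t)) / sigma2
  list(Sigma = Sigma, u = u)
}

# Log marginal likelihood (evidence) log p(t | alpha, sigma2) of the
# Gaussian model with Omega = sigma2 I + phi A^-1 phi^T, evaluated
# through the weight-space quantities (Woodbury identities):
#   log|Omega| = N log sigma2 - log|Sigma| - sum(log alpha)
#   t' Omega^-1 t = (t'(t - phi u)) / sigma2
# which avoids factorizing the N x N covariance directly and stays
# stable for the ill-conditioned Gram matrices poly2 produces.
rvm_log_evidence <- function(phi, t, alpha, sigma2) {
  n <- nrow(phi); m <- ncol(phi)
  H <- crossprod(phi) / sigma2
  diag(H) <- diag(H) + alpha
  R <- tryCatch(chol(H), error = function(e)
    chol(H + diag(1e-10 * sum(diag(H)) / m, m)))
  logdet_Sigma <- -2 * sum(log(diag(R)))
  u <- backsolve(R, backsolve(R, crossprod(phi, t), transpose = TRUE)) / sigma2
  quad <- sum(t * (t - phi %*% u)) / sigma2
  -0.5 * (n * log(2 * pi) + n * log(sigma2) - logdet_Sigma -
            sum(log(alpha)) + quad)
}

#' Fit a relevance vector machine
#'
#' Sparse Bayesian kernel classifier trained on 0/1 labels with a
#' Gaussian likelihood. Each weight w_i carries an independent zero-mean
#' Gaussian prior of precision alpha_i; type-II maximum likelihood
#' iterates
#' \enumerate{
#'   \item weight posterior (Sigma, u) at the current (alpha, sigma2)
#'     (see [rvm_posterior()]);
#'   \item gamma_i = 1 - alpha_i Sigma_ii (well-determinedness of w_i);
#'   \item alpha_i <- gamma_i / u_i^2;
#'   \item sigma2 <- ||t - phi u||^2 / (N - sum(gamma)),
#' }
#' until max |delta log alpha| < `tol` or `max_iter`. Basis functions
#' whose alpha exceeds `alpha_prune` are removed each iteration; the
#' training points whose kernel basis functions survive are the relevance
#' vectors. The evidence log p(t | alpha, sigma2) is recorded per
#' iteration in the returned model for diagnostics.
#'
#' @param X n x d training inputs (n >= 2, no NA/Inf).
#' @param t 0/1 labels; both classes must be present.
#' @param kernel a `"kernel_spec"` (default degree-2 polynomial, width 1).
#' @param control an `"rvm_control"`.
#' @param threshold decision cutoff on the continuous score (default 0.5).
#' @return object of class `"rvm"`: `relevance_vectors`, `weights`,
#'   `bias`, `has_bias`, `rv_index` (training-row indices), `kernel`,
#'   `alpha_final`, `sigma2_final`, `gamma`, `threshold`, `n_iter`,
#'   `converged`, `evidence` (log-evidence trace).
#' @examples
#' set.seed(7)
#' X <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' t <- rep(c(0, 1), each = 10)
#' m <- rvm_fit(X, t)
#' mean(rvm_classify(m, X) == t)
#' @export
rvm_fit <- function(X, t, kernel = kernel_spec("poly2", 1),
                    control = rvm_control(), threshold = 0.5) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  t <- as.numeric(t)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training samples")
  if (length(t) != n) stop("length(t) must equal nrow(X)")
  if (!all(t %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(t)) < 2L)
    stop("training labels contain a single class; both classes are required")
  if (anyNA(X) || any(!is.finite(X))) stop("training inputs contain NA/Inf")

  phi_full <- design_matrix(kernel, X, X)          # n x (n+1), col 1 = bias
  M <- n + 1L
  alpha_full <- rep(if (identical(control$init_alpha, "1/N")) 1 / n
                    else control$init_alpha, M)
  sigma2 <- control$init_sigma2 %||% max(0.1 * stats::var(t), 1e-3)
  active <- seq_len(M)
  evidence <- numeric(0L)
  converged <- FALSE
  n_iter <- 0L
  post <- NULL

  for (it in seq_len(control$max_iter)) {
    n_iter <- it
    phi <- phi_full[, active, drop = FALSE]
    a <- alpha_full[active]
    post <- rvm_posterior(phi, t, a, sigma2)
    evidence <- c(evidence, rvm_log_evidence(phi, t, a, sigma2))
    if (it == control$max_iter) break
    u <- post$u
    # gamma lies in (0, 1) in exact arithmetic; keep it off exact 0 so
    # the alpha update cannot produce an improper zero precision
    gam <- pmin(pmax(1 - a * diag(post$Sigma), 1e-12), 1)
    a_new <- ifelse(u == 0, Inf, gam / u^2)
    resid2 <- sum((t - drop(phi %*% u))^2)
    sigma2 <- max(resid2 / max(n - sum(gam), 1e-6), 1e-10)
    keep <- a_new <= control$alpha_prune
    delta <- if (any(keep)) max(abs(log(a_new[keep]) - log(a[keep]))) else 0
    alpha_full[active] <- a_new
    active <- active[keep]
    if (length(active) == 0L) break
    if (delta < control$tol) {
      phi <- phi_full[, active, drop = FALSE]
      post <- rvm_posterior(phi, t, alpha_full[active], sigma2)
      evidence <- c(evidence,
                    rvm_log_evidence(phi, t, alpha_full[active], sigma2))
      converged <- TRUE
      break
    }
  }

  if (length(active) == 0L) {
    warning("all basis functions were pruned; returning an empty model")
    return(rvm_model(kernel, X[0L, , drop = FALSE], numeric(0L), bias = 0,
                     has_bias = FALSE, threshold = threshold,
                     rv_index = integer(0L), alpha_final = numeric(0L),
                     sigma2_final = sigma2, gamma = numeric(0L),
                     n_iter = n_iter, converged = FALSE, evidence = evidence))
  }
  if (!converged)
    warning("RVM did not converge within max_iter = ", control$max_iter,
            "; returning the final iterate")

  gam_final <- pmin(pmax(1 - alpha_full[active] * diag(post$Sigma), 0), 1)
  has_bias <- 1L %in% active
  rv_idx <- setdiff(active, 1L) - 1L
  w <- post$u
  bias <- if (has_bias) w[match(1L, active)] else 0
  weights <- w[match(setdiff(active, 1L), active)]
  rvm_model(kernel, X[rv_idx, , drop = FALSE], weights, bias = bias,
            has_bias = has_bias, threshold = threshold, rv_index = rv_idx,
            alpha_final = alpha_full[active], sigma2_final = sigma2,
            gamma = gam_final, n_iter = n_iter, converged = converged,
            evidence = evidence)
}

#' Construct an RVM model object directly
#'
#' Low-level constructor used by [rvm_fit()] and by the JSON
#' deserializer; also convenient for building small models by hand.
#'
#' @param kernel a `"kernel_spec"`.
#' @param relevance_vectors m x d matrix of retained training inputs.
#' @param weights numeric vector of length m (kernel weights).
#' @param bias intercept weight w0 (0 if the bias basis was pruned).
#' @param has_bias logical; whether the bias basis function survived.
#' @param threshold decision cutoff (default 0.5).
#' @param rv_index,alpha_final,sigma2_final,gamma,n_iter,converged,evidence
#'   optional fit metadata.
#' @return object of class `"rvm"`.
#' @export
rvm_model <- function(kernel, relevance_vectors, weights, bias = 0,
                      has_bias = TRUE, threshold = 0.5,
                      rv_index = NULL, alpha_final = NULL,
                      sigma2_final = NULL, gamma = NULL,
                      n_iter = NA_integer_, converged = NA,
                      evidence = numeric(0L)) {
  stopifnot(inherits(kernel, "kernel_spec"))
  relevance_vectors <- as.matrix(relevance_vectors)
  if (length(weights) != nrow(relevance_vectors))
    stop("number of weights must equal number of relevance vectors")
  structure(list(kernel = kernel, relevance_vectors = relevance_vectors,
                 weights = as.numeric(weights), bias = as.numeric(bias),
                 has_bias = isTRUE(has_bias), threshold = threshold,
                 rv_index = rv_index, alpha_final = alpha_final,
                 sigma2_final = sigma2_final, gamma = gamma,
                 n_iter = n_iter, converged = converged, evidence = evidence),
            class = "rvm")
}

#' @export
print.rvm <- function(x, ...) {
  cat("Relevance vector machine (", x$kernel$name, ", width ",
      x$kernel$width, ")\n", sep = "")
  cat("  relevance vectors: ", nrow(x$relevance_vectors),
      if (x$has_bias) " (+ bias)" else "", "\n", sep = "")
  if (!is.na(x$n_iter))
    cat("  iterations: ", x$n_iter, ", converged: ", x$converged,
        ", sigma2: ", format(x$sigma2_final, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Continuous RVM scores
#'
#' Evaluates the decision function
#' \eqn{y(x) = w_0 + \sum_j w_j k(x, rv_j)} at the query points. Scores
#' are returned unsquashed; for a model trained on 0/1 labels they sit
#' near 0 or 1 for confident queries.
#'
#' @param m an `"rvm"` model.
#' @param X query inputs (matrix, or a single vector).
#' @return numeric score vector.
#' @export
rvm_predict <- function(m, X) {
  stopifnot(inherits(m, "rvm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (nrow(m$relevance_vectors) > 0L && ncol(X) != ncol(m$relevance_vectors))
    stop("query dimension ", ncol(X), " does not match relevance-vector ",
         "dimension ", ncol(m$relevance_vectors))
  y <- rep(m$bias, nrow(X))
  if (length(m$weights))
    y <- y + drop(kernel_matrix(m$kernel, X, m$relevance_vectors) %*% m$weights)
  y
}

#' Hard 0/1 classification
#'
#' @param m an `"rvm"` model.
#' @param X query inputs.
#' @return integer vector; 1 where the score is >= `m$threshold`.
#' @export
rvm_classify <- function(m, X) {
  as.integer(rvm_predict(m, X) >= m$threshold)
}

#' Serialize / restore an RVM model as JSON
#'
#' @param m an `"rvm"` model.
#' @param path JSON file path.
#' @return `write_rvm_json` returns `path` invisibly; `read_rvm_json`
#'   returns the restored model.
#' @export
write_rvm_json <- function(m, path) {
  stopifnot(inherits(m, "rvm"))
  jsonlite::write_json(
    list(kernel = list(name = m$kernel$name, width = m$kernel$width),
         relevance_vectors = m$relevance_vectors,
         weights = m$weights, bias = m$bias, has_bias = m$has_bias,
         threshold = m$threshold, rv_index = m$rv_index,
         alpha_final = m$alpha_final, sigma2_final = m$sigma2_final,
         n_iter = m$n_iter, converged = m$converged),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rvm_json
#' @export
read_rvm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rv <- j$relevance_vectors
  if (is.null(rv) || length(rv) == 0L) rv <- matrix(0, 0L, 0L)
  if (!is.matrix(rv)) rv <- matrix(as.numeric(rv), nrow = 1L)
  storage.mode(rv) <- "double"
  rvm_model(kernel_spec(j$kernel$name, j$kernel$width), rv,
            as.numeric(j$weights %||% numeric(0L)), bias = j$bias,
            has_bias = j$has_bias, threshold = j$threshold,
            rv_index = as.integer(j$rv_index %||% integer(0L)),
            alpha_final = as.numeric(j$alpha_final %||% numeric(0L)),
            sigma2_final = j$sigma2_final,
            n_iter = as.integer(j$n_iter %||% NA_integer_),
            converged = j$converged %||% NA)
}
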