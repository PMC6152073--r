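#' Bi-gram transition features from a PSSM
#'
#' Summarizes consecutive-position amino-acid co-occurrence in an L x 20
#' profile P as the 400 bi-gram values
#' \deqn{B_{mn} = \sum_{i=1}^{L-1} P_{i,m} P_{i+1,n}, \quad 1 \le m,n \le 20,}
#' flattened row-major into a vector indexed by u = 20(m-1) + n, i.e. all
#' transitions out of the first amino acid come first. For a single-row
#' PSSM the sum is empty and the vector is all zero. With a sigmoid- or
#' rowsum-normalized PSSM every entry is non-negative.
#'
#' @param p a `"pssm"` object (any normalization state; the pipeline
#'   default is sigmoid, see [normalize_pssm()]).
#' @return numeric vector of length 400, named by transition (e.g. `"AR"`
#'   is the A-to-R component), with the protein id in attribute
#'   `"protein_id"`.
#' @examples
#' p <- pssm(matrix(0.5, 3, 20), "toy", normalization = "sigmoid")
#' all(bigram_features(p) == 0.5)
#' @export
bigram_features <- function(p) {
  stopifnot(inherits(p, "pssm"))
  P <- p$scores
  L <- nrow(P)
  if (L < 2L) {
    v <- numeric(400L)
  } else {
    # B[m, n] = sum_i P[i, m] * P[i+1, n]
    B <- crossprod(P[-L, , drop = FALSE], P[-1L, , drop = FALSE])
    v <- as.vector(t(B))
  }
  names(v) <- paste0(rep(AA_ORDER, each = 20L), rep(AA_ORDER, times = 20L))
  attr(v, "protein_id") <- p$protein_id
  v
}

#' Compute bi-gram features for a set of PSSMs
#'
#' @param pssms list of `"pssm"` objects.
#' @return list with `ids` (protein ids, in input order) and `X`
#'   (matrix of stacked 400-dimensional bi-gram vectors, one row per protein).
#' @export
bigram_feature_matrix <- function(pssms) {
  ids <- vapply(pssms, function(p) p$protein_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  X <- do.call(rbind, lapply(pssms, function(p) as.vector(bigram_features(p))))
  rownames(X) <- ids
  list(ids = ids, X = X)
}

#' Write / read a feature matrix as CSV
#'
#' Plain CSV with a header row: an `id` column followed by `f1..fd`.
#'
#' @param X numeric matrix, one sample per row; no NA/Inf allowed.
#' @param ids character vector of row identifiers.
#' @param path file path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns a list with `ids` and `X` (rownames set to ids).
#' @export
write_feature_csv <- function(X, ids, path) {
  X <- as.matrix(X)
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (anyNA(X) || any(!is.finite(X))) stop("feature matrix contains NA/Inf")
  df <- data.frame(id = as.character(ids), X, check.names = FALSE)
  colnames(df) <- c("id", paste0("f", seq_len(ncol(X))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(df)) stop("feature CSV must have an 'id' column: ", path)
  ids <- as.character(df$id)
  X <- as.matrix(df[, setdiff(colnames(df), c("id", "label")), drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature CSV contains non-numeric or missing values: ", path)
  rownames(X) <- ids
  out <- list(ids = ids, X = X)
  if ("label" %in% colnames(df)) out$labels <- as.integer(df$label)
  out
}

#' Fit a centered principal component analysis model
#'
#' Standard PCA used to reduce the 400-dimensional bi-gram vectors (to 350
#' by default) before classification, discarding low-variance noise
#' directions. The components are the eigenvectors of the sample
#' covariance ordered by decreasing eigenvalue (computed via
#' [stats::prcomp()]); the sign of each component is fixed by forcing its
#' largest-magnitude loading to be positive, so results are deterministic
#' across linear-algebra backends.
#'
#' @param X numeric matrix (n_samples x d); requires n_samples > n_components.
#' @param n_components number of components to retain (default 350).
#' @return an object of class `"pca_model"` with fields `mean` (d-vector),
#'   `components` (n_components x d, orthonormal rows),
#'   `explained_variance` (non-increasing), `n_components`, `d`.
#' @export
fit_pca <- function(X, n_components = 350L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > d)
    stop("'n_components' must be in [1, ", d, "]")
  if (n <= n_components)
    stop("PCA needs more samples (", n, ") than components (", n_components,
         "); lower n_components")
  if (anyNA(X) || any(!is.finite(X))) stop("feature matrix contains NA/Inf")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(mean = unname(pr$center),
                 components = unname(t(rot)),
                 explained_variance = unname(pr$sdev[seq_len(n_components)]^2),
                 n_components = n_components, d = d),
            class = "pca_model")
}

#' Project a feature matrix onto fitted principal components
#'
#' @param model a `"pca_model"` from [fit_pca()].
#' @param X numeric matrix with the same column dimension the model was
#'   fit on.
#' @return n_samples x n_components matrix `(X - mean) %*% t(components)`.
#' @export
transform_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("feature dimension ", ncol(X),
         " does not match PCA model input dimension ", model$d)
  sweep(X, 2L, model$mean, "-") %*% t(model$components)
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model: ", x$d, " -> ", x$n_components, " dimensions\n", sep = "")
  invisible(x)
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model a `"pca_model"`.
#' @param path JSON file path.
#' @return `write_pca_json` returns `path` invisibly; `read_pca_json`
#'   returns the restored model.
#' @export
write_pca_json <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  jsonlite::write_json(
    list(mean = model$mean,
         components = model$components,
         explained_variance = model$explained_variance,
         n_components = model$n_components, d = model$d),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- if (is.matrix(j$components)) j$components
        else matrix(as.numeric(j$components), nrow = as.integer(j$n_components),
                    byrow = TRUE)
  storage.mode(cm) <- "double"
  dimnames(cm) <- NULL
  structure(list(mean = as.numeric(j$mean),
                 components = cm,
                 explained_variance = as.numeric(j$explained_variance),
                 n_components = as.integer(j$n_components),
                 d = as.integer(j$d)),
            class = "pca_model")
}
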