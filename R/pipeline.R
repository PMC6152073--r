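#' Bipartite drug-target interaction network
#'
#' Drug nodes on one side, protein-target nodes on the other; edges are
#' experimentally known interactions (the positive set). Every non-edge
#' is a candidate negative.
#'
#' @param drug_ids,target_ids character vectors of unique node ids (may be
#'   empty, in which case there can be no edges).
#' @param positive_edges data.frame (or 2-column matrix) with columns
#'   `drug_id`, `target_id`; every endpoint must appear in the id lists.
#'   Duplicate edges are collapsed.
#' @return object of class `"interaction_network"`.
#' @export
interaction_network <- function(drug_ids, target_ids, positive_edges) {
  drug_ids <- as.character(drug_ids); target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids")
  if (anyDuplicated(target_ids)) stop("duplicate target ids")
  pe <- as.data.frame(positive_edges, stringsAsFactors = FALSE)
  if (nrow(pe) > 0L) {
    if (!all(c("drug_id", "target_id") %in% colnames(pe)))
      colnames(pe)[1:2] <- c("drug_id", "target_id")
    pe <- unique(pe[, c("drug_id", "target_id")])
    bad_d <- setdiff(pe$drug_id, drug_ids)
    bad_t <- setdiff(pe$target_id, target_ids)
    if (length(bad_d) || length(bad_t))
      stop("edge endpoints missing from id lists: ",
           paste(c(bad_d, bad_t), collapse = ", "))
  } else {
    pe <- data.frame(drug_id = character(0L), target_id = character(0L))
  }
  rownames(pe) <- NULL
  structure(list(drug_ids = drug_ids, target_ids = target_ids,
                 positive_edges = pe),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network: ", length(x$drug_ids), " drugs x ",
      length(x$target_ids), " targets, ", nrow(x$positive_edges),
      " positive edges (", possible_pairs(x), " possible pairs)\n", sep = "")
  invisible(x)
}

#' Number of possible drug-target pairs
#'
#' @param net an `"interaction_network"`.
#' @return `|drugs| * |targets|`.
#' @export
possible_pairs <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  length(net$drug_ids) * length(net$target_ids)
}

#' Balanced negative sampling from the non-edge set
#'
#' Known interactions are vastly outnumbered by candidate non-edges, so
#' negatives are drawn uniformly without replacement from the pairs that
#' are not positive edges, by default as many as there are positives
#' (ratio 1), giving a balanced two-class dataset.
#'
#' @param net an `"interaction_network"` with at least one positive edge.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed; the sample is deterministic given the seed
#'   and does not disturb the global RNG stream.
#' @return data.frame with columns `drug_id`, `target_id`, disjoint from
#'   the positive edge set.
#' @export
sample_negatives <- function(net, ratio = 1, seed) {
  stopifnot(inherits(net, "interaction_network"))
  nd <- length(net$drug_ids); nt <- length(net$target_ids)
  npos <- nrow(net$positive_edges)
  n_neg <- round(ratio * npos)
  di <- match(net$positive_edges$drug_id, net$drug_ids)
  ti <- match(net$positive_edges$target_id, net$target_ids)
  pos_cell <- (di - 1) * nt + ti
  avail <- nd * nt - npos
  if (avail <= 0L)
    stop("no non-interacting pairs available (network is complete bipartite)")
  if (n_neg > avail)
    stop("requested ", n_neg, " negatives but only ", avail,
         " non-interacting pairs are available")
  cells <- setdiff(seq_len(nd * nt), pos_cell)
  sel <- withr::with_seed(seed, sample(cells, n_neg))
  data.frame(drug_id = net$drug_ids[(sel - 1) %/% nt + 1],
             target_id = net$target_ids[(sel - 1) %% nt + 1],
             stringsAsFactors = FALSE)
}

#' Assemble a labeled pair dataset with features
#'
#' Positive edges get label 1, sampled negatives label 0. The default
#' pair representation is the target protein's feature vector (e.g. the
#' PCA-reduced bi-gram vector); if drug feature vectors are supplied the
#' pair vector is the concatenation drug-then-protein.
#'
#' @param net an `"interaction_network"`.
#' @param negatives data.frame of negative pairs (from
#'   [sample_negatives()]).
#' @param protein_features numeric matrix with one row per target,
#'   rownames = target ids.
#' @param drug_features optional numeric matrix with one row per drug,
#'   rownames = drug ids.
#' @return object of class `"pair_dataset"`: `pairs` (data.frame
#'   `drug_id`, `target_id`, `label`) and `X` (aligned feature matrix).
#' @export
build_pair_dataset <- function(net, negatives, protein_features,
                               drug_features = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  negatives <- as.data.frame(negatives, stringsAsFactors = FALSE)
  pairs <- rbind(cbind(net$positive_edges, label = 1L),
                 cbind(negatives[, c("drug_id", "target_id")], label = 0L))
  rownames(pairs) <- NULL
  protein_features <- as.matrix(protein_features)
  miss_t <- setdiff(unique(pairs$target_id), rownames(protein_features))
  if (length(miss_t))
    stop("missing protein feature vectors for: ", paste(miss_t, collapse = ", "))
  X <- protein_features[pairs$target_id, , drop = FALSE]
  if (!is.null(drug_features)) {
    drug_features <- as.matrix(drug_features)
    miss_d <- setdiff(unique(pairs$drug_id), rownames(drug_features))
    if (length(miss_d))
      stop("missing drug feature vectors for: ", paste(miss_d, collapse = ", "))
    X <- cbind(drug_features[pairs$drug_id, , drop = FALSE], X)
  }
  rownames(X) <- NULL
  structure(list(pairs = pairs, X = X), class = "pair_dataset")
}

#' Wrap a plain feature matrix and labels as a pair dataset
#'
#' Convenience for feeding feature-level data (e.g. from
#' [gen_two_class_features()]) into [run_cv()]; placeholder pair ids are
#' fabricated.
#'
#' @param X numeric feature matrix.
#' @param labels 0/1 vector aligned to rows of `X`.
#' @return a `"pair_dataset"`.
#' @export
as_pair_dataset <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("nrow(X) must equal length(labels)")
  if (!all(labels %in% 0:1)) stop("labels must be 0/1")
  n <- nrow(X)
  structure(list(pairs = data.frame(drug_id = sprintf("d%05d", seq_len(n)),
                                    target_id = sprintf("t%05d", seq_len(n)),
                                    label = labels),
                 X = unname(X)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("Pair dataset: ", nrow(x$X), " pairs (", sum(x$pairs$label == 1L),
      " positive / ", sum(x$pairs$label == 0L), " negative), ",
      ncol(x$X), " features\n", sep = "")
  invisible(x)
}

#' Deterministic k-fold split
#'
#' Partitions 1..n into k disjoint test folds of near-equal size (sizes
#' differ by at most 1), optionally stratified so that each fold carries
#' each class in proportion (class counts per fold within +/- 1).
#'
#' @param n number of samples (n >= k).
#' @param k number of folds (default 5).
#' @param stratify_labels optional label vector of length n.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list of k elements, each a list with integer vectors `train`
#'   and `test`; the test folds are disjoint and cover 1..n.
#' @export
kfold_split <- function(n, k = 5L, stratify_labels = NULL, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  if (!is.null(stratify_labels) && length(stratify_labels) != n)
    stop("'stratify_labels' must have length n")
  ord <- withr::with_seed(seed, {
    if (is.null(stratify_labels)) {
      sample.int(n)
    } else {
      unlist(lapply(split(seq_len(n), stratify_labels),
                    function(ix) ix[sample.int(length(ix))]),
             use.names = FALSE)
    }
  })
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Cross-validated training and evaluation
#'
#' Runs stratified k-fold cross-validation of the full classification
#' stage: optional PCA reduction of the pair features, classifier
#' training on the k-1 training folds, scoring of the held-out fold, and
#' confusion-based metrics. By default PCA is fit on the training folds
#' only (leakage-safe); `pca_mode = "global"` fits it once on the pooled
#' dataset. Held-out scores from all folds are pooled for a single ROC
#' curve and AUC.
#'
#' The default classifier is the package's relevance vector machine; an
#' off-the-shelf SVM baseline (RBF kernel via \pkg{e1071}, defaults
#' cost 0.5, gamma 0.6) is available behind the same harness for
#' comparison runs.
#'
#' @param dataset a `"pair_dataset"`.
#' @param k number of folds (default 5).
#' @param kernel RVM `"kernel_spec"` (default poly2, width 1).
#' @param control an `"rvm_control"`.
#' @param pca_components number of PCA components (default 350); `NULL`
#'   skips PCA. Must be smaller than the training-fold size.
#' @param pca_mode `"per_fold"` (default) or `"global"`.
#' @param classifier `"rvm"` (default) or `"svm"`.
#' @param threshold decision cutoff on RVM scores (default 0.5).
#' @param seed integer seed controlling the fold split.
#' @param svm_cost,svm_gamma SVM baseline hyperparameters (defaults 0.5
#'   and 0.6).
#' @return object of class `"metrics_report"`: `per_fold` (data.frame of
#'   fold-level Ac/Sn/Pe/Mcc percentages and confusion counts), `summary`
#'   (mean and sample sd per metric), `roc`, `auc`, and the resolved run
#'   settings.
#' @export
run_cv <- function(dataset, k = 5L, kernel = kernel_spec("poly2", 1),
                   control = rvm_control(), pca_components = 350L,
                   pca_mode = c("per_fold", "global"),
                   classifier = c("rvm", "svm"), threshold = 0.5,
                   seed = 1L, svm_cost = 0.5, svm_gamma = 0.6) {
  stopifnot(inherits(dataset, "pair_dataset"))
  pca_mode <- match.arg(pca_mode)
  classifier <- match.arg(classifier)
  X <- dataset$X
  y <- dataset$pairs$label
  n <- nrow(X)
  folds <- kfold_split(n, k, stratify_labels = y, seed = seed)
  if (!is.null(pca_components) && pca_mode == "global") {
    Xg <- transform_pca(fit_pca(X, pca_components), X)
  }
  scores_all <- numeric(n)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (length(unique(y[tr])) < 2L)
      stop("training fold ", f, " contains a single class")
    if (is.null(pca_components)) {
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    } else if (pca_mode == "per_fold") {
      pm <- fit_pca(X[tr, , drop = FALSE], pca_components)
      Xtr <- transform_pca(pm, X[tr, , drop = FALSE])
      Xte <- transform_pca(pm, X[te, , drop = FALSE])
    } else {
      Xtr <- Xg[tr, , drop = FALSE]; Xte <- Xg[te, , drop = FALSE]
    }
    if (classifier == "rvm") {
      m <- rvm_fit(Xtr, y[tr], kernel, control, threshold)
      sc <- rvm_predict(m, Xte)
      pred <- as.integer(sc >= threshold)
    } else {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("the SVM baseline requires the e1071 package")
      fit <- e1071::svm(Xtr, factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", cost = svm_cost,
                        gamma = svm_gamma, scale = FALSE)
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # e1071 orients decision values toward the first factor level seen;
      # flip so larger always means class 1
      if (grepl("^0/1", colnames(attr(pr, "decision.values"))[1L])) dv <- -dv
      sc <- dv
      pred <- as.integer(as.character(pr))
    }
    scores_all[te] <- sc
    cc <- confusion_counts(y[te], pred)
    mt <- compute_metrics(cc)
    per_fold[[f]] <- data.frame(fold = f, Ac = mt$Ac, Sn = mt$Sn,
                                Pe = mt$Pe, Mcc = mt$Mcc,
                                TP = cc$TP, FP = cc$FP, TN = cc$TN,
                                FN = cc$FN)
  }
  pf <- do.call(rbind, per_fold)
  ra <- roc_and_auc(scores_all, y)
  sm <- lapply(c(Ac = "Ac", Sn = "Sn", Pe = "Pe", Mcc = "Mcc"),
               function(col) aggregate_folds(pf[[col]]))
  structure(list(per_fold = pf, summary = sm, roc = ra$roc, auc = ra$auc,
                 scores = scores_all, labels = y,
                 settings = list(k = k, seed = seed, classifier = classifier,
                                 kernel = kernel$name, width = kernel$width,
                                 pca_components = pca_components,
                                 pca_mode = pca_mode, threshold = threshold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("Cross-validation report (", x$settings$k, "-fold, ",
      x$settings$classifier, ")\n", sep = "")
  print(format(x$per_fold[, c("fold", "Ac", "Sn", "Pe", "Mcc")],
               digits = digits, nsmall = digits), row.names = FALSE)
  for (mname in names(x$summary))
    cat(sprintf("  %-3s %.2f +/- %.2f %%\n", mname,
                x$summary[[mname]]$mean, x$summary[[mname]]$sd))
  cat(sprintf("  AUC %.4f (pooled held-out scores)\n", x$auc))
  invisible(x)
}

#' Write a metrics report to JSON (plus ROC points as CSV)
#'
#' @param report a `"metrics_report"`.
#' @param path output JSON path.
#' @param roc_csv optional path for the ROC points as CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, roc_csv = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(per_fold = report$per_fold,
         summary = lapply(report$summary, function(s)
           list(mean = s$mean, sd = s$sd)),
         auc = report$auc, settings = report$settings),
    path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  if (!is.null(roc_csv))
    utils::write.csv(report$roc, roc_csv, row.names = FALSE, quote = FALSE)
  invisible(path)
}
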