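#' Generate a synthetic PSSM
#'
#' Draws an L x 20 matrix of i.i.d. integer scores, uniform over
#' `score_range` (default [-10, 10], the typical magnitude of PSI-BLAST
#' log-odds, which keeps sigmoid normalization in a realistic operating
#' region), plus a random amino-acid sequence for bookkeeping. Pure
#' function of its arguments: repeat calls with the same seed are
#' bit-identical, and the global RNG stream is left untouched.
#'
#' @param length number of residues (L >= 1).
#' @param seed integer seed.
#' @param score_range integer interval `c(min, max)`.
#' @param protein_id identifier (default derived from the seed).
#' @return a raw `"pssm"`.
#' @export
gen_pssm <- function(length, seed, score_range = c(-10L, 10L),
                     protein_id = sprintf("synth%06d", seed)) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be at least 1")
  if (score_range[1] > score_range[2]) stop("'score_range' must have min <= max")
  withr::with_seed(seed, {
    sc <- matrix(sample(seq(score_range[1], score_range[2]),
                        length * 20L, replace = TRUE), nrow = length)
    seqc <- paste(sample(AA_ORDER, length, replace = TRUE), collapse = "")
    pssm(sc, protein_id, seqc)
  })
}

#' Generate a synthetic bipartite interaction network
#'
#' Drug ids d0001..., target ids t0001...; `n_positive` edges sampled
#' uniformly without replacement from the full drug x target grid.
#' Deterministic given the seed.
#'
#' @param n_drugs,n_targets numbers of nodes (>= 1).
#' @param n_positive number of positive edges
#'   (`<= n_drugs * n_targets`).
#' @param seed integer seed.
#' @return an `"interaction_network"`.
#' @examples
#' net <- gen_network(3, 4, 5, seed = 1)
#' possible_pairs(net)
#' @export
gen_network <- function(n_drugs, n_targets, n_positive, seed) {
  n_drugs <- as.integer(n_drugs); n_targets <- as.integer(n_targets)
  n_positive <- as.integer(n_positive)
  if (n_drugs < 1L || n_targets < 1L) stop("node counts must be positive")
  if (n_positive < 1L) stop("'n_positive' must be positive")
  if (n_positive > n_drugs * n_targets)
    stop("cannot place ", n_positive, " positive edges in a ",
         n_drugs, " x ", n_targets, " grid (", n_drugs * n_targets,
         " cells)")
  cells <- withr::with_seed(seed, sample(n_drugs * n_targets, n_positive))
  drug_ids <- sprintf("d%04d", seq_len(n_drugs))
  target_ids <- sprintf("t%04d", seq_len(n_targets))
  interaction_network(
    drug_ids, target_ids,
    data.frame(drug_id = drug_ids[(cells - 1) %/% n_targets + 1],
               target_id = target_ids[(cells - 1) %% n_targets + 1],
               stringsAsFactors = FALSE))
}

#' Generate two-class Gaussian feature data
#'
#' Class 0 is drawn from N(-s/2 * 1, I) and class 1 from N(+s/2 * 1, I)
#' with s = separation / sqrt(dim), so the Euclidean distance between the
#' class mean vectors equals `separation` regardless of dimension.
#' `separation = 0` makes the two classes identically distributed.
#'
#' @param n_per_class samples per class (>= 1).
#' @param dim feature dimension (>= 1).
#' @param separation Euclidean class-mean distance (>= 0; default 6, a
#'   well-separated regime with Bayes error around 0.1%).
#' @param seed integer seed.
#' @return list with `X` (2 * n_per_class rows), `labels` (0 then 1
#'   blocks).
#' @export
gen_two_class_features <- function(n_per_class, dim, separation = 6, seed) {
  n_per_class <- as.integer(n_per_class); dim <- as.integer(dim)
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1")
  if (dim < 1L) stop("'dim' must be >= 1")
  if (separation < 0) stop("'separation' must be >= 0")
  s <- separation / sqrt(dim)
  X <- withr::with_seed(seed, {
    rbind(matrix(stats::rnorm(n_per_class * dim, mean = -s / 2), nrow = n_per_class),
          matrix(stats::rnorm(n_per_class * dim, mean = s / 2), nrow = n_per_class))
  })
  list(X = X, labels = rep(0:1, each = n_per_class))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the same plain-text formats the real pipeline reads: one PSSM
#' TSV dump per target under `pssms/`, a FASTA file of the bookkeeping
#' sequences, a `pairs.tsv` of positive edges, and a `manifest.json`
#' recording the seed and parameters (so the dataset can be regenerated
#' exactly).
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed.
#' @param n_drugs,n_targets,n_positive network shape (defaults 25 x 40
#'   with 120 positive edges, a small-scale bipartite benchmark shape).
#' @param length_range PSSM length interval (default 50..200 residues).
#' @param score_range integer PSSM score interval (default [-10, 10]).
#' @param force overwrite an existing dataset (default FALSE).
#' @return invisibly, the manifest as a list.
#' @export
simulate_dataset <- function(out_dir, seed = 1L, n_drugs = 25L,
                             n_targets = 40L, n_positive = 120L,
                             length_range = c(50L, 200L),
                             score_range = c(-10L, 10L), force = FALSE) {
  seed <- as.integer(seed)
  n_drugs <- as.integer(n_drugs); n_targets <- as.integer(n_targets)
  n_positive <- as.integer(n_positive)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("dataset already exists at ", out_dir, "; use force = TRUE to overwrite")
  dir.create(file.path(out_dir, "pssms"), recursive = TRUE, showWarnings = FALSE)
  # one sub-seed per generated object, all derived from the master seed
  sub <- withr::with_seed(seed, sample.int(2^31 - 2, n_targets + 1L))
  lens <- withr::with_seed(seed + 1L,
                           sample(seq(length_range[1], length_range[2]),
                                  n_targets, replace = TRUE))
  net <- gen_network(n_drugs, n_targets, n_positive, seed = sub[1L])
  pssm_files <- character(n_targets)
  seqs <- character(n_targets)
  for (i in seq_len(n_targets)) {
    id <- net$target_ids[i]
    p <- gen_pssm(lens[i], seed = sub[i + 1L], score_range = score_range,
                  protein_id = id)
    pssm_files[i] <- file.path("pssms", paste0(id, ".tsv"))
    write_pssm_tsv(p, file.path(out_dir, pssm_files[i]))
    seqs[i] <- p$sequence
  }
  fasta_path <- file.path(out_dir, "proteins.fasta")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::AAStringSet(seqs)
    names(ss) <- net$target_ids
    Biostrings::writeXStringSet(ss, fasta_path)
  } else {
    writeLines(rbind(paste0(">", net$target_ids), seqs), fasta_path)
  }
  utils::write.table(net$positive_edges, file.path(out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = seed, n_drugs = n_drugs, n_targets = n_targets,
                   n_positive = n_positive,
                   length_range = as.integer(length_range),
                   score_range = as.integer(score_range),
                   files = c("pairs.tsv", "proteins.fasta", pssm_files))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
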