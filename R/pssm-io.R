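# PSI-BLAST column order; every PSSM in this package uses these 20 columns.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a PSSM object
#'
#' A position-specific scoring matrix (PSSM) is an L x 20 profile of
#' per-position amino-acid substitution scores for one protein, with
#' columns in PSI-BLAST order (A R N D C Q E G H I L K M F P S T W Y V).
#' Raw PSI-BLAST scores are log-odds integers; normalized variants map
#' them to probability-like values (see [normalize_pssm()]).
#'
#' @param scores numeric matrix with L >= 1 rows and exactly 20 columns.
#' @param protein_id single non-empty string identifying the protein.
#' @param sequence optional amino-acid string of length L (the 20 standard
#'   letters plus X/B/Z/U are accepted; rows for nonstandard residues are
#'   kept as-is).
#' @param normalization one of `"raw"`, `"sigmoid"`, `"rowsum"`; the state
#'   the scores are already in.
#' @return an object of class `"pssm"` with fields `protein_id`, `scores`,
#'   `sequence`, `normalization`.
#' @examples
#' p <- pssm(matrix(0, 3, 20), "prot1")
#' dim(p$scores)
#' @export
pssm <- function(scores, protein_id, sequence = NULL, normalization = "raw") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L)
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L)
    stop("a PSSM must have at least 1 row")
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id))
    stop("'protein_id' must be a single non-empty string")
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("PSSM scores must be finite and non-missing")
  normalization <- match.arg(normalization, c("raw", "sigmoid", "rowsum"))
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != nrow(scores))
      stop("sequence length (", nchar(sequence),
           ") does not equal the number of score rows (", nrow(scores), ")")
  }
  if (normalization == "sigmoid" && (any(scores <= 0) || any(scores >= 1)))
    stop("sigmoid-normalized entries must lie strictly in (0, 1)")
  if (normalization == "rowsum" && any(abs(rowSums(scores) - 1) > 1e-9))
    stop("rowsum-normalized rows must each sum to 1 (tolerance 1e-9)")
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(list(protein_id = protein_id, scores = scores,
                 sequence = sequence, normalization = normalization),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for ", x$protein_id, ": ", nrow(x$scores), " x 20 (",
      x$normalization, ")\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` output of PSI-BLAST: header lines, then one
#' line per residue carrying the position, the residue letter, 20 integer
#' log-odds columns, 20 weighted-percentage columns and two trailing
#' floats. Only the first block of 20 columns (the log-odds scores) is
#' retained; the percentage block is ignored. Rows for nonstandard
#' residues (X/B/Z/U) are kept so that the row count always equals the
#' sequence length.
#'
#' @param path path to the ASCII PSSM file.
#' @param protein_id identifier for the protein; defaults to the file name
#'   without extension.
#' @return a `"pssm"` object with `normalization = "raw"`; the residue
#'   letters of the parsed rows concatenate to the stored sequence.
#' @seealso [write_pssm_tsv()] for the internal plain-text dump format.
#' @export
parse_psiblast_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty PSSM file: ", path)
  row_like <- grepl("^\\s*[0-9]+\\s+[A-Za-z](\\s|$)", lines)
  if (!any(row_like))
    stop("no residue rows found in ", path, "; not a PSI-BLAST ASCII PSSM")
  first <- which(row_like)[1L]
  scores <- list()
  residues <- character()
  for (i in seq(first, length(lines))) {
    if (!row_like[i]) break                      # footer (Lambda/K block) or blank
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    num <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(num))
      stop("non-numeric score field on line ", i, " of ", path)
    # full dialect: 20 log-odds + 20 percentages (+ information, weight);
    # bare 20-column rows are also accepted
    if (length(num) != 20L && length(num) < 40L)
      stop("expected 20 log-odds columns on line ", i, " of ", path,
           ", found ", length(num), " numeric fields")
    scores[[length(scores) + 1L]] <- num[1:20]
    residues[length(residues) + 1L] <- toupper(f[2L])
  }
  pssm(do.call(rbind, scores),
       protein_id = protein_id %||% tools::file_path_sans_ext(basename(path)),
       sequence = paste(residues, collapse = ""))
}

#' Write / read the internal PSSM TSV dump
#'
#' A plain-text round-trip format for fixtures and for files emitted by
#' [simulate_dataset()]: comment header lines with the protein id,
#' normalization state and sequence, then L rows of 20 tab-separated
#' values at full double precision.
#'
#' @param p a `"pssm"` object.
#' @param path output (or input) file path.
#' @return `write_pssm_tsv` returns `path` invisibly; `read_pssm_tsv`
#'   returns the reconstructed `"pssm"`.
#' @export
write_pssm_tsv <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  hdr <- c(paste0("# protein_id=", p$protein_id),
           paste0("# normalization=", p$normalization),
           if (!is.null(p$sequence)) paste0("# sequence=", p$sequence))
  body <- apply(p$scores, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pssm_tsv
#' @export
read_pssm_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no score rows in ", path)
  field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^#\\s*", key, "="), "", m[1L]) else NULL
  }
  sc <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (anyNA(sc)) stop("non-numeric score field in ", path)
  pssm(sc,
       protein_id = field("protein_id") %||% tools::file_path_sans_ext(basename(path)),
       sequence = field("sequence"),
       normalization = field("normalization") %||% "raw")
}

# Sniff format: internal TSV dumps start with a '# protein_id=' header.
read_pssm_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^#\\s*protein_id=", first))
    read_pssm_tsv(path)
  else
    parse_psiblast_pssm(path)
}

#' Normalize a raw PSSM
#'
#' Maps raw log-odds scores to probability-like values. `sigmoid` applies
#' the element-wise logistic 1/(1+exp(-s)), placing every entry in (0, 1).
#' `rowsum` first shifts each row by its minimum (raw log-odds rows can
#' sum to <= 0) and divides by the row sum, so each row sums to 1; an
#' all-constant row maps to the uniform value 1/20. `raw` returns an
#' identity copy. Normalizing an already-normalized PSSM is an error.
#'
#' @param p a `"pssm"` with `normalization == "raw"`.
#' @param mode one of `"sigmoid"` (default), `"raw"`, `"rowsum"`.
#' @return a `"pssm"` with the requested normalization state.
#' @export
normalize_pssm <- function(p, mode = c("sigmoid", "raw", "rowsum")) {
  stopifnot(inherits(p, "pssm"))
  mode <- match.arg(mode)
  if (p$normalization != "raw")
    stop("PSSM is already normalized ('", p$normalization,
         "'); normalization must start from a raw PSSM")
  s <- p$scores
  out <- switch(mode,
    raw = s,
    sigmoid = 1 / (1 + exp(-s)),
    rowsum = {
      shifted <- s - apply(s, 1L, min)
      rs <- rowSums(shifted)
      flat <- rs <= 0                      # all-constant row
      if (any(flat)) {
        shifted[flat, ] <- 1
        rs[flat] <- 20
      }
      shifted / rs
    })
  pssm(out, p$protein_id, p$sequence, normalization = mode)
}

#' Read protein records from a FASTA file
#'
#' Thin reader used for id mapping and bookkeeping; sequences themselves
#' are not needed for feature extraction (features come from PSSMs).
#'
#' @param path FASTA file of amino-acid sequences.
#' @return data.frame with columns `protein_id` (first token of each
#'   header), `sequence`, `length`.
#' @export
read_fasta_records <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)
  if (any(!nzchar(ids))) stop("empty protein id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(protein_id = ids, sequence = as.character(seqs),
             length = Biostrings::width(seqs), row.names = NULL)
}
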