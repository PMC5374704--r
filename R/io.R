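#' Read a FASTA file of protein or RNA sequences
#'
#' Sequences are returned as a named character vector (ids as names) with
#' class `"seq_set"`.  RNA sequences are canonicalized on load: lowercase is
#' uppercased and `T` is mapped to `U`, so that downstream code only ever
#' sees the `{A, U, C, G}` alphabet.  Protein sequences are uppercased;
#' letters outside the 20 standard amino acids are permitted but flagged
#' with a warning (positions covered by them are later excluded from
#' triad counting).
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"protein"` or `"rna"`.
#' @return A `seq_set`: named character vector of sequences with an
#'   `alphabet` attribute.  Record order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ccucu"), tf)
#' read_fasta(tf, "rna")
#' @export
read_fasta <- function(path, alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop("malformed FASTA in ", path, ": line 1 does not start with '>'")
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  if (alphabet == "rna") {
    seqs <- chartr("T", "U", seqs)
    bad <- grepl("[^AUCG]", seqs)
    if (any(bad))
      stop("RNA sequence(s) with letters outside {A,U,C,G,T}: ",
           paste(ids[bad], collapse = ", "))
  } else {
    nonstd <- grepl(sprintf("[^%s]", AA_STANDARD), seqs)
    if (any(nonstd))
      warning("non-standard amino-acid letters in: ",
              paste(ids[nonstd], collapse = ", "))
  }
  names(seqs) <- ids
  seq_set(seqs, alphabet)
}

AA_STANDARD <- "ACDEFGHIKLMNPQRSTVWY"

#' Construct a sequence set
#'
#' @param seqs Named character vector of sequences (ids as names).
#' @param alphabet `"protein"` or `"rna"`.
#' @return A `seq_set`.
#' @export
seq_set <- function(seqs, alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  structure(seqs, alphabet = alphabet, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "alphabet"), "sequences;",
      "lengths", min(nchar(x)), "-", max(nchar(x)), "\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  seq_set(NextMethod(), attr(x, "alphabet"))
}

#' Write sequences to FASTA
#'
#' @param seqs A `seq_set` or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct an interaction set
#'
#' An interaction set is a data frame with columns `protein` and `rna`
#' (and optionally `score`), a `label` attribute marking it as a positive
#' or negative set, and class `"interaction_set"`.
#'
#' @param protein,rna Character vectors of equal length.
#' @param label `"positive"` or `"negative"`.
#' @param score Optional numeric vector of per-pair confidence scores.
#' @return An `interaction_set`.
#' @export
interaction_set <- function(protein = character(), rna = character(),
                            label = c("positive", "negative"), score = NULL) {
  label <- match.arg(label)
  protein <- as.character(protein)
  rna <- as.character(rna)
  stopifnot(length(protein) == length(rna))
  df <- data.frame(protein = protein, rna = rna, stringsAsFactors = FALSE)
  if (!is.null(score)) {
    stopifnot(length(score) == length(protein))
    df$score <- as.numeric(score)
  }
  if (anyDuplicated(pair_keys(df)))
    stop("duplicate (protein, rna) pair(s) in interaction set")
  structure(df, label = label, class = c("interaction_set", "data.frame"))
}

pair_keys <- function(pairs) paste(pairs$protein, pairs$rna, sep = "\r")

#' @export
print.interaction_set <- function(x, ...) {
  cat(attr(x, "label"), "interaction set:", nrow(x), "pairs,",
      length(unique(x$protein)), "proteins,",
      length(unique(x$rna)), "RNAs\n")
  if (nrow(x)) print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Parse whitespace/tab-delimited text with `ncols` (or ncols + 1, when one
# extra trailing column is tolerated) fields per row; "#" comment lines and
# blank lines are ignored.  An optional header row naming the columns is
# skipped.  Returns a character matrix.
read_delim_columns <- function(path, ncols, header_names, extra = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  n <- lengths(fields)
  allowed <- if (extra) c(ncols, ncols + 1L) else ncols
  if (any(!n %in% allowed))
    stop("expected ", ncols, " columns but found ", n[!n %in% allowed][1L],
         " on line ", rows[!n %in% allowed][1L], " of ", path)
  if (!length(fields)) return(matrix(character(), 0L, ncols))
  width <- max(n)
  m <- do.call(rbind, lapply(fields, function(f) c(f, rep(NA, width - length(f)))))
  if (all(tolower(m[1L, seq_len(ncols)]) %in% header_names))
    m <- m[-1L, , drop = FALSE]
  m
}

#' Read a protein-RNA pair file
#'
#' Pair files are two-column delimited text (protein id, RNA id), with
#' `#`-prefixed comment lines ignored and an optional header row.  A third
#' numeric column, when present, is read as a per-pair score (scored
#' negative sets are written in this form).  Duplicate rows are collapsed
#' with a warning.
#'
#' @param path Path to the pair file.
#' @param label `"positive"` or `"negative"`.
#' @return An [interaction_set()].
#' @export
read_pairs <- function(path, label = c("positive", "negative")) {
  label <- match.arg(label)
  m <- read_delim_columns(path, 2L, c("protein", "rna", "score"),
                          extra = TRUE)
  if (nrow(m) == 0L) return(interaction_set(label = label))
  keys <- paste(m[, 1L], m[, 2L], sep = "\r")
  if (anyDuplicated(keys)) {
    warning(sum(duplicated(keys)), " duplicate pair(s) collapsed in ", path)
    m <- m[!duplicated(keys), , drop = FALSE]
  }
  score <- if (ncol(m) == 3L && !anyNA(m[, 3L])) as.numeric(m[, 3L])
  interaction_set(m[, 1L], m[, 2L], label = label, score = score)
}

#' Write an interaction set to a tab-separated pair file
#'
#' @param pairs An [interaction_set()].
#' @param path Output file path.
#' @param scores Write the score column, if present?
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, scores = !is.null(pairs$score)) {
  df <- as.data.frame(pairs)
  if (!scores) df$score <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a protein annotation table (GO terms or Pfam domains)
#'
#' Two-column delimited text: protein id, annotation id.  Rows are grouped
#' into one identifier set per protein.  Proteins absent from the file are
#' treated as annotated with the empty set on lookup (real GO/Pfam coverage
#' is incomplete; Jaccard similarity degrades gracefully to 0).
#'
#' @param path Path to the annotation file.
#' @param role `"go"` or `"domain"`.
#' @return An `annotation_table`: named list of character vectors with a
#'   `role` attribute.
#' @export
read_annotations <- function(path, role = c("go", "domain")) {
  role <- match.arg(role)
  m <- read_delim_columns(path, 2L,
                          c("protein", "annotation", "term", "domain", "id"))
  tab <- if (nrow(m) == 0L) list() else
    lapply(split(m[, 2L], m[, 1L]), unique)
  annotation_table(tab, role)
}

#' Construct an annotation table from a named list of identifier sets
#'
#' @param sets Named list (protein id -> character vector of annotation
#'   ids).
#' @param role `"go"` or `"domain"`.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(sets, role = c("go", "domain")) {
  role <- match.arg(role)
  structure(sets, role = role, class = "annotation_table")
}

#' Look up the annotation set of one protein
#'
#' @param table An `annotation_table` (or `NULL`, treated as empty).
#' @param id Protein identifier.
#' @return Character vector of annotation ids; `character(0)` for proteins
#'   with no recorded annotation.
#' @export
get_annotations <- function(table, id) {
  if (is.null(table)) return(character())
  s <- table[[id]]
  if (is.null(s)) character() else s
}

#' Write a labeled feature dataset as tab-separated text
#'
#' The header row holds the feature names followed by `label`; each
#' subsequent row is one protein-RNA pair's feature values and its class
#' label.
#'
#' @param dataset A `pri_dataset` (see [build_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset$features, check.names = FALSE)
  df$label <- as.character(dataset$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a labeled feature dataset written by [write_dataset()]
#'
#' @param path Path to the dataset file.
#' @return A `pri_dataset`: list with a numeric `features` matrix and a
#'   `labels` factor with levels `negative`, `positive`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  lab <- df$label
  df$label <- NULL
  pri_dataset(as.matrix(df), factor(lab, levels = c("negative", "positive")))
}

#' Construct a labeled feature dataset
#'
#' @param features Numeric matrix, one row per protein-RNA pair.
#' @param labels Factor with levels `negative`, `positive`.
#' @param pairs Optional data frame of (protein, rna) ids aligned with the
#'   rows.
#' @return A `pri_dataset`.
#' @export
pri_dataset <- function(features, labels, pairs = NULL) {
  stopifnot(nrow(features) == length(labels))
  structure(list(features = features, labels = labels, pairs = pairs),
            class = "pri_dataset")
}

#' @export
print.pri_dataset <- function(x, ...) {
  cat("pri_dataset:", nrow(x$features), "samples x", ncol(x$features),
      "features (", sum(x$labels == "positive"), "positive /",
      sum(x$labels == "negative"), "negative )\n")
  invisible(x)
}
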