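#' Alignment and similarity parameters
#'
#' Smith-Waterman scoring scheme used for protein sequence similarity.
#' Defaults are the canonical local-alignment settings: BLOSUM62 with gap
#' open 10 and gap extend 0.5 (a gap of length L costs
#' `gap_open + gap_extend * L`).
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open,gap_extend Affine gap penalties (non-negative costs).
#' @return A list of class `"alignment_params"`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  mat <- get_substitution_matrix(matrix)
  structure(list(matrix = matrix, substitution = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# Raw Smith-Waterman local alignment score, clamped at 0 (the empty local
# alignment always scores 0).
sw_score <- function(a, b, params = alignment_params()) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$substitution,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  max(0, s)
}

# Vectorized: SW scores of each sequence in `patterns` against `subject`.
sw_scores_vs <- function(patterns, subject, params) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = params$substitution,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  pmax(0, s)
}

#' Normalized Smith-Waterman similarity
#'
#' The local-alignment score of the two sequences divided by the geometric
#' mean of their self-alignment scores:
#' `nsw(a, b) = sw(a, b) / (sqrt(sw(a, a)) * sqrt(sw(b, b)))`.
#' Symmetric, 1 for identical sequences, 0 when no positive-scoring local
#' alignment exists.
#'
#' @param a,b Protein sequences (character scalars).
#' @param params An [alignment_params()] object.
#' @return A similarity in `[0, 1]`.
#' @export
normalized_sw <- function(a, b, params = alignment_params()) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  saa <- sw_score(a, a, params)
  sbb <- sw_score(b, b, params)
  if (saa == 0 || sbb == 0)
    stop("self-alignment score is 0; normalization undefined for these ",
         "scoring parameters")
  sw_score(a, b, params) / (sqrt(saa) * sqrt(sbb))
}

#' Protein sequence similarity SS
#'
#' The average of the normalized Smith-Waterman score over both argument
#' orders, `SS(a, b) = (nsw(a, b) + nsw(b, a)) / 2`.  The two orders are
#' identical under the self-score normalization; the average is retained
#' for fidelity to the definition.
#'
#' @inheritParams normalized_sw
#' @return SS in `[0, 1]`.
#' @export
sequence_similarity <- function(a, b, params = alignment_params()) {
  (normalized_sw(a, b, params) + normalized_sw(b, a, params)) / 2
}

#' Jaccard similarity of two identifier sets
#'
#' `|s1 n s2| / |s1 u s2|`, with the two-empty-sets case defined as 0: the
#' absence of annotation evidence is not counted as similarity.
#'
#' @param s1,s2 Character vectors (treated as sets).
#' @return A value in `[0, 1]`.
#' @export
jaccard <- function(s1, s2) {
  s1 <- unique(as.character(s1))
  s2 <- unique(as.character(s2))
  u <- length(union(s1, s2))
  if (u == 0L) return(0)
  length(intersect(s1, s2)) / u
}

#' Aggregate protein-protein similarity AS
#'
#' The arithmetic mean of the three evidence channels:
#' `AS = (SS + FS + DS) / 3` where SS is sequence similarity, FS the GO
#' term Jaccard and DS the Pfam domain Jaccard.  A missing evidence channel
#' contributes 0 rather than renormalizing the mean over the available
#' channels.
#'
#' @param ss,fs,ds Component similarities, each in `[0, 1]`.
#' @return AS in `[0, 1]`.
#' @export
aggregate_similarity <- function(ss, fs, ds) {
  v <- c(ss, fs, ds)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("similarity components must lie in [0, 1]")
  (ss + fs + ds) / 3
}

#' Build the aggregated protein-protein similarity matrix
#'
#' For every pair of proteins computes the sequence similarity (normalized
#' Smith-Waterman), the GO-term Jaccard and the domain Jaccard, and
#' aggregates them with [aggregate_similarity()].  Proteins missing from an
#' annotation table contribute an empty set (Jaccard 0 against everything).
#'
#' @param proteins A `seq_set` of protein sequences (see [read_fasta()]).
#' @param go,domains Optional `annotation_table`s (see [read_annotations()]).
#' @param params An [alignment_params()] object.
#' @return A symmetric numeric matrix with protein ids as dimnames; every
#'   entry lies in `[0, 1]`.
#' @export
build_similarity_matrix <- function(proteins, go = NULL, domains = NULL,
                                    params = alignment_params()) {
  ids <- names(proteins)
  n <- length(ids)
  stopifnot(n >= 1, !anyDuplicated(ids))
  seqs <- as.character(proteins)

  self <- vapply(seqs, function(s) sw_score(s, s, params), numeric(1))
  if (any(self == 0))
    stop("self-alignment score is 0 for: ",
         paste(ids[self == 0], collapse = ", "))
  ss <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      raw <- sw_scores_vs(seqs[rest], seqs[i], params)
      ss[i, rest] <- ss[rest, i] <- raw / sqrt(self[i] * self[rest])
    }
  }

  go_sets <- lapply(ids, function(id) get_annotations(go, id))
  dom_sets <- lapply(ids, function(id) get_annotations(domains, id))
  fs <- matrix(0, n, n)
  ds <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    fs[i, j] <- fs[j, i] <- jaccard(go_sets[[i]], go_sets[[j]])
    ds[i, j] <- ds[j, i] <- jaccard(dom_sets[[i]], dom_sets[[j]])
  }

  as_mat <- (ss + fs + ds) / 3
  dimnames(as_mat) <- list(ids, ids)
  as_mat
}

#' Write / read a similarity matrix as tab-separated text
#'
#' Protein ids form the first row and first column.
#'
#' @param sp A similarity matrix from [build_similarity_matrix()].
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_matrix <- function(sp, path) {
  utils::write.table(sp, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
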