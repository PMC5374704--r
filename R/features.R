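#' @name feature-space
#' @title The paired triad x k-nucleotide feature space
#'
#' @description
#' A protein-RNA pair is encoded over 5376 paired (k+3)-mer dimensions.
#' The protein contributes conjoint triads — three consecutive residues
#' identified up to the reduced 4-class alphabet `{DE}`, `{HRK}`,
#' `{CGNQSTY}`, `{AFILMPVW}` (64 triad classes).  The RNA contributes
#' k-nucleotide units (k-NAs) for k = 1, 2, 3 (4, 16 and 64 distinct
#' units).  Pairing every triad class with every k-NA yields 256 4-mers,
#' 1024 5-mers and 4096 6-mers; a feature vector stores them in the order
#' 6-mers, 5-mers, 4-mers, each block lexicographic by (k-NA, triad class
#' triple).
NULL

# residue -> class index; 1 = {DE}, 2 = {HRK}, 3 = {CGNQSTY}, 4 = {AFILMPVW}
RESIDUE_CLASS <- c(
  D = 1L, E = 1L,
  H = 2L, R = 2L, K = 2L,
  C = 3L, G = 3L, N = 3L, Q = 3L, S = 3L, T = 3L, Y = 3L,
  A = 4L, F = 4L, I = 4L, L = 4L, M = 4L, P = 4L, V = 4L, W = 4L)

RNA_ALPHABET <- c("A", "C", "G", "U")

N_TRIAD_CLASSES <- 64L
KMER_TYPE_SIZES <- c(`1` = 256L, `2` = 1024L, `3` = 4096L)  # 4-, 5-, 6-mers
N_FEATURES <- 5376L

#' Encode a protein sequence over the 4-class residue alphabet
#'
#' @param seq Protein sequence (character scalar).
#' @return Integer vector of class indices in `{1, 2, 3, 4}`, one per
#'   residue; positions holding non-standard letters are `NA` and are
#'   excluded from triad counting.
#' @export
encode_residue_classes <- function(seq) {
  unname(RESIDUE_CLASS[strsplit(toupper(seq), "")[[1]]])
}

triad_class_labels <- function() {
  g <- expand.grid(c3 = 1:4, c2 = 1:4, c1 = 1:4)
  paste0(g$c1, g$c2, g$c3)[order(paste0(g$c1, g$c2, g$c3))]
}

#' Conjoint-triad class counts of a protein sequence
#'
#' Slides a width-3 window over the residue-class encoding; each window is
#' one conjoint triad, identified by its class triple.  Windows touching a
#' non-standard residue are skipped.
#'
#' @param seq Protein sequence.
#' @return Named integer vector of length 64 (names `"111"` ... `"444"`),
#'   summing to `length - 2` minus the number of skipped windows.
#' @export
triad_counts <- function(seq) {
  cls <- encode_residue_classes(seq)
  counts <- stats::setNames(integer(N_TRIAD_CLASSES), triad_class_labels())
  L <- length(cls)
  if (L < 3L) return(counts)
  c1 <- cls[1:(L - 2L)]; c2 <- cls[2:(L - 1L)]; c3 <- cls[3:L]
  ok <- !(is.na(c1) | is.na(c2) | is.na(c3))
  if (!any(ok)) return(counts)
  tab <- table(paste0(c1[ok], c2[ok], c3[ok]))
  counts[names(tab)] <- as.integer(tab)
  counts
}

all_knas <- function(k) {
  g <- do.call(expand.grid, rep(list(RNA_ALPHABET), k))
  sort(do.call(paste0, rev(g)))
}

#' k-nucleotide (k-NA) counts of an RNA sequence
#'
#' Slides a width-k window over the sequence; counts sum to
#' `max(length - k + 1, 0)`.
#'
#' @param seq RNA sequence over `{A, U, C, G}`.
#' @param k Unit size, 1 (uniNA), 2 (biNA) or 3 (triNA).
#' @return Named integer vector of length `4^k`, names in lexicographic
#'   order.
#' @export
kna_counts <- function(seq, k) {
  stopifnot(k %in% 1:3)
  counts <- stats::setNames(integer(4L^k), all_knas(k))
  L <- nchar(seq)
  if (L < k) return(counts)
  windows <- substring(seq, 1:(L - k + 1L), k:L)
  bad <- !windows %in% names(counts)
  if (any(bad)) stop("RNA sequence contains letters outside {A,U,C,G}")
  tab <- table(windows)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Concentration weight of a (k+3)-mer type
#'
#' The fraction of the 5376-dimensional feature space occupied by type-i
#' features: `C_i = N_i / (N_1 + N_2 + N_3)` with `N_1 = 256` (4-mers),
#' `N_2 = 1024` (5-mers), `N_3 = 4096` (6-mers).
#'
#' @param i Type index: 1 (4-mers), 2 (5-mers) or 3 (6-mers).
#' @return `C_i` in `(0, 1)`; the three concentrations sum to 1.
#' @export
concentration <- function(i) {
  stopifnot(all(i %in% 1:3))
  unname(KMER_TYPE_SIZES[as.character(i)] / N_FEATURES)
}

#' Names of the 5376 feature dimensions
#'
#' Blocks in the order 6-mers (4096), 5-mers (1024), 4-mers (256); within
#' a block lexicographic by (k-NA string, triad class triple).  Format:
#' `"<kNA>-<classTriple>"`, e.g. `"CCU-444"`.
#'
#' @return Character vector of length 5376.
#' @export
feature_names <- function() {
  tri <- triad_class_labels()
  unlist(lapply(c(3L, 2L, 1L), function(k)
    as.vector(vapply(all_knas(k), function(w) paste0(w, "-", tri),
                     character(N_TRIAD_CLASSES)))),
    use.names = FALSE)
}

# raw (un-normalized) feature vector: t_j * C_i per block
raw_feature_vector <- function(tri_counts, kna1, kna2, kna3) {
  c(as.vector(outer(tri_counts, kna3)) * concentration(3),
    as.vector(outer(tri_counts, kna2)) * concentration(2),
    as.vector(outer(tri_counts, kna1)) * concentration(1))
}

# min-max rescale a vector to [0, 1]; a constant vector maps to all zeros
min_max <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Encode one protein-RNA pair as a 5376-dimensional feature vector
#'
#' The raw value of the dimension pairing triad class `c` with k-NA `w` is
#' `t * C_i`, where `t` is the product of the triad-class count in the
#' protein and the k-NA count in the RNA (one occurrence of the paired
#' unit per co-occurrence of its two components), and `C_i` is the
#' concentration weight of the block.  With `normalize = TRUE` the vector
#' is min-max rescaled over its 5376 entries (a constant raw vector maps
#' to all zeros).
#'
#' @param protein Protein sequence (character scalar).
#' @param rna RNA sequence over `{A, U, C, G}`.
#' @param normalize Apply the per-vector min-max rescaling?
#' @return Named numeric vector of length 5376 (names from
#'   [feature_names()]).
#' @export
featurize_pair <- function(protein, rna, normalize = TRUE) {
  f <- raw_feature_vector(triad_counts(protein),
                          kna_counts(rna, 1L), kna_counts(rna, 2L),
                          kna_counts(rna, 3L))
  if (normalize) f <- min_max(f)
  stats::setNames(f, feature_names())
}

#' Enumerate the sequence units of one protein-RNA pair
#'
#' A readable inventory of what [featurize_pair()] counts: the literal
#' conjoint triads grouped by residue class, the distinct k-NAs for
#' k = 1, 2, 3, and the literal (k+3)-mer pairings (every present k-NA
#' matched with every present literal triad).
#'
#' @inheritParams featurize_pair
#' @return A list with components `triads` (list of literal triad vectors,
#'   named by class triple), `knas` (list of distinct k-NA vectors, named
#'   `"1"`, `"2"`, `"3"`) and `pairings` (list of literal
#'   `"<kNA>-<triad>"` labels per k).
#' @examples
#' units <- enumerate_pair_units("DPPVPPPPPV", "CCUCU")
#' length(units$triads)        # 2 triad classes
#' length(units$pairings$`3`)  # 15 six-mers
#' @export
enumerate_pair_units <- function(protein, rna) {
  res <- strsplit(toupper(protein), "")[[1]]
  cls <- encode_residue_classes(protein)
  L <- length(res)
  triads <- character(); triad_cls <- character()
  if (L >= 3L) for (i in 1:(L - 2L)) {
    cc <- cls[i:(i + 2L)]
    if (anyNA(cc)) next
    triads <- c(triads, paste(res[i:(i + 2L)], collapse = ""))
    triad_cls <- c(triad_cls, paste(cc, collapse = ""))
  }
  keep <- !duplicated(triads)
  triads <- triads[keep]; triad_cls <- triad_cls[keep]
  tri_by_class <- split(triads, triad_cls)

  knas <- lapply(1:3, function(k) {
    n <- kna_counts(rna, k)
    names(n)[n > 0L]
  })
  names(knas) <- as.character(1:3)

  pairings <- lapply(knas, function(ws)
    as.vector(outer(ws, triads, paste, sep = "-")))
  list(triads = tri_by_class, knas = knas, pairings = pairings)
}

#' Build a labeled feature dataset from positive and negative pairs
#'
#' Encodes every pair with [featurize_pair()] (triad and k-NA counts are
#' cached per sequence, so large pair sets reuse the per-sequence work).
#'
#' @param positives,negatives [interaction_set()]s.
#' @param proteins,rnas `seq_set`s resolving every id in the pair sets.
#' @return A `pri_dataset`: list with `features` (pairs x 5376 matrix),
#'   `labels` (factor, levels `negative`, `positive`) and `pairs` (data
#'   frame of the encoded (protein, rna) ids, row-aligned with
#'   `features`).
#' @export
build_dataset <- function(positives, negatives, proteins, rnas) {
  pairs <- rbind(data.frame(protein = positives$protein, rna = positives$rna,
                            label = "positive", stringsAsFactors = FALSE),
                 data.frame(protein = negatives$protein, rna = negatives$rna,
                            label = "negative", stringsAsFactors = FALSE))
  bad <- setdiff(c(pairs$protein, pairs$rna), c(names(proteins), names(rnas)))
  if (length(bad)) stop("unresolved id(s): ", paste(bad, collapse = ", "))

  pid <- unique(pairs$protein)
  rid <- unique(pairs$rna)
  tri <- lapply(stats::setNames(pid, pid),
                function(p) triad_counts(proteins[[p]]))
  kn <- lapply(stats::setNames(rid, rid), function(r)
    list(kna_counts(rnas[[r]], 1L), kna_counts(rnas[[r]], 2L),
         kna_counts(rnas[[r]], 3L)))

  x <- matrix(0, nrow(pairs), N_FEATURES,
              dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(pairs))) {
    k <- kn[[pairs$rna[i]]]
    x[i, ] <- min_max(raw_feature_vector(tri[[pairs$protein[i]]],
                                         k[[1L]], k[[2L]], k[[3L]]))
  }
  pri_dataset(x, factor(pairs$label, levels = c("negative", "positive")),
              pairs = pairs[, c("protein", "rna")])
}
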