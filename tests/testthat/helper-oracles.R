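# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Smith-Waterman local alignment with affine gaps (Gotoh), where a gap of
# length L costs open + extend * L.  Quadratic DP over explicit matrices.
oracle_sw <- function(a, b, mat, open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + extend), E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - (open + extend), F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_nsw <- function(a, b, open = 10, extend = 0.5) {
  oracle_sw(a, b, blosum62, open, extend) /
    (sqrt(oracle_sw(a, a, blosum62, open, extend)) *
       sqrt(oracle_sw(b, b, blosum62, open, extend)))
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "U", "C", "G"), len, TRUE), collapse = "")
}

# Exhaustive FIRE selection: enumerate and score every non-positive cell of
# the protein x RNA grid with explicit loops, sort, take m.
oracle_fire_select <- function(sp, positives, m) {
  pid <- sort(unique(positives$protein))
  rid <- sort(unique(positives$rna))
  rows <- NULL
  for (p in pid) for (r in rid) {
    if (any(positives$protein == p & positives$rna == r)) next
    s <- 0
    for (k in pid) {
      if (k != p && any(positives$protein == k & positives$rna == r))
        s <- s + sp[p, k]
    }
    rows <- rbind(rows, data.frame(protein = p, rna = r, score = s,
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$score, rows$protein, rows$rna, method = "radix"), ]
  utils::head(rows, m)
}

# Naive pair-materialization of the (k+3)-mer encoding: walk every (triad
# window, k-NA window) pair of positions and increment the corresponding
# dimension, then weight by concentration and min-max rescale.
oracle_featurize <- function(protein, rna) {
  cls_of <- c(D = 1, E = 1, H = 2, R = 2, K = 2,
              C = 3, G = 3, N = 3, Q = 3, S = 3, T = 3, Y = 3,
              A = 4, F = 4, I = 4, L = 4, M = 4, P = 4, V = 4, W = 4)
  res <- strsplit(protein, "")[[1]]
  Lp <- length(res); Lr <- nchar(rna)
  counts <- stats::setNames(numeric(length(feature_names())), feature_names())
  conc <- c(`1` = 256 / 5376, `2` = 1024 / 5376, `3` = 4096 / 5376)
  if (Lp >= 3) for (i in 1:(Lp - 2)) {
    cc <- cls_of[res[i:(i + 2)]]
    if (anyNA(cc)) next
    triple <- paste(cc, collapse = "")
    for (k in 1:3) {
      if (Lr < k) next
      for (j in 1:(Lr - k + 1)) {
        w <- substr(rna, j, j + k - 1)
        dim <- paste0(w, "-", triple)
        counts[dim] <- counts[dim] + conc[as.character(k)]
      }
    }
  }
  lo <- min(counts); hi <- max(counts)
  if (hi == lo) counts[] <- 0 else counts <- (counts - lo) / (hi - lo)
  counts
}

# Small deterministic toy system for selection tests: 4 proteins x 3 RNAs
# with a hand-built similarity matrix and 4 positives.
toy_system <- function() {
  pid <- c("pa", "pb", "pc", "pd")
  sp <- matrix(c(1.0, 0.8, 0.2, 0.1,
                 0.8, 1.0, 0.3, 0.2,
                 0.2, 0.3, 1.0, 0.7,
                 0.1, 0.2, 0.7, 1.0),
               4, 4, dimnames = list(pid, pid))
  positives <- interaction_set(c("pa", "pb", "pc", "pd"),
                               c("r1", "r1", "r2", "r3"),
                               label = "positive")
  list(sp = sp, positives = positives, proteins = pid,
       rnas = c("r1", "r2", "r3"))
}
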