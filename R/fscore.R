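#' FScore filter statistics for a labeled feature dataset
#'
#' For each feature, its normalized values are summed over the positive
#' samples and over the negative samples, giving two per-feature frequency
#' profiles.  Each profile is min-max rescaled across the 5376 features
#' (the same rescaling applied to individual feature vectors), floored at
#' `eps`, and the FScore is the ratio positive/negative.  Features
#' enriched in positives score above 1, features enriched in negatives
#' below 1; features never observed in either class score exactly 1
#' (neutral).
#'
#' @param dataset A `pri_dataset` with at least one sample in each class.
#' @param eps Floor applied to both normalized profiles before the ratio;
#'   defaults to `1 / (2 * ncol)`, half the mass a single observation of
#'   the rarest feature would carry.
#' @return An object of class `"fscore_table"`: list with `score`,
#'   `f_pos`, `f_neg` (raw per-class sums) and `ff_pos`, `ff_neg`
#'   (normalized, floored profiles), all named by feature.
#' @export
fscore_table <- function(dataset, eps = 1 / (2 * ncol(dataset$features))) {
  x <- dataset$features
  y <- dataset$labels
  if (!any(y == "positive") || !any(y == "negative"))
    stop("dataset must contain at least one positive and one negative sample")
  f_pos <- colSums(x[y == "positive", , drop = FALSE])
  f_neg <- colSums(x[y == "negative", , drop = FALSE])
  ff_pos <- pmax(min_max(f_pos), eps)
  ff_neg <- pmax(min_max(f_neg), eps)
  structure(list(score = ff_pos / ff_neg, f_pos = f_pos, f_neg = f_neg,
                 ff_pos = ff_pos, ff_neg = ff_neg, eps = eps),
            class = "fscore_table")
}

#' @export
print.fscore_table <- function(x, ...) {
  cat("FScore table over", length(x$score), "features\n")
  cat("  score range:", format(range(x$score)), "\n")
  cat("  features > 1 (positive-enriched):", sum(x$score > 1),
      "; < 1 (negative-enriched):", sum(x$score < 1), "\n")
  invisible(x)
}

#' Select the k most discriminative features by FScore
#'
#' Keeps the `k/2` features with the largest FScore (positive-enriched)
#' and the `k/2` with the smallest (negative-enriched).  Ties are broken
#' by ascending feature index; if the two halves would overlap (too few
#' distinct scores for the requested `k`), an error is raised.
#'
#' @param table An [fscore_table()].
#' @param k Even target dimensionality, at most the number of features.
#'   The default 1000 is the standard reduced dimension.
#' @return Integer vector of `k` distinct feature indices in ascending
#'   order.
#' @export
select_features <- function(table, k = 1000) {
  score <- table$score
  n <- length(score)
  if (k %% 2 != 0) stop("k must be even")
  if (k > n) stop("k exceeds the number of features (", n, ")")
  idx <- seq_len(n)
  top <- idx[order(-score, idx)][seq_len(k / 2)]
  bottom <- idx[order(score, idx)][seq_len(k / 2)]
  overlap <- intersect(top, bottom)
  if (length(overlap))
    stop("top and bottom halves overlap (", length(overlap),
         " feature(s)); too few distinct FScore values for k = ", k)
  sort(c(top, bottom))
}

#' Reduce a dataset to the FScore-selected features
#'
#' Convenience wrapper: compute the FScore table on `dataset` and keep the
#' `k` selected columns.
#'
#' @inheritParams select_features
#' @param dataset A `pri_dataset`.
#' @return A `pri_dataset` with `k` feature columns, plus the selected
#'   indices in attribute `"selected"`.
#' @export
reduce_dataset <- function(dataset, k = 1000) {
  sel <- select_features(fscore_table(dataset), k)
  out <- pri_dataset(dataset$features[, sel, drop = FALSE], dataset$labels,
                     pairs = dataset$pairs)
  attr(out, "selected") <- sel
  out
}
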