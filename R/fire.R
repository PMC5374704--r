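#' Fit a FIRE interaction-confidence model
#'
#' FIRE ranks every candidate (protein, RNA) pair that is *not* a known
#' interaction by a similarity-transfer score
#' \deqn{SPR_{ij} = \sum_k \delta(k, j)\, SP_{ik},}
#' the sum of the aggregated similarities between protein \eqn{i} and every
#' protein \eqn{k} known to bind RNA \eqn{j}.  A low score marks a pair
#' that no protein similar to \eqn{i} is known to realize — a reliable
#' negative; a high score marks a likely undiscovered interaction.
#'
#' The candidate universe is the cross product of the proteins and RNAs
#' appearing in the positive set, minus the positive set itself.
#'
#' @param positives An [interaction_set()] of known positive pairs.
#' @param proteins A `seq_set` of protein sequences covering every protein
#'   id in `positives`.
#' @param rnas A `seq_set` of RNA sequences covering every RNA id in
#'   `positives` (sequences are not needed for scoring, but anchor the
#'   candidate universe and downstream feature encoding).
#' @param go,domains Optional `annotation_table`s used for the aggregated
#'   protein-protein similarity.
#' @param params An [alignment_params()] object.
#' @param sp Optional precomputed similarity matrix (dimnames must cover
#'   the positive-set proteins); when supplied, sequence alignment is
#'   skipped.
#' @return An object of class `"fire"` with components `protein_ids`,
#'   `rna_ids`, `positives`, `sp` (the similarity matrix restricted to the
#'   candidate proteins) and `spr` (the protein x RNA score matrix, `NA`
#'   at positive cells).
#' @seealso [negatives()] to extract a negative set, [predict.fire()] to
#'   rank candidate positives.
#' @export
fire <- function(positives, proteins, rnas, go = NULL, domains = NULL,
                 params = alignment_params(), sp = NULL) {
  stopifnot(inherits(positives, "interaction_set"))
  if (attr(positives, "label") != "positive")
    stop("`positives` must be a positive interaction set")
  if (nrow(positives) == 0L) stop("positive set is empty")

  prot_ids <- sort(unique(positives$protein))
  rna_ids <- sort(unique(positives$rna))
  missing_p <- setdiff(prot_ids, names(proteins))
  if (length(missing_p))
    stop("positive pairs reference unknown protein(s): ",
         paste(missing_p, collapse = ", "))
  missing_r <- setdiff(rna_ids, names(rnas))
  if (length(missing_r))
    stop("positive pairs reference unknown RNA(s): ",
         paste(missing_r, collapse = ", "))

  if (is.null(sp)) {
    sp <- build_similarity_matrix(proteins[prot_ids], go, domains, params)
  } else {
    if (!all(prot_ids %in% rownames(sp)))
      stop("supplied similarity matrix does not cover all positive-set proteins")
    sp <- sp[prot_ids, prot_ids, drop = FALSE]
  }

  inc <- matrix(0, length(prot_ids), length(rna_ids),
                dimnames = list(prot_ids, rna_ids))
  inc[cbind(match(positives$protein, prot_ids),
            match(positives$rna, rna_ids))] <- 1
  spr <- sp %*% inc                       # row i, col j: sum_k SP_ik * inc_kj
  spr[inc == 1] <- NA_real_               # positives are not candidates

  structure(list(protein_ids = prot_ids, rna_ids = rna_ids,
                 positives = positives, sp = sp, spr = spr,
                 call = match.call()),
            class = "fire")
}

#' @export
print.fire <- function(x, ...) {
  cat("FIRE model\n")
  cat("  proteins:", length(x$protein_ids),
      " RNAs:", length(x$rna_ids),
      " positives:", nrow(x$positives), "\n")
  cat("  candidate pairs:", sum(!is.na(x$spr)), "\n")
  invisible(x)
}

#' @export
summary.fire <- function(object, ...) {
  sc <- object$spr[!is.na(object$spr)]
  structure(list(n_proteins = length(object$protein_ids),
                 n_rnas = length(object$rna_ids),
                 n_positives = nrow(object$positives),
                 n_candidates = length(sc),
                 score_quantiles = stats::quantile(sc),
                 zero_score_fraction = mean(sc == 0)),
            class = "summary.fire")
}

#' @export
print.summary.fire <- function(x, ...) {
  cat("FIRE model summary\n")
  cat("  proteins:", x$n_proteins, " RNAs:", x$n_rnas,
      " positives:", x$n_positives, "\n")
  cat("  candidate pairs:", x$n_candidates,
      sprintf("(%.1f%% with score 0)\n", 100 * x$zero_score_fraction))
  cat("  SPR score quantiles:\n")
  print(round(x$score_quantiles, 4))
  invisible(x)
}

#' @export
plot.fire <- function(x, breaks = 30, main = "Candidate-pair SPR scores",
                      xlab = "SPR score", ...) {
  sc <- x$spr[!is.na(x$spr)]
  graphics::hist(sc, breaks = breaks, main = main, xlab = xlab, ...)
  invisible(x)
}

#' Rank candidate pairs as putative new positives
#'
#' For each RNA, returns the `top_per_rna` highest-scoring candidate
#' proteins whose SPR score exceeds `min_score`.  RNAs whose candidates
#' all fall at or below the floor yield no predictions.
#'
#' @param object A fitted [fire()] model.
#' @param top_per_rna Number of predictions retained per RNA.
#' @param min_score Strict lower bound on the SPR score of a reported
#'   pair.  The default 1 keeps only pairs backed by more aggregate
#'   similarity than one identical annotated protein would contribute.
#' @param ... Unused.
#' @return An [interaction_set()] (label `"positive"`) with a `score`
#'   column, ordered by RNA id then descending score.
#' @export
predict.fire <- function(object, top_per_rna = 4, min_score = 1, ...) {
  stopifnot(top_per_rna >= 1)
  out <- lapply(object$rna_ids, function(r) {
    sc <- object$spr[, r]
    keep <- which(!is.na(sc) & sc > min_score)
    if (!length(keep)) return(NULL)
    ord <- order(-sc[keep], object$protein_ids[keep], method = "radix")
    take <- keep[ord][seq_len(min(top_per_rna, length(keep)))]
    data.frame(protein = object$protein_ids[take], rna = r,
               score = unname(sc[take]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(interaction_set(label = "positive", score = numeric()))
  interaction_set(out$protein, out$rna, label = "positive", score = out$score)
}

#' Extract a negative interaction set from a FIRE model
#'
#' @param object A fitted [fire()] model.
#' @param m Number of negative pairs to produce.  Defaults to the positive
#'   set size (a 1:1 positive-to-negative ratio); the presets `ratio =
#'   "2:1"` and `"1:2"` give half and double the positive count.
#' @param method `"fire"` (ascending SPR score), `"random"` (uniform
#'   without replacement), or `"threshold"` (scores closest to `st`).
#' @param st Score threshold for `method = "threshold"`.
#' @param seed Random seed for `method = "random"`.
#' @param ratio Optional `"1:1"`, `"2:1"` or `"1:2"` positive:negative
#'   preset used when `m` is not given.
#' @param ... Unused.
#' @return An [interaction_set()] with label `"negative"` (with a `score`
#'   column for the scored methods).
#' @export
negatives <- function(object, ...) UseMethod("negatives")

#' @rdname negatives
#' @export
negatives.fire <- function(object, m = NULL,
                           method = c("fire", "random", "threshold"),
                           st = 0, seed = NULL, ratio = NULL, ...) {
  method <- match.arg(method)
  if (is.null(m)) {
    np <- nrow(object$positives)
    m <- if (is.null(ratio)) np else switch(
      match.arg(ratio, c("1:1", "2:1", "1:2")),
      "1:1" = np, "2:1" = ceiling(np / 2), "1:2" = 2L * np)
  }
  cand <- candidate_table(object)
  switch(method,
    fire = take_candidates(cand, m, order(cand$score, cand$protein,
                                          cand$rna, method = "radix"),
                           scores = TRUE),
    threshold = {
      stopifnot(st >= 0)
      take_candidates(cand, m, order(abs(cand$score - st), cand$protein,
                                     cand$rna, method = "radix"),
                      scores = TRUE)
    },
    random = {
      if (!is.null(seed)) {
        old <- get_rng_state()
        on.exit(restore_rng_state(old))
        set.seed(seed)
      }
      take_candidates(cand, m, sample.int(nrow(cand)), scores = FALSE)
    })
}

candidate_table <- function(object) {
  idx <- which(!is.na(object$spr), arr.ind = TRUE)
  data.frame(protein = object$protein_ids[idx[, 1L]],
             rna = object$rna_ids[idx[, 2L]],
             score = object$spr[idx], stringsAsFactors = FALSE)
}

take_candidates <- function(cand, m, ord, scores) {
  if (m < 1) stop("m must be >= 1")
  if (m > nrow(cand))
    stop("m = ", m, " exceeds the number of candidate pairs (",
         nrow(cand), ")")
  sel <- cand[ord[seq_len(m)], , drop = FALSE]
  interaction_set(sel$protein, sel$rna, label = "negative",
                  score = if (scores) sel$score else NULL)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- standalone functional forms -------------------------------------------

#' Enumerate candidate (protein, RNA) pairs
#'
#' The full cross product of the given proteins and RNAs minus the positive
#' set, in lexicographic (protein, rna) order.
#'
#' @param proteins,rnas `seq_set`s or character vectors of ids.
#' @param positives An [interaction_set()] of known positives.
#' @return A data frame with columns `protein` and `rna`.
#' @export
candidate_pairs <- function(proteins, rnas, positives) {
  pid <- sort(if (is.character(proteins)) proteins else names(proteins))
  rid <- sort(if (is.character(rnas)) rnas else names(rnas))
  bad_p <- setdiff(positives$protein, pid)
  bad_r <- setdiff(positives$rna, rid)
  if (length(bad_p) || length(bad_r))
    stop("positive pairs reference unknown id(s): ",
         paste(c(bad_p, bad_r), collapse = ", "))
  grid <- expand.grid(rna = rid, protein = pid,
                      stringsAsFactors = FALSE)[, c("protein", "rna")]
  keep <- !(pair_keys(grid) %in% pair_keys(positives))
  rownames(grid) <- NULL
  grid[keep, , drop = FALSE]
}

#' Randomly sampled negative pairs
#'
#' The classical construction: sample `m` pairs uniformly without
#' replacement from the candidate pairs (cross product minus positives).
#'
#' @inheritParams candidate_pairs
#' @param m Number of negatives.
#' @param seed Random seed (reproducible for a fixed seed).
#' @return An [interaction_set()] with label `"negative"`.
#' @export
random_negatives <- function(proteins, rnas, positives, m, seed = NULL) {
  cand <- candidate_pairs(proteins, rnas, positives)
  if (m > nrow(cand))
    stop("m = ", m, " exceeds the number of candidate pairs (",
         nrow(cand), ")")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  sel <- cand[sample.int(nrow(cand), m), , drop = FALSE]
  interaction_set(sel$protein, sel$rna, label = "negative")
}

#' SPR confidence score of one candidate pair
#'
#' The sum, over every protein `k` known to bind `rna`, of the similarity
#' `SP[protein, k]`.  Zero when the RNA has no positive partner other than
#' `protein` itself.
#'
#' @param protein,rna Identifiers of the candidate pair (must not be a
#'   positive pair).
#' @param positives An [interaction_set()] of known positives.
#' @param sp Similarity matrix with protein ids as dimnames.
#' @return A non-negative score.
#' @export
spr_score <- function(protein, rna, positives, sp) {
  if (!protein %in% rownames(sp)) stop("unknown protein id: ", protein)
  if (any(positives$protein == protein & positives$rna == rna))
    stop("(", protein, ", ", rna, ") is a positive pair; SPR is only ",
         "defined for candidate pairs")
  partners <- setdiff(positives$protein[positives$rna == rna], protein)
  bad <- setdiff(partners, rownames(sp))
  if (length(bad)) stop("unknown protein id(s): ", paste(bad, collapse = ", "))
  if (!length(partners)) return(0)
  sum(sp[protein, partners])
}

#' FIRE-selected negative pairs (standalone form)
#'
#' Scores every candidate pair with [spr_score()] and returns the `m`
#' lowest-scoring pairs (ties broken lexicographically by protein then RNA
#' id).
#'
#' @inheritParams random_negatives
#' @param sp Similarity matrix over the candidate proteins.
#' @return An [interaction_set()] with label `"negative"` and a `score`
#'   column.
#' @export
fire_negatives <- function(proteins, rnas, positives, sp, m) {
  object <- fire_from_sp(proteins, rnas, positives, sp)
  negatives(object, m = m, method = "fire")
}

#' Threshold-selected negative pairs (standalone form)
#'
#' Returns the `m` candidate pairs whose SPR scores are closest to the
#' threshold `st` (ties broken by absolute difference, then protein then
#' RNA id).  `st = 0` reproduces the FIRE selection.
#'
#' @inheritParams fire_negatives
#' @param st Non-negative score threshold.
#' @export
threshold_negatives <- function(proteins, rnas, positives, sp, m, st) {
  object <- fire_from_sp(proteins, rnas, positives, sp)
  negatives(object, m = m, method = "threshold", st = st)
}

#' Rank candidate positives (standalone form)
#'
#' @inheritParams fire_negatives
#' @param top_per_rna,min_score See [predict.fire()].
#' @export
rank_candidate_positives <- function(proteins, rnas, positives, sp,
                                     top_per_rna = 4, min_score = 1) {
  object <- fire_from_sp(proteins, rnas, positives, sp)
  predict(object, top_per_rna = top_per_rna, min_score = min_score)
}

# Build a fire object from ids + a precomputed similarity matrix, without
# requiring sequences (used by the standalone functional forms).  Unlike
# fire(), the candidate universe is the ids the caller passes, which may
# extend beyond the positive set.
fire_from_sp <- function(proteins, rnas, positives, sp) {
  pid <- sort(unique(if (is.character(proteins)) proteins
                     else names(proteins)))
  rid <- sort(unique(if (is.character(rnas)) rnas else names(rnas)))
  if (!all(positives$protein %in% pid) || !all(positives$rna %in% rid))
    stop("positive pairs reference ids outside the given universe")
  if (!all(pid %in% rownames(sp)))
    stop("similarity matrix does not cover all candidate proteins")
  sp <- sp[pid, pid, drop = FALSE]
  inc <- matrix(0, length(pid), length(rid), dimnames = list(pid, rid))
  inc[cbind(match(positives$protein, pid), match(positives$rna, rid))] <- 1
  spr <- sp %*% inc
  spr[inc == 1] <- NA_real_
  structure(list(protein_ids = pid, rna_ids = rid, positives = positives,
                 sp = sp, spr = spr, call = match.call()),
            class = "fire")
}
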