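#' Generate a synthetic protein-RNA interactome with planted similarity
#' structure
#'
#' Emulates the statistical premise of similarity-transfer negative
#' selection: proteins fall into groups of homologs (each group derived
#' from one ancestral sequence by per-site mutation, sharing core GO terms
#' and Pfam-like domains), and every RNA interacts with *all* proteins of
#' the 1-2 groups it is assigned to.  The observed positive set is a
#' uniform subsample of this ground truth, so candidate pairs split into
#' true-but-unobserved interactions (which a good negative selector must
#' avoid) and genuine non-interactions.
#'
#' @param n_groups Number of protein similarity groups.
#' @param proteins_per_group Proteins per group.
#' @param n_rnas Number of RNAs.
#' @param mutation_rate Per-site probability that a group member differs
#'   from the group ancestor (substitution to a uniformly chosen other
#'   residue), in `[0, 1)`.
#' @param observation_fraction Fraction of true interactions present in
#'   the observed positive set, in `(0, 1]`.
#' @param seed Random seed; a fixed seed regenerates the identical world.
#' @param protein_length,rna_length Length ranges (uniform) for ancestral
#'   protein and RNA sequences.
#' @param go_core,go_noise Shared core GO terms per group / private noise
#'   terms per protein.
#' @param domain_core,domain_noise Shared core domains per group / private
#'   noise domains per protein.
#' @return An object of class `"synthetic_world"`: list with `proteins`,
#'   `rnas` (`seq_set`s), `go`, `domains` (`annotation_table`s), `truth`
#'   and `observed` ([interaction_set()]s, observed being a subset of
#'   truth), `group_of` (named group index per protein) and `params`.
#' @export
generate_world <- function(n_groups = 5, proteins_per_group = 8, n_rnas = 40,
                           mutation_rate = 0.1, observation_fraction = 0.6,
                           seed = 1,
                           protein_length = c(50L, 300L),
                           rna_length = c(20L, 200L),
                           go_core = 6, go_noise = 2,
                           domain_core = 3, domain_noise = 1) {
  stopifnot(n_groups >= 1, proteins_per_group >= 1, n_rnas >= 1,
            mutation_rate >= 0, mutation_rate < 1,
            observation_fraction > 0, observation_fraction <= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  aa <- strsplit(AA_STANDARD, "")[[1]]
  prot_seqs <- character(); group_of <- integer()
  go_tab <- list(); dom_tab <- list()
  for (g in seq_len(n_groups)) {
    len <- sample(protein_length[1]:protein_length[2], 1L)
    ancestor <- sample(aa, len, replace = TRUE)
    core_go <- sprintf("GO:g%d:%d", g, seq_len(go_core))
    core_dom <- sprintf("PF:g%d:%d", g, seq_len(domain_core))
    for (p in seq_len(proteins_per_group)) {
      id <- sprintf("g%dp%d", g, p)
      s <- ancestor
      mut <- stats::runif(len) < mutation_rate
      if (any(mut))
        s[mut] <- vapply(s[mut], function(r) sample(setdiff(aa, r), 1L),
                         character(1))
      prot_seqs[id] <- paste(s, collapse = "")
      group_of[id] <- g
      go_tab[[id]] <- c(core_go,
                        if (go_noise > 0) sprintf("GO:n:%s:%d", id,
                                                  seq_len(go_noise)))
      dom_tab[[id]] <- c(core_dom,
                         if (domain_noise > 0) sprintf("PF:n:%s:%d", id,
                                                       seq_len(domain_noise)))
    }
  }

  rna_seqs <- character()
  truth_p <- character(); truth_r <- character()
  for (j in seq_len(n_rnas)) {
    id <- sprintf("r%03d", j)
    len <- sample(rna_length[1]:rna_length[2], 1L)
    rna_seqs[id] <- paste(sample(RNA_ALPHABET, len, replace = TRUE),
                          collapse = "")
    groups <- sample(seq_len(n_groups), sample(1:2, 1L))
    partners <- names(group_of)[group_of %in% groups]
    truth_p <- c(truth_p, partners)
    truth_r <- c(truth_r, rep(id, length(partners)))
  }
  truth <- interaction_set(truth_p, truth_r, label = "positive")
  n_obs <- max(1L, round(observation_fraction * nrow(truth)))
  obs_idx <- sort(sample.int(nrow(truth), n_obs))
  observed <- interaction_set(truth$protein[obs_idx], truth$rna[obs_idx],
                              label = "positive")

  structure(list(
    proteins = seq_set(prot_seqs, "protein"),
    rnas = seq_set(rna_seqs, "rna"),
    go = annotation_table(go_tab, "go"),
    domains = annotation_table(dom_tab, "domain"),
    truth = truth, observed = observed, group_of = group_of,
    params = list(n_groups = n_groups,
                  proteins_per_group = proteins_per_group,
                  n_rnas = n_rnas, mutation_rate = mutation_rate,
                  observation_fraction = observation_fraction, seed = seed)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat("synthetic_world:", p$n_groups, "groups x", p$proteins_per_group,
      "proteins,", p$n_rnas, "RNAs\n")
  cat("  mutation rate", p$mutation_rate,
      "; observed", nrow(x$observed), "of", nrow(x$truth),
      "true interactions (seed", paste0(p$seed, ")\n"))
  invisible(x)
}

#' Fraction of a negative set that is secretly positive
#'
#' The fraction of selected negative pairs that are true (hidden)
#' interactions of a synthetic world — the quantity a reliable negative
#' selector minimizes.
#'
#' @param negatives An [interaction_set()] of selected negatives (must be
#'   disjoint from the world's observed positives and non-empty).
#' @param world A [generate_world()] object.
#' @return A fraction in `[0, 1]`.
#' @export
contamination_rate <- function(negatives, world) {
  if (nrow(negatives) == 0L)
    stop("contamination rate undefined for an empty negative set")
  if (any(pair_keys(negatives) %in% pair_keys(world$observed)))
    stop("negative set overlaps the observed positive set")
  mean(pair_keys(negatives) %in% pair_keys(world$truth))
}

#' Benchmark reliable against random negatives on a synthetic world
#'
#' Runs the full pipeline once per negative-selection method: fit the
#' similarity-transfer model on the observed positives, draw `m =`
#' #observed negatives (reliable and random), encode the dataset, reduce
#' to `k` features by FScore, and run stratified `folds`-fold
#' cross-validation.  Two confusions are pooled from the out-of-fold
#' predictions: one against the constructed dataset labels (what standard
#' cross-validation reports) and one against the world's hidden
#' ground-truth labels, under which a selected "negative" that is secretly
#' a true interaction counts as a positive.  The truth-referenced GM is
#' the headline benefit measure: a contaminated negative set both injects
#' label noise into training and mislabels its own evaluation pairs.
#'
#' @param world A [generate_world()] object.
#' @param classifier Passed to [cross_validate()].
#' @param k Reduced feature dimension (even), capped at 5376.
#' @param folds Cross-validation folds.
#' @param seed Seed for the random negative draw, fold assignment and
#'   classifier randomness.
#' @return List with `contamination` (named: fire, random), `gm`
#'   (truth-referenced GM, named: fire, random), `cv` (the two
#'   `"pri_metrics"` reports against dataset labels), `truth_metrics`
#'   (the two reports against ground truth), the selected `negatives`,
#'   and the fitted [fire()] `model`.
#' @export
negative_benefit <- function(world, classifier = "rf", k = 1000, folds = 10,
                             seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  fit <- fire(world$observed, world$proteins, world$rnas,
              go = world$go, domains = world$domains)
  m <- nrow(world$observed)
  neg <- list(fire = negatives(fit, m = m, method = "fire"),
              random = negatives(fit, m = m, method = "random"))

  eval_one <- function(negset) {
    train <- build_dataset(world$observed, negset,
                           world$proteins, world$rnas)
    train <- reduce_dataset(train, min(k, ncol(train$features)))
    cv <- cross_validate(train, classifier, folds = folds, seed = seed)
    y_true <- factor(ifelse(pair_keys(train$pairs) %in%
                              pair_keys(world$truth),
                            "positive", "negative"),
                     levels = c("negative", "positive"))
    truth <- confusion_metrics(
      tp = sum(y_true == "positive" & cv$predictions == "positive"),
      fn = sum(y_true == "positive" & cv$predictions == "negative"),
      tn = sum(y_true == "negative" & cv$predictions == "negative"),
      fp = sum(y_true == "negative" & cv$predictions == "positive"))
    truth$auc <- roc_auc(y_true, cv$scores)
    list(cv = cv, truth = truth)
  }
  reports <- lapply(neg, eval_one)

  list(contamination = vapply(neg, contamination_rate, numeric(1),
                              world = world),
       gm = vapply(reports, function(r) r$truth$gm, numeric(1)),
       cv = lapply(reports, `[[`, "cv"),
       truth_metrics = lapply(reports, `[[`, "truth"),
       negatives = neg, model = fit)
}

#' Cross-validated AUC as a function of the negative-score threshold
#'
#' Mirrors the score-threshold experiment: negatives are the `m`
#' candidate pairs whose SPR scores are closest to `st`, for `st` running
#' over `st_fractions * max(SPR)`; each resulting dataset (observed
#' positives + threshold negatives) is reduced by FScore and evaluated by
#' stratified cross-validation.  Raising the threshold admits
#' ever-more-plausible interactions into the negative set, so the AUC is
#' expected to fall.
#'
#' @param world A [generate_world()] object.
#' @param st_fractions Threshold positions as fractions of the maximum
#'   candidate score.
#' @param classifier,folds,k,seed See [cross_validate()] and
#'   [negative_benefit()].
#' @return Data frame with columns `st_fraction`, `st` and `auc`.
#' @export
threshold_experiment <- function(world,
                                 st_fractions = c(0, 0.2, 0.4, 0.7, 1),
                                 classifier = "rf", folds = 10, k = 1000,
                                 seed = 1) {
  fit <- fire(world$observed, world$proteins, world$rnas,
              go = world$go, domains = world$domains)
  s_max <- max(fit$spr, na.rm = TRUE)
  m <- nrow(world$observed)
  auc <- vapply(st_fractions, function(fr) {
    neg <- negatives(fit, m = m, method = "threshold", st = fr * s_max)
    train <- build_dataset(world$observed, neg, world$proteins, world$rnas)
    train <- reduce_dataset(train, min(k, ncol(train$features)))
    cross_validate(train, classifier, folds = folds, seed = seed)$auc
  }, numeric(1))
  data.frame(st_fraction = st_fractions, st = st_fractions * s_max,
             auc = auc)
}
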