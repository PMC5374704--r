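test_that("candidate pairs are the cross product minus the positive set", {
  pos <- interaction_set("p1", "r1", label = "positive")
  cand <- candidate_pairs(c("p1", "p2"), c("r1", "r2"), pos)
  expect_equal(nrow(cand), 3L)
  expect_false(any(cand$protein == "p1" & cand$rna == "r1"))

  full <- interaction_set(rep(c("p1", "p2"), each = 2),
                          rep(c("r1", "r2"), 2), label = "positive")
  expect_equal(nrow(candidate_pairs(c("p1", "p2"), c("r1", "r2"), full)), 0L)
  none <- interaction_set(label = "positive")
  expect_equal(nrow(candidate_pairs("p1", "r1", none)), 1L)
})

test_that("random negatives are uniform over candidates and seed-reproducible", {
  pos <- interaction_set("p1", "r1", label = "positive")
  prot <- paste0("p", 1:3); rna <- paste0("r", 1:3)

  n1 <- random_negatives(prot, rna, pos, m = 3, seed = 99)
  n2 <- random_negatives(prot, rna, pos, m = 3, seed = 99)
  expect_identical(as.data.frame(n1), as.data.frame(n2))

  all8 <- random_negatives(prot, rna, pos, m = 8, seed = 1)
  expect_setequal(paste(all8$protein, all8$rna),
                  paste(candidate_pairs(prot, rna, pos)$protein,
                        candidate_pairs(prot, rna, pos)$rna))
  expect_error(random_negatives(prot, rna, pos, m = 9), "exceeds")

  # empirical selection frequency ~ m/8 for each of the 8 candidates
  set.seed(123)
  m <- 2; reps <- 1000
  counts <- table(unlist(lapply(seq_len(reps), function(i) {
    s <- random_negatives(prot, rna, pos, m = m)
    paste(s$protein, s$rna)
  })))
  expect_equal(length(counts), 8L)
  freq <- as.numeric(counts) / reps
  expect_true(all(abs(freq - m / 8) < 4 * sqrt((m / 8) * (1 - m / 8) / reps)))
})

test_that("SPR score sums similarities over the RNA's positive partners", {
  toy <- toy_system()
  # r2's only partner is pc: SPR(pd, r2) = SP[pd, pc] = 0.7
  expect_equal(spr_score("pd", "r2", toy$positives, toy$sp), 0.7)
  # r1 has partners pa, pb: SPR(pc, r1) = 0.2 + 0.3
  expect_equal(spr_score("pc", "r1", toy$positives, toy$sp), 0.5)
  # an RNA with no partners scores 0
  lone <- interaction_set("pa", "r1", label = "positive")
  expect_equal(spr_score("pb", "rX", lone, toy$sp), 0)
  expect_error(spr_score("pZ", "r1", toy$positives, toy$sp), "unknown")
  expect_error(spr_score("pa", "r1", toy$positives, toy$sp), "positive pair")
})

test_that("adding one positive partner raises SPR by exactly that similarity", {
  toy <- toy_system()
  base <- spr_score("pd", "r2", toy$positives, toy$sp)
  grown <- interaction_set(c(toy$positives$protein, "pa"),
                           c(toy$positives$rna, "r2"), label = "positive")
  expect_equal(spr_score("pd", "r2", grown, toy$sp),
               base + toy$sp["pd", "pa"])
})

test_that("FIRE selection matches the exhaustive enumeration oracle on the toy system", {
  toy <- toy_system()
  for (m in 1:4) {
    got <- fire_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp, m)
    want <- oracle_fire_select(toy$sp, toy$positives, m)
    expect_equal(got$protein, want$protein)
    expect_equal(got$rna, want$rna)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("FIRE selection matches exhaustive enumeration on random small systems", {
  set.seed(5)
  for (np in 2:6) for (nr in c(2, 4, 6)) {
    pid <- paste0("p", seq_len(np))
    rid <- paste0("r", seq_len(nr))
    sp <- matrix(stats::runif(np * np), np, np, dimnames = list(pid, pid))
    sp <- (sp + t(sp)) / 2; diag(sp) <- 1
    npos <- sample(seq_len(np * nr - 1), 1)
    cells <- expand.grid(protein = pid, rna = rid, stringsAsFactors = FALSE)
    pos_rows <- cells[sample.int(nrow(cells), npos), ]
    pos <- interaction_set(pos_rows$protein, pos_rows$rna, label = "positive")
    ncand <- length(unique(pos$protein)) * length(unique(pos$rna)) - npos
    if (ncand < 1) next
    m <- sample(ncand, 1)
    got <- fire_negatives(unique(pos$protein), unique(pos$rna), pos, sp, m)
    want <- oracle_fire_select(sp, pos, m)
    expect_equal(got$protein, want$protein, info = paste(np, nr, m))
    expect_equal(got$rna, want$rna)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    # disjointness invariant
    expect_false(any(paste(got$protein, got$rna) %in%
                       paste(pos$protein, pos$rna)))
  }
})

test_that("threshold selection minimizes |score - st| and reduces to FIRE at st = 0", {
  toy <- toy_system()
  f <- fire_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp, 3)
  t0 <- threshold_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp,
                            3, st = 0)
  expect_equal(as.data.frame(f), as.data.frame(t0))

  # st above every score returns the m highest-scoring candidates
  all_c <- fire_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp, 8)
  thi <- threshold_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp,
                             2, st = 100)
  top2 <- all_c[order(-all_c$score, all_c$protein, all_c$rna,
                      method = "radix"), ][1:2, ]
  expect_setequal(paste(thi$protein, thi$rna),
                  paste(top2$protein, top2$rna))

  # closest-to-st pick on known scores
  sel <- threshold_negatives(toy$proteins, toy$rnas, toy$positives, toy$sp,
                             1, st = 0.65)
  expect_equal(sel$score, 0.7)
})

test_that("candidate-positive ranking returns per-RNA argmax candidates above the floor", {
  toy <- toy_system()
  ranked <- rank_candidate_positives(toy$proteins, toy$rnas, toy$positives,
                                     toy$sp, top_per_rna = 1, min_score = 0)
  for (r in unique(ranked$rna)) {
    cand <- oracle_fire_select(toy$sp, toy$positives, 100)
    cand_r <- cand[cand$rna == r, ]
    expect_equal(ranked$score[ranked$rna == r], max(cand_r$score))
  }
  # min_score filters out everything when set above the max
  none <- rank_candidate_positives(toy$proteins, toy$rnas, toy$positives,
                                   toy$sp, top_per_rna = 4, min_score = 1e6)
  expect_equal(nrow(none), 0L)
  # min_score = 0, unlimited top -> every candidate, descending per RNA
  all_r <- rank_candidate_positives(toy$proteins, toy$rnas, toy$positives,
                                    toy$sp, top_per_rna = Inf,
                                    min_score = -1)
  expect_equal(nrow(all_r), 8L)
  expect_true(all(tapply(all_r$score, all_r$rna,
                         function(s) all(diff(s) <= 0))))
})

test_that("the fire model object scores candidates like the standalone functions", {
  set.seed(21)
  prot <- seq_set(stats::setNames(replicate(4, random_protein(20)),
                                  paste0("p", 1:4)), "protein")
  rna <- seq_set(stats::setNames(replicate(3, random_rna(15)),
                                 paste0("r", 1:3)), "rna")
  pos <- interaction_set(c("p1", "p2", "p3", "p4"),
                         c("r1", "r1", "r2", "r3"), label = "positive")
  fit <- fire(pos, prot, rna)
  expect_s3_class(fit, "fire")
  for (i in seq_len(nrow(fit$spr))) for (j in seq_len(ncol(fit$spr))) {
    if (is.na(fit$spr[i, j])) next
    expect_equal(fit$spr[i, j],
                 spr_score(fit$protein_ids[i], fit$rna_ids[j], pos, fit$sp),
                 tolerance = 1e-12)
  }
  nf <- negatives(fit, m = 3, method = "fire")
  sf <- fire_negatives(fit$protein_ids, fit$rna_ids, pos, fit$sp, 3)
  expect_equal(as.data.frame(nf), as.data.frame(sf))
  expect_output(print(fit), "FIRE model")
  expect_output(print(summary(fit)), "quantiles")
  pred <- predict(fit, top_per_rna = 2, min_score = 0)
  expect_true(all(pred$score > 0))
})

test_that("all-tie candidates are selected by the deterministic lexicographic rule", {
  pid <- c("pa", "pb"); rid <- c("r1", "r2")
  sp <- matrix(0, 2, 2, dimnames = list(pid, pid)); diag(sp) <- 1
  # one positive per isolated RNA-protein pair; other RNA partners dissimilar
  pos <- interaction_set("pa", "r1", label = "positive")
  sel <- fire_negatives(pid, rid, pos, sp, 2)
  # scores: (pa,r2)=0, (pb,r1)=SP[pb,pa]=0, (pb,r2)=0 -> lexicographic order
  expect_equal(paste(sel$protein, sel$rna), c("pa r2", "pb r1"))
})
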