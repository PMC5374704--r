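test_that("residue class encoding maps the 4-class alphabet and flags invalid letters", {
  expect_equal(encode_residue_classes("DPPVPPPPPV"),
               c(1L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L))
  expect_equal(encode_residue_classes("DEHRK"), c(1L, 1L, 2L, 2L, 2L))
  expect_equal(encode_residue_classes("DXP"), c(1L, NA, 4L))
})

test_that("triad counts follow the sliding window over class triples", {
  tc <- triad_counts("DPPVPPPPPV")
  expect_equal(unname(tc["144"]), 1L)
  expect_equal(unname(tc["444"]), 7L)
  expect_equal(sum(tc), 8L)           # L - 2 windows
  expect_equal(sum(tc > 0), 2L)       # two distinct triad classes
  expect_equal(sum(triad_counts("DP")), 0L)
  expect_equal(unname(triad_counts("AAAA")["444"]), 2L)
  # windows touching an invalid residue are skipped
  expect_equal(sum(triad_counts("AAXAA")), 0L)
})

test_that("k-NA counts follow the sliding window over the RNA", {
  k3 <- kna_counts("CCUCU", 3)
  expect_equal(unname(k3[c("CCU", "CUC", "UCU")]), c(1L, 1L, 1L))
  expect_equal(sum(k3), 3L)
  expect_equal(sum(k3 > 0), 3L)
  k1 <- kna_counts("CCUCU", 1)
  expect_equal(unname(k1[c("C", "U")]), c(3L, 2L))
  expect_equal(sum(k1 > 0), 2L)
  k2 <- kna_counts("CCUCU", 2)
  expect_equal(unname(k2[c("CC", "CU", "UC")]), c(1L, 2L, 1L))
  expect_equal(sum(kna_counts("AU", 3)), 0L)
})

test_that("concentrations reflect the 256/1024/4096 block sizes and sum to 1", {
  expect_equal(concentration(3), 4096 / 5376)
  expect_equal(round(concentration(3), 3), 0.762)
  expect_equal(concentration(1), 256 / 5376)
  expect_equal(sum(concentration(1:3)), 1.0)
})

test_that("feature space bookkeeping: 5376 dimensions in 6-/5-/4-mer block order", {
  nm <- feature_names()
  expect_equal(length(nm), 5376L)
  expect_equal(length(unique(nm)), 5376L)
  widths <- nchar(sub("-.*", "", nm))
  expect_equal(unname(table(widths)[c("3", "2", "1")]),
               c(4096L, 1024L, 256L), ignore_attr = TRUE)
  expect_true(all(widths == rep(c(3, 2, 1), c(4096, 1024, 256))))
  expect_equal(nm[1], "AAA-111")
  expect_true("CCU-444" %in% nm)
})

test_that("the worked-example pair activates exactly the present unit pairings", {
  v <- featurize_pair("DPPVPPPPPV", "CCUCU", normalize = FALSE)
  widths <- rep(c(3, 2, 1), c(4096, 1024, 256))
  expect_equal(sum(v[widths == 3] > 0), 6L)  # 3 triNAs x 2 triad classes
  expect_equal(sum(v[widths == 2] > 0), 6L)
  expect_equal(sum(v[widths == 1] > 0), 4L)
  expect_equal(unname(v["CCU-444"]), 1 * 7 * 4096 / 5376)
  expect_equal(unname(v["CCU-144"]), 1 * 1 * 4096 / 5376)
  expect_equal(unname(v["U-444"]), 2 * 7 * 256 / 5376)
})

test_that("enumerating the worked-example pair reproduces its unit inventory", {
  u <- enumerate_pair_units("DPPVPPPPPV", "CCUCU")
  expect_equal(length(u$triads), 2L)
  expect_setequal(u$triads[["144"]], "DPP")
  expect_setequal(u$triads[["444"]], c("PPV", "PVP", "VPP", "PPP"))
  expect_setequal(u$knas[["3"]], c("CCU", "CUC", "UCU"))
  expect_setequal(u$knas[["2"]], c("CC", "CU", "UC"))
  expect_setequal(u$knas[["1"]], c("C", "U"))
  expect_equal(lengths(u$pairings), c(`1` = 10L, `2` = 15L, `3` = 15L))
  expect_true("CCU-DPP" %in% u$pairings[["3"]])
})

test_that("pair encoding agrees with the naive pair-materialization oracle", {
  set.seed(8)
  for (i in 1:12) {
    p <- random_protein(sample(3:12, 1))
    r <- random_rna(sample(3:10, 1))
    expect_equal(featurize_pair(p, r), oracle_featurize(p, r),
                 tolerance = 1e-12, info = paste(p, r))
  }
})

test_that("degenerate pairs give the all-zero vector", {
  expect_equal(unname(featurize_pair("DP", "CCUCU")), rep(0, 5376))
  expect_equal(unname(featurize_pair("DPPV", "AU")[1:4096]),
               rep(0, 4096))  # no 3-NA block signal for a 2-nt RNA
})

test_that("min-max normalization is invariant to positive scaling of the raw vector", {
  v <- featurize_pair("DPPVPPPPPV", "CCUCU", normalize = FALSE)
  mm <- function(x) if (max(x) == min(x)) rep(0, length(x)) else
    (x - min(x)) / (max(x) - min(x))
  expect_equal(unname(mm(v)), unname(mm(5 * v)), tolerance = 1e-12)
  expect_equal(unname(mm(v)), unname(featurize_pair("DPPVPPPPPV", "CCUCU")),
               tolerance = 1e-12)
})

toy_fscore_dataset <- function() {
  prot <- seq_set(c(pp = "DPPVPPPPPV", pn = "MKVHRW"), "protein")
  rna <- seq_set(c(rp = "CCUCU", rn = "AUGGC"), "rna")
  build_dataset(interaction_set("pp", "rp", label = "positive"),
                interaction_set("pn", "rn", label = "negative"),
                prot, rna)
}

test_that("FScore on a two-sample dataset equals the independent arithmetic oracle", {
  ds <- toy_fscore_dataset()
  tab <- fscore_table(ds)

  # spreadsheet-style oracle: per-class sums, min-max each profile, floor,
  # ratio -- computed here from the raw matrix with plain arithmetic
  x <- ds$features
  fp <- apply(x[ds$labels == "positive", , drop = FALSE], 2, sum)
  fn <- apply(x[ds$labels == "negative", , drop = FALSE], 2, sum)
  mm <- function(v) if (max(v) == min(v)) rep(0, length(v)) else
    (v - min(v)) / (max(v) - min(v))
  eps <- 1 / (2 * 5376)
  want <- pmax(mm(fp), eps) / pmax(mm(fn), eps)
  expect_equal(unname(tab$score), unname(want), tolerance = 1e-12)

  # a feature absent from both classes sits at the smoothing floor -> 1.0
  absent <- fp == 0 & fn == 0
  expect_true(any(absent))
  expect_true(all(tab$score[absent] == 1.0))
})

test_that("FScore is invariant to the order of samples in the dataset", {
  ds <- toy_fscore_dataset()
  perm <- c(2, 1)
  ds2 <- ds
  ds2$features <- ds$features[perm, , drop = FALSE]
  ds2$labels <- ds$labels[perm]
  expect_equal(fscore_table(ds2)$score, fscore_table(ds)$score)
})

test_that("FScore requires both classes", {
  ds <- toy_fscore_dataset()
  ds$labels <- factor(c("positive", "positive"),
                      levels = c("negative", "positive"))
  expect_error(fscore_table(ds), "positive and .* negative")
})

test_that("feature selection keeps the k/2 largest and smallest scores", {
  tab <- structure(list(score = c(5.0, 1.0, 0.2, 1.0)),
                   class = "fscore_table")
  expect_equal(select_features(tab, 2), c(1L, 3L))
  expect_error(select_features(tab, 3), "even")
  expect_error(select_features(tab, 6), "exceeds")
  # overlap between halves: all scores tied
  tied <- structure(list(score = rep(1, 4)), class = "fscore_table")
  expect_error(select_features(tied, 4), "overlap")
  # k = all features returns every index
  distinct <- structure(list(score = c(3, 1, 2, 5)), class = "fscore_table")
  expect_equal(select_features(distinct, 4), 1:4)
})
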