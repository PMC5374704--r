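---
title: "Reliable negative selection for protein-RNA interaction prediction"
author: "firePRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliable negative selection for protein-RNA interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firePRI)
```

## The problem

Sequence-based classifiers of protein-RNA interactions (PRIs) are trained
on known interactions (positives) plus *constructed* negatives, because
experimentally validated non-interactions are essentially never published.
The classical construction pairs proteins and RNAs at random and removes
known positives. Since interactomes are sparsely charted, a nontrivial
fraction of those "negatives" are simply undiscovered interactions, and
this label noise caps classifier performance.

This package selects negatives by a similarity-transfer argument: if RNA
$r_j$ is known to bind proteins $p_k$, then a protein $p_i$ that is very
*dissimilar* to all of them is unlikely to bind $r_j$. Each candidate pair
$(p_i, r_j)$ outside the positive set is scored by

$$\mathrm{SPR}_{ij} \;=\; \sum_{k} \delta(k, j)\,\mathrm{SP}_{ik},$$

where $\delta(k,j) = 1$ iff $(p_k, r_j)$ is a known positive and
$\mathrm{SP}_{ik}$ is the aggregated protein-protein similarity. Sorting
candidates by ascending score and taking the top $m$ yields the reliable
negative set; the same score, sorted descending, ranks plausible *new*
positives (`predict()` on the fitted model).

## The similarity model

$\mathrm{SP}$ averages three evidence channels, each in $[0,1]$:

$$\mathrm{AS}(p_i, p_j) = \tfrac13\left(\mathrm{SS} + \mathrm{FS} +
\mathrm{DS}\right),$$

* **SS** — normalized Smith-Waterman similarity
  $sw(i,j)/\sqrt{sw(i,i)\,sw(j,j)}$, computed with BLOSUM62 and affine
  gaps (open 10, extend 0.5; a gap of length $L$ costs
  $\mathrm{open} + \mathrm{extend}\cdot L$). The raw local score is
  clamped at 0 (the empty alignment), so SS is 0 when no positive-scoring
  local alignment exists and 1 for identical sequences. These are the
  canonical local-alignment defaults; they are exposed via
  `alignment_params()` because no single scheme is privileged.
* **FS** — Jaccard overlap of the proteins' GO term sets (all three
  sub-ontologies pooled, directly assigned terms only; annotation ids are
  treated as opaque strings, so no ancestor closure is attempted).
* **DS** — Jaccard overlap of the proteins' Pfam domain sets.

Two conventions matter for sparse annotations. The Jaccard of two empty
sets is defined as 0: absence of evidence is not evidence of similarity.
And a missing channel contributes 0 rather than renormalizing the mean
over available channels — the aggregate is a fixed mean of three terms, so
poorly annotated proteins are conservatively pushed toward dissimilarity
(hence toward being selected as negatives).

## Negative selection variants

`negatives(fit, m, method = ...)` implements three constructions over the
candidate universe (positive-set proteins x positive-set RNAs, minus the
positives):

* `"fire"` — the $m$ lowest-SPR candidates;
* `"random"` — $m$ uniform draws without replacement (the classical
  baseline);
* `"threshold"` — the $m$ candidates whose scores are *closest to* a
  threshold `st`; `st = 0` reproduces `"fire"`, and raising `st` admits
  ever-more-plausible pairs, which is how the quality/quantity trade-off
  of the threshold is probed (`threshold_experiment()`).

Equal scores are broken lexicographically by (protein id, RNA id) so
selections are reproducible across platforms. `m` defaults to the
positive count (1:1 ratio), with 2:1 and 1:2 presets.

## The paired (k+3)-mer encoding

A pair is encoded over $64 \times (4 + 16 + 64) = 5376$ dimensions. The
protein contributes conjoint triads — three consecutive residues mapped
to the 4-class alphabet $\{DE\}$, $\{HRK\}$, $\{CGNQSTY\}$,
$\{AFILMPVW\}$ (64 triad classes); windows touching a non-standard letter
are skipped rather than the sequence rejected. The RNA contributes
k-nucleotide units for $k = 1, 2, 3$. The raw value of the dimension
pairing triad class $c$ with unit $w$ is $t \cdot C_i$, where $t$ is the
*product* of the two sliding-window counts — a paired unit occurs once
per co-occurrence of its components, which is the only definition
consistent with independent counts — and $C_i$
($256/5376,\,1024/5376,\,4096/5376$ for 4-, 5-, 6-mers) weights each
block by the share of the feature space it occupies. Each vector is then
min-max rescaled across its 5376 entries; a constant raw vector (e.g. a
protein shorter than 3 residues) maps to all zeros, preserving "no
information" without a 0/0.

Dimensions are ordered 6-mers, 5-mers, 4-mers, lexicographically by
(k-NA, class triple) within a block, and named like `CCU-444` — a
deterministic serialization for the tab-separated dataset format.

## FScore feature filtering

For each feature, the normalized values are summed over positives and
over negatives; the two 5376-long profiles are each min-max rescaled
(the same rescaling used for single vectors), floored at
$\varepsilon = 1/(2\cdot 5376)$, and ratioed
($\mathrm{FScore} = \mathrm{FF}_p/\mathrm{FF}_n$). The floor keeps the
ratio finite and scores never-observed features as exactly 1 (neutral).
Selection keeps the $k/2$ largest and $k/2$ smallest scores (default
$k = 1000$), ties broken by ascending index; if ties make the two halves
collide, the request is refused rather than silently shrunk.

## Evaluation harness

`cross_validate()` runs stratified k-fold CV (folds preserve the class
ratio; `folds = n` degrades to unstratified leave-one-out) and pools the
out-of-fold confusion — micro-averaging, which is stable for datasets
with as few as tens of positives — reporting SE, SP, their geometric
mean GM (the headline metric under class imbalance), ACC, and AUC from
the pooled out-of-fold scores with a fixed ROC direction (so chance
really is 0.5, not 0.5 folded upward). Classifiers: SVM (RBF, cost 1,
gamma 1/dimension), random forest (500 trees, via ranger) and Gaussian
naive Bayes (class-conditional standard deviations floored at $10^{-3}$
to guard zero-variance features). These are ecosystem defaults; none of
them is tuned. `improvement_ratio()` reports the signed percent change
of any metric when reliable negatives replace random ones.

## The synthetic benchmark

`generate_world()` plants exactly the structure the method's premise
assumes: proteins come in homology groups (one ancestral sequence of
50-300 aa per group, members mutated per-site at `mutation_rate`;
shared core GO terms and domains plus private noise terms), and each RNA
(20-200 nt, uniform A/U/C/G) interacts with *all* members of its 1-2
assigned groups. The observed positive set is a uniform subsample of
this ground truth at `observation_fraction`, so the hidden remainder is
exactly the contamination a random negative set will pick up.
`contamination_rate()` measures that pickup;
`negative_benefit()` runs the full pipeline (fit, select negatives,
encode, reduce to $k = 1000$ features, 10-fold CV) and scores the pooled
out-of-fold predictions against the *ground-truth* labels, under which a
selected negative that is secretly a true interaction counts as a
positive. This is the benefit measure: a contaminated negative set hurts
twice, by injecting label noise into training and by mislabelling its
own evaluation pairs.

The default world (5 groups x 8 proteins, 40 RNAs, mutation 0.1,
observation 0.6) is the study condition used throughout the tests and
the acceptance script; the benchmark there uses 20 seeds (tests) and 8
seeds (acceptance script) with the RF classifier, and the threshold
experiment 3 seeds and 1 seed respectively — sizes chosen so the whole
suite runs on a laptop-class single core in minutes.

What the generator does *not* emulate: realistic degree distributions
(real interactomes are heavy-tailed; here RNA degree is the group size),
GO DAG structure, compositional bias of real sequences, or binding-site
signal in the RNA (RNA sequences are pure noise, so classifiers can only
memorize RNA identity and generalize over protein similarity). Passing
the benchmark therefore shows the machinery is correct and the selection
principle works where its premise holds — not that any particular real
interactome satisfies the premise.

## Limitations worth knowing

* **Extreme negatives bias decision boundaries.** Because FIRE picks the
  *most* dissimilar pairs, a classifier trained on them sees no
  borderline negatives and over-calls positives on pairs of intermediate
  similarity. On a held-out test set of hidden true interactions versus
  genuine non-interactions, FIRE-trained models show high sensitivity but
  depressed specificity relative to random-negative training. The
  benefit measured here — against truth-scored labels on the
  construction distribution — is real, but users predicting across the
  whole candidate space should consider mixing selection strategies or
  calibrating the decision threshold.
* The candidate universe is restricted to proteins and RNAs that appear
  in the positive set, because SPR needs at least one known partner per
  RNA and a similarity row per protein; proteins never seen interacting
  cannot be scored.
* Whether raw SPR or a rescaled version is the right axis for the
  threshold variant is under-determined; `threshold_experiment()` uses
  fractions of the observed maximum score, which keeps the sweep
  comparable across worlds.
* Scoring is quadratic in the number of proteins (alignment of all
  pairs); thousands of proteins call for a precomputed `sp` matrix,
  which `fire()` accepts.

## A worked example

```{r example, eval = FALSE}
w <- generate_world(seed = 1)
fit <- fire(w$observed, w$proteins, w$rnas, go = w$go, domains = w$domains)
summary(fit)

neg_fire <- negatives(fit, method = "fire")
neg_rand <- negatives(fit, method = "random", seed = 1)
contamination_rate(neg_fire, w)
contamination_rate(neg_rand, w)

b <- negative_benefit(w, seed = 1)
b$gm
improvement_ratio(b$gm[["fire"]], b$gm[["random"]])
```

The vignette leaves this chunk unevaluated to keep builds fast; the same
computation, at the sizes stated above, is what `tests/testthat/` and
`scripts/acceptance.R` run and check.
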