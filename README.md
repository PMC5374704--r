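# firePRI

Reliable negative sample selection for protein-RNA interaction (PRI)
prediction, with the paired conjoint-triad × k-nucleotide sequence
encoding, FScore filter-based feature selection, a cross-validated
classifier harness, and a synthetic interactome benchmark.

## Why

Machine-learning PRI predictors need negative training pairs, but
validated non-interactions are essentially unavailable. The classical fix
— pair proteins and RNAs at random and drop known positives — quietly
labels undiscovered interactions as negatives, and that contamination
drags classifier performance down. firePRI instead scores every candidate
pair (pᵢ, rⱼ) outside the positive set by similarity transfer:

    SPR_ij = Σₖ δ(k, j) · SP_ik

where δ(k, j) = 1 iff (pₖ, rⱼ) is a known interaction, and SP is the
aggregated protein-protein similarity

    AS(pᵢ, pⱼ) = (SS + FS + DS) / 3

combining normalized Smith-Waterman sequence similarity (SS), GO-term
Jaccard (FS) and Pfam-domain Jaccard (DS). Candidates with the *lowest*
SPR — pairs no protein similar to pᵢ is known to realize — become the
negative set; the *highest*-scoring candidates are ranked as putative new
positives.

## Worked example

```r
library(firePRI)

w <- generate_world(seed = 1)        # 5 homology groups x 8 proteins, 40 RNAs
fit <- fire(w$observed, w$proteins, w$rnas, go = w$go, domains = w$domains)
print(fit)
#> FIRE model
#>   proteins: 40  RNAs: 40  positives: 293
#>   candidate pairs: 1307

neg_fire <- negatives(fit, method = "fire")      # m = 293, lowest SPR
neg_rand <- negatives(fit, method = "random", seed = 1)
contamination_rate(neg_fire, w)
#> [1] 0
contamination_rate(neg_rand, w)
#> [1] 0.1433447
```

None of the 293 FIRE-selected negatives is a hidden true interaction,
versus ~14% of the random ones. Training a random forest on each
constructed dataset (triad × k-NA features, FScore-reduced to 1000
dimensions, 10-fold cross-validation scored against the hidden ground
truth):

```r
b <- negative_benefit(w, seed = 1)
b$gm
#>      fire    random
#> 0.9451707 0.8312731
improvement_ratio(b$gm[["fire"]], b$gm[["random"]])
#> [1] 13.70158
```

The geometric mean of sensitivity and specificity improves by ~14% on
this world simply by choosing better negatives. `predict(fit)` returns,
per RNA, the top candidate proteins whose SPR exceeds a confidence floor
— the same score used in reverse to propose new interactions.

A command-line wrapper over these functions lives in
`inst/scripts/fire-pri.R` (subcommands `simulate`, `select-negatives`,
`featurize`, `reduce`, `evaluate`, `compare`).

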