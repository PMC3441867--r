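# causepattern

Detecting implicit cause–effect relations between sentences in mental-health
text — pairs like *"I broke up with my boyfriend. Life now is meaningless to
me."* — where no discourse connective signals the relation. The package is
aimed at text-mining researchers and clinical-NLP practitioners who have a
corpus of POS-tagged (cause span, effect span) records and want to go beyond
the classical word-pair feature.

## What it implements

The classical feature for cross-sentence causality is the **word pair**
(WP): the cross product of cause-span and effect-span content words,
e.g. `(broke up, life)`. Word pairs capture single-word associations but are
often semantically incomplete. `causepattern` mines **inter-sentential
language patterns** (ISLP) instead: combinations of multi-word patterns from
the two sides, such as `<<broke up, boyfriend>, <life, meaningless>>`.

1. **Intra-sentential pattern mining** — frequent word sets within each
   side's spans by the level-wise join/prune (Apriori) iteration, scored by
   pointwise mutual information:
   `Conf(lp) = P(w_1..w_k) · log [ P(w_1..w_k) / ∏ P(w_i) ]`,
   probabilities being span-containment fractions. Alternatively, intra
   patterns can be derived from dependency parses (CoNLL-U) as word–head
   pairs.
2. **Inter-sentential pattern mining** — the same join/prune iteration over
   pattern items across the cause/effect boundary, scored by the same MI
   form with joint probabilities over sentence pairs; top-N% selection by
   confidence.
3. **Detection** — a factored probabilistic classifier
   `c* = argmax_c ∏ P(islp_i|c) · ∏ P((w_i,w_j)|c) · P(c)`
   with add-one smoothing, computed in the log domain.
4. **Evaluation** — recall/precision/F, stratified k-fold cross-validation
   with per-fold re-mining (no leakage), paired two-tailed t-tests between
   feature sets, and parameter sweeps.
5. **Synthetic corpora** — a seeded generator planting dependent word groups
   and cross-span links, so mining recovery and detection gains are testable
   without any clinical data.

Everything is tidyverse-shaped: functions take a data frame first and return
tibbles, fitted models have `tidy()`/`glance()` methods, and result objects
have `autoplot()` methods.

## Worked example

```r
library(causepattern)

bm  <- default_benchmark(seed = 13)   # 2000 synthetic pairs, 35% causality
pat <- mine_patterns(bm$pairs, min_support = 2, top_frac = 0.3)
pat$inter[1:2, c("pattern", "support", "confidence")]
#> 1 <<cw4_a, cw4_b> | <ew4_b, ew4_a>>      91      0.167
#> 2 <<cw2_a, cw2_b> | <ew2_a, ew2_b>>      86      0.153
```

The top patterns are exactly the planted cause-group/effect-group links of
the generator: each was contained in ~90 of the 2000 pairs (support) and its
members co-occur far above chance (confidence, in nats).

```r
cv <- kfold_cv(bm$pairs, k = 10, feature_sets = c("wp", "wp+islp_arm"),
               seed = 13)
cv_summary(cv)
#>   feature_set recall precision f_measure
#> 1 wp           0.600     0.468     0.525
#> 2 wp+islp_arm  0.658     0.488     0.560

compare_feature_sets(cv[cv$feature_set == "wp+islp_arm", ],
                     cv[cv$feature_set == "wp", ])
#>   mean_diff     t    df  p_value degenerate
#> 1    0.0348  9.12     9 7.64e-06 FALSE
```

Word pairs alone reach a mean F of 0.53 under this noise level; adding
inter-sentential patterns lifts F to 0.56, a consistent gain across all ten
folds (paired two-tailed t-test, p ≈ 8e-6). `autoplot(cv)` shows the
per-fold spread; see the vignette (`vignettes/causality-patterns.Rmd`) for
the model, the parameter defaults, and what the synthetic benchmark does and
does not demonstrate.

A thin command-line interface over the same functions ships in
`inst/cli/causepattern.R` (subcommands `simulate`, `split`, `mine`, `train`,
`predict`, `evaluate`).

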