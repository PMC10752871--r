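# forumstylo

Stylometric identification of peer-support user groups in online
mental-health forums, and comparison of their emotional expression.

Forum services assign role labels — *senior contributor*, *community
guide*, *community elder*, *casual contributor*, *contributor* — largely
by hand. `forumstylo` is for researchers and forum service teams who
want to ask two questions of a labeled post collection:

1. **Can the groups be told apart from writing style alone?**
   (Burrows' Delta over four stylometric feature types, calibrated into
   same-group probabilities and evaluated by ROC/AUC.)
2. **How does their emotional expression differ?**
   (NRC-style emotion-lexicon counting, polarity ratios, pairwise
   chi-square tests with Benjamini–Hochberg correction, odds ratios
   with Woolf confidence intervals, radar profiles.)

Because real forum exports of this kind are rarely shareable, the
package includes a seeded synthetic corpus generator emulating the five
published user groups (group-specific lognormal post lengths and
emotion-usage profiles), so the whole pipeline is testable end to end.

## The model

For groups $1..n$ and features $f_1,\dots,f_k$ (the $k$ most frequent
candidate words), each text $T$ gets a z-profile
$z_i(T) = (C_i(T) - \mu_i)/\sigma_i$, where $C_i$ is the relative
frequency of $f_i$ in $T$ and $\mu_i, \sigma_i$ are the mean and
(population) standard deviation of $f_i$'s frequency across the $n$
group subcorpora. Burrows' Delta between a questioned text and a
candidate group is

$$\Delta_C = \frac{1}{k}\sum_{i=1}^{k} \left| z_i(C) - z_i(T) \right|,$$

and the lowest delta wins. A logistic calibration
$P(\text{same group} \mid \Delta) = \mathrm{logit}^{-1}(\beta_0 +
\beta_1\Delta)$, fitted on labeled same/different-group chunk pairs
with class balancing, turns deltas into probabilities; AUC of those
probabilities on held-out pairs measures identification quality.
Feature pools: `token`, `emotion`, `token_pron`, `emotion_pron`, swept
over $k \in \{50,\dots,500\}$.

## Worked example

Emotion statistics recomputed from the packaged published group ×
emotion count table of the SANE forum user groups:

```r
library(forumstylo)

ect <- sane_emotion_counts()
head(pairwise_chi_square(ect), 3)
#>              group_a            group_b chi_square df  p_adjusted
#> 1 senior contributor    community guide  2564.0940  7 0.00000e+00
#> 2 senior contributor    community elder    72.6966  7 4.20557e-13
#> 3 senior contributor casual contributor  4687.9652  7 0.00000e+00
```

Every group pair differs significantly in its emotion distribution; the
senior-contributor / community-elder pair is by far the most alike
(statistic 72.7 against thousands elsewhere). Polarity aggregation and
the positive:negative ratio:

```r
pt <- polarity_table(ect)
pt[pt$group == "community guide", ]
#>             group positive negative positive_prop negative_prop
#> 2 community guide   129080    59126          17.1         7.833
polarity_ratio(pt, "community guide")
#> [1] 2.18
```

Community guides write 2.18 positive emotion words for every negative
one — the most positive-leaning group. Odds of *fear* words, senior
contributors versus community guides:

```r
odds_ratio(ect, "fear", "senior contributor", "community guide")
#>   emotion          group_ref       group_cmp odds_ratio ci_low ci_high
#> 1    fear senior contributor community guide      1.319  1.298   1.341
```

Senior contributors are ~1.32× as likely to use fear words as community
guides (CI excludes 1). Stylometric sweep on a synthetic corpus:

```r
spec <- default_profiles(n_posts = 300, seed = 1)
posts <- generate_posts(spec)
sweep_feature_grid(posts, c("emotion", "token"), 100, seed = 1,
                   lexicon = spec$emotion_vocab,
                   max_pairs_per_class = 2000)
#>   feature_type   k k_used       auc n_pairs_train n_pairs_test note
#> 1      emotion 100    100 0.5079771          4000         1540
#> 2        token 100    100 0.4720478          4000         1540
```

AUC near 0.5 here is the expected result, not a failure: the generator
reproduces only concept-level emotion proportions, which are too weak a
word-level signature for chunk-level Delta — see the methods vignette
(`vignettes/forumstylo-methods.Rmd`) for the analysis, and for the
well-separated-profile control on which the same pipeline exceeds
AUC 0.99.

A command-line wrapper covers the common runs:

```sh
exec/forumstylo simulate --out sim --n-posts 500 --seed 7
exec/forumstylo sweep --posts sim/posts.csv --lexicon sim/emotion_lexicon.tsv --out sweep
exec/forumstylo emotions --counts-table inst/extdata/sane_group_emotion_counts.csv --out emo
```

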