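# typostab

Seven published estimators of the evolutionary stability of structural
(typological) features of language, re-implemented as one tested R pipeline,
together with the cross-method comparison that asks whether the estimators —
despite resting on very different concepts of "stability" — agree on which
features are stable.

## Who this is for

Quantitative typologists and researchers in language evolution working with
WALS-style data: a languages × categorical-features table with genealogical
(family, genus) and areal metadata. The package also ships a synthetic-world
generator with known per-feature change and borrowing rates, so each
estimator's recovery behaviour can be checked under controlled conditions.

## The estimators

For a feature *f* over languages with attested categorical values:

* **CM, CC, CR — consistency with the overall pattern.** Per-feature distance
  d_f(a,b) ∈ {0,1,2} (same / different / unattested on either side); the
  overall matrix M averages d_f over the features attested in both languages.
  CM = 1 − p̂ from a Mantel permutation test of cor(d_f, M); CC compares
  summed triplet excesses E(a,b|c) = d(a,c) + d(c,b) − d(a,b) between d_f and
  M; CR rescales the summed neighbour ranks of co-valued languages between
  their attainable bounds (low CR = consistent, so −CR enters the
  comparison).
* **M — transition probabilities from related pairs.** Binary feature with
  switch probabilities α (a→b) and β (b→a); within-genus language pairs obey
  D = p·2α(1−α) + (1−p)·2β(1−β), so two genus samples with different
  designated-value frequencies p identify (α, β); stability is
  1 − [p̂α + (1−p̂)β].
* **W — metric C.** C = (R̄ − U)/(1 − U), where R̄ is the weighted mean
  proportion of same-valued pairs within families and U the same proportion
  across families.
* **P1, P2 — homogeneity ratio.** Mean within-family Herfindahl homogeneity
  Σ_v s_v² divided by mean within-area homogeneity; P2 restricts to twelve
  widely accepted families. Measures resistance to borrowing.
* **D — phylogenetic rates.** Per family (classification tree, unit
  branches), the Mk maximum-likelihood rate and the parsimony change count
  per attested tip; within-family ranks aggregated across families by their
  first principal component.

## Worked example

The packaged fixture (`inst/extdata/table1_ranks.csv`) compiles the eight
published estimate columns for the 142 WALS features as relative ranks in
[0, 1] (higher = more stable; missing where a method does not cover a
feature).

```r
library(typostab)
sm <- loadTable1Fixture()
report <- runComparison(sm, n_null = 10000, seed = 1)
print(report)
```

```
Cross-method stability comparison
  shared features: 62
  outliers: 11, 58, 136
  method distances: min 1.34 mean 2.43 max 3.43 (p_min=0.0001, p_mean=0.0001)
  PC1 50.1% of variance; first four 88.0%
  mean feature IQR 0.30 (null 0.44 +/- 0.14)
  Holm-significant IQR: low = 86, 87 ; high = 11
  area ANOVA: F = 2.81, p = 0.0146; top Tukey pair WO-NC (adj p = 0.0145)
```

Reading this: 62 of 142 features are covered by every method. In the
62-dimensional rank space the eight estimate vectors sit far closer together
(mean pairwise distance 2.43) than eight random points would (≈ 3.2,
empirical p = 1/10001), and one principal component carries half the variance
with same-signed loadings — the methods largely agree on which features are
stable. Per feature, the interquartile range of the eight ranks averages 0.30
against a permutation null of 0.44 ± 0.14; after Holm correction the methods
agree unusually well on features 86/87 (order of genitive/adjective and noun)
and disagree most on feature 11 (front rounded vowels). Word-order features
are rated more stable than nominal-category features (Tukey-adjusted
p = 0.0145). Features 11, 58 and 136 are flagged as regression outliers
between method pairs.

Estimating from your own table and simulating ground-truth worlds:

```r
tab <- readTypologyTable("my_wals_subset.tsv")
est <- estimateStability(tab, methods = c("w", "m", "p1"), seed = 1)
writeEstimates(est, "estimates.csv")

w <- simulateWorld(simulationConfig(seed = 42))
est <- estimateStability(worldTable(w), methods = c("w", "m", "d"),
                         d_estimator = "parsimony", seed = 7)
recoveryReport(w, est)   # Spearman of each estimate against -true rate
```

A thin command-line wrapper is installed at
`system.file("scripts", "typostab", package = "typostab")` with subcommands
`estimate`, `compare`, `simulate` and `reproduce-paper`.

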