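# charmark

Character-level Markov chain biomarkers from transcribed speech.

## What problem this addresses

Speech changes early in cognitive decline, but most computational markers
rely on semantic, lexical or acoustic features that are hard to interpret
and expensive to compute. charmark works at the most granular textual
level: it models each transcript as a first-order Markov chain over a
27-symbol alphabet (the letters a–z plus the space character) and uses the
chain's stationary distribution as a compact, interpretable fingerprint of
how language flows. The space symbol — a word-boundary token that proxies
pausing behaviour — is retained as a modelled state, because elevated and
rigid space usage is a candidate marker of disrupted fluency.

The package is aimed at researchers in digital biomarkers and speech
analysis who need a transparent, fully seeded pipeline: feature extraction,
distributional screening, unsupervised structure discovery, and calibrated
sparse classification, plus a synthetic-corpus generator so every stage is
testable without access-gated clinical data.

## The model

Per transcript, transition probabilities are estimated with Laplace
smoothing,

    P_ij = (n_ij + α) / Σ_u (n_iu + α),     k = 27, α = 0.01 by default,

and the steady-state vector π solves πP = π with Σ π_i = 1. The 27
stationary probabilities are the features. Downstream:

- **Screening** — two-sample Kolmogorov–Smirnov tests per character,
  Bonferroni-corrected across the full character set (m = 27), ranked by D.
- **Structure** — k-means with silhouette-selected k, and a 2-D PCA
  projection for display.
- **Classification** — L1-penalised logistic regression (class-balanced,
  fixed inverse regularisation C = 1.0) under stratified 5-fold
  cross-validation with all of a participant's transcripts confined to one
  fold; metrics as mean ± SD across folds, plus Brier score, expected
  calibration error, reliability bins, Youden-J / max-F1 thresholds,
  frequency-only / space-only / second-order (729 bigram states) ablations,
  and a smoothing-constant sensitivity sweep over
  α ∈ {0.001, 0.005, 0.01, 0.05, 0.1}.

## A worked example

```r
library(charmark)

spec   <- generator_spec(seed = 42)   # two-group synthetic corpus,
corpus <- generate_corpus(spec)       # reference composition: 310 + 242
fm     <- build_feature_matrix(corpus$sequences, alpha = 0.01)
fm
#> <feature_matrix> 552 transcripts x 27 features (order 1, alpha = 0.01)
#>   groups: case=310, control=242

screen_features(fm)
#> Kolmogorov-Smirnov feature screen: case vs control (Bonferroni, level 0.05)
#> 6 of 27 features significant
#>
#>  feature      D   p_value p_adjusted significant
#>    space 0.7250 0.000e+00  0.000e+00        TRUE
#>        e 0.2837 6.351e-10  1.715e-08        TRUE
#>        u 0.2476 1.165e-07  3.146e-06        TRUE
#>        n 0.2026 2.859e-05  7.721e-04        TRUE
#>        d 0.1775 3.818e-04  1.031e-02        TRUE
#> ... and 22 more rows

cv <- charmark_cv(corpus, seed = 7)   # grouped stratified 5-fold Lasso
cv
#> <charmark_cv> variant charmark (alpha = 0.01, C = 1, 5-fold grouped CV)
#>           auc            f1     precision        recall   specificity
#> 0.936 ± 0.034 0.872 ± 0.035 0.885 ± 0.063 0.861 ± 0.029 0.851 ± 0.096
#>      accuracy         brier           ece
#> 0.857 ± 0.045 0.135 ± 0.007 0.181 ± 0.051
```

The screen says the planted case-group effect (a 0.05 additive tilt on
transitions into the space symbol) is overwhelmingly concentrated on the
space feature, with knock-on shifts in common letters; the CV report says
those 27 probabilities separate the synthetic groups with AUC ≈ 0.94 under
participant-grouped folds, with moderate calibration error. `summary(cv)`
adds pooled metrics, optimised thresholds, the pooled confusion matrix and
per-fold selected features; `plot(cv)` draws the reliability curve.

A thin CLI wraps the same functions
(`inst/cli/charmark simulate | preprocess | features | screen | cluster |
classify | sweep-alpha | network`); transition networks export as DOT,
edge CSV or GraphML with the space node rendered as "␣".

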