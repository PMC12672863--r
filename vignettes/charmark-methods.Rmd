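---
title: "Character-level Markov chain biomarkers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-level Markov chain biomarkers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charmark)
```

## The model

charmark treats a transcribed speech sample as a symbol stream over a fixed
27-character alphabet — the lowercase letters plus the space character — and
models it as a first-order Markov chain: the probability of the next
character depends only on the current one. Two quantities are estimated per
transcript:

* the transition matrix, from Laplace-smoothed bigram counts

  $$P_{ij} = \frac{n_{ij} + \alpha}{\sum_{u=1}^{k} (n_{iu} + \alpha)},
  \qquad k = 27,$$

  where $n_{ij}$ counts observed transitions from character $i$ to $j$ and
  $\alpha > 0$ guarantees a strictly positive, hence irreducible and
  aperiodic, chain;

* the stationary (steady-state) distribution $\pi$, the unique probability
  vector solving $\pi P = \pi$, $\sum_i \pi_i = 1$. It summarises the
  long-run occupancy of each character under the transcript's own dynamics
  and is the 27-dimensional feature vector ("linguistic fingerprint") used
  by every downstream analysis.

The space character is retained as a modelled state because, in transcribed
speech, word boundaries act as a structural proxy for pausing behaviour:
elevated stationary space probability corresponds to shorter words and more
frequent boundaries, a pattern associated with disfluent, hesitant speech.
It is a textual proxy only — no acoustic pause information enters the model.

A second-order variant lifts the state space to the 729 character bigrams.
Smoothing is applied over the 27 emitted symbols of each bigram row, and the
stationary vector lives on the induced 729-state chain in which state
$(c_1, c_2)$ moves to $(c_2, c_3)$ with probability $P[(c_1, c_2), c_3]$.
This keeps $729 \times 26 = 18{,}954$ free transition parameters, more than
25 times the first-order count, which is the statistical argument for
preferring the first-order model at clinical sample sizes.

## Preprocessing

`normalize_text()` lowercases, folds common accented Latin letters to their
ASCII base, deletes apostrophes in place (so contractions collapse:
"don't" becomes "dont"), replaces every other non-alphabetic character with
a space, collapses space runs and trims the ends. Deleting apostrophes
rather than spacing them is deliberate: spacing would split contractions
into spurious short words; conversely, deleting *all* punctuation would fuse
neighbouring words ("cat,dog" must become "cat dog"), corrupting exactly the
space-usage signal the model centres on. Digits are treated like
punctuation — there is no verbalisation rule. Multi-line transcripts are
joined with a space. A minimal CHAT reader keeps only the participant tier
of `.cha` files and strips annotation codes and bracketed markup;
investigator speech is excluded. Transcripts that are empty after
normalisation are excluded (they admit no transition counts) with a warning.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.01 | Laplace constant; the main analysis setting. `alpha_grid()` = {0.001, 0.005, 0.01, 0.05, 0.1} is the sensitivity sweep. |
| `order` | 1 | Markov order (1 or 2). |
| `penalty_C` | 1.0 | Inverse L1 regularisation of the logistic classifier (glmnet lambda = 1/(C·n)), with class-balanced weights. |
| `n_folds` | 5 | Participant-grouped stratified cross-validation folds. |
| `n_bins` | 10 | Equal-width calibration bins for ECE/reliability. |
| `k_range` | 2–6 | Candidate k for silhouette-selected k-means. |
| window | 25 | Rolling mean/SD window (transcripts), for drift plots. |

Features enter the classifier un-standardised: stationary probabilities
share a common scale, and z-scoring would inflate rare-letter noise. A
`standardize` flag exists (statistics fit on training folds only, preserving
the leakage guarantee) but is off by default. Thresholds other than the 0.5
default are chosen on pooled out-of-fold predictions by Youden's J or
maximal F1, scanning midpoints of sorted unique probabilities with ties
going to the lower threshold.

## Numerical choices

* Stationary vectors come from a dense left eigendecomposition (eigenvalue
  nearest 1, real parts taken, negative entries clipped, renormalised) with
  a power-iteration fallback (tolerance 1e-12, at most 10,000 iterations);
  the stationarity residual $\max_i |(\pi P)_i - \pi_i|$ is checked against
  1e-8 and attached to the result. For order 2 the 729×729 lifted operator
  is applied implicitly (a 27×27 reshape per iteration) and never
  materialised.
* Smoothed rows sum to 1 to within 1e-12 by construction; `alpha = 0` with
  an unobserved row is rejected rather than zero-filled.
* KS p-values use the asymptotic two-sample distribution at effective size
  $n_x n_y/(n_x+n_y)$; a seeded permutation mode exists for small samples.
  Bonferroni correction always uses m = 27 (the full character set), even
  when some columns are constant.
* PCA is computed on centred, unscaled features; component signs follow a
  deterministic convention (largest-magnitude loading positive). Rank-1
  data projects with a zero-variance second axis; only rank-0 input errors.
* Sequences shorter than order + 1 symbols are excluded from feature
  matrices, not zero-filled.
* Feature CSVs are written with 12 significant digits, making the
  write/read round trip reproducible at that formatting.

## The synthetic-transcript generator

Clinical speech corpora in this area are access-gated, so the package ships
a generator whose defaults encode the reference study conditions: 168 case
participants contributing 310 transcripts and 98 controls contributing 242
(552 transcripts in all), transcript lengths uniform on [300, 1500]
characters (picture-description scale), per-participant heterogeneity via
Dirichlet resampling of transition rows (concentration 500), and a
case-group additive shift of 0.05 on transitions into the space symbol. The
base chain is estimated from a bundled original English passage written in a
picture-description register, so the 27 features carry realistic,
non-exchangeable English character statistics.

Three case-group effects can be composed:

* `space_shift` — additive tilt on each row's space-transition probability
  (rows renormalised): raises the stationary space probability, emulating
  elevated word-boundary frequency;
* `self_loop_boost` — diagonal inflation, emulating repetitive, locally
  concentrated transitions;
* `letter_tilt` — multiplicative tilt on letter-to-letter transitions with
  each row's space probability held fixed, optionally followed by a
  root-found space-column tilt that re-matches the case chain's stationary
  space probability to the control's (`match_space = TRUE`). This isolates
  transition-structure signal from space usage and is the scenario behind
  the ablation comparisons. The shipped tilt strength (0.4) was chosen once
  from the analytic stationary shifts it induces — a few parts per thousand
  on common letters, the same scale as the space-shift effect.

What the generator does *not* emulate: lexical or semantic content, real
word-length distributions (text is a character-level chain sample),
disfluency tokens, demographic covariates, or any acoustic phenomenon.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly under controlled, known effects — not that the effects themselves
transfer to clinical corpora.

## Scenario sizes used by the test-suite

Property and whole-pipeline tests run at the reference composition (552
transcripts) for everything classifier-facing: with the fixed penalty
C = 1.0 the Lasso's selection threshold is calibrated to that sample scale,
and at a few hundred transcripts a single small-scale feature is correctly
shrunk to zero — an honest property of the stated classifier rather than a
test artefact. The clustering property uses 100 transcripts per group at
fixed length 1500 (the top of the default range) so that within-group
spread is dominated by the modelled participant heterogeneity rather than
finite-length estimation noise. Null calibration uses 1000 simulated
feature screens and 200 label permutations; stationary recovery uses 20
transcripts of 5000 characters. These sizes are the package's own choices
for stable, seeded checks.

## Design decisions that were genuinely open

* **Penalty strength.** The classifier uses a fixed inverse regularisation
  C = 1.0 with class-balanced weights; an inner-CV selection mode was
  considered and rejected by default for determinism and comparability
  across variants and smoothing constants.
* **Aggregation.** Reported metrics are means ± SD of per-fold metrics;
  pooled out-of-fold metrics are reported alongside, and calibration and
  threshold analyses operate on the pooled predictions.
* **Clustering space.** k-means runs in the full 27-dimensional feature
  space; PCA is display-only. Silhouette selects k, ties to the smaller k.
* **Label agreement.** For k = 2 the cluster/label agreement is the
  max-over-swaps accuracy; for k > 2 each cluster claims its majority
  label.
* **Ranking.** KS screen results are ranked by the D statistic (not the
  p-value); both raw and Bonferroni-adjusted p-values are emitted.
* **Second-order smoothing.** Smoothing is over the 27 emissions per
  bigram row, not over 729 successor states; this preserves the 18,954
  free-parameter count and is the standard lifting of a bigram-emission
  model to a bigram-to-bigram chain.

## Known limitations

* The asymptotic KS p-value is conservative for very small groups; use the
  permutation mode below a few dozen samples per group.
* The fixed-penalty Lasso is scale-sensitive: at sample sizes well below
  the reference composition it can shrink weak single-feature signals to
  zero (predicting the majority-class rate everywhere, AUC 0.5).
* Greedy grouped stratification keeps fold class proportions within a few
  points of global in all tested regimes but offers no worst-case
  guarantee when one participant dominates the corpus.
* The generator's effects act uniformly over rows; real cognitive decline
  presumably perturbs specific lexical contexts heterogeneously.

## A worked run

```{r pipeline, eval = FALSE}
spec <- generator_spec(seed = 42)          # reference composition
corpus <- generate_corpus(spec)
fm <- build_feature_matrix(corpus$sequences, alpha = 0.01)
screen_features(fm)                        # KS screen, space ranks first
cv <- charmark_cv(corpus, seed = 7)        # grouped 5-fold Lasso
summary(cv)
plot(cv)                                   # reliability curve
```
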