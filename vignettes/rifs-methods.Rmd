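---
title: "Randomly re-started incremental feature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomly re-started incremental feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Transcriptome case/control studies produce matrices with thousands to tens
of thousands of features (genes, probesets) and tens to a few hundred
samples — the "large *p*, small *n*" regime.  Biomarker panels for such
data are usually assembled with *filter* methods: each feature is scored by
its univariate association with the class label (a t-test p-value, say),
and the top *k* features are kept.  Filters are fast but blind to
inter-feature structure.  The classical *incremental feature selection*
(IFS) refinement evaluates the prefixes of the ranked list —
$\{f_1\}, \{f_1,f_2\}, \dots$ — with a classifier under cross-validation
and stops at the first accuracy decrease.

Two failure modes motivate this package:

1. **Low-ranked synergies.**  Two features can be individually near-null
   under a univariate test yet jointly separable (their informative
   direction is a *contrast* that no marginal test sees).  A prefix search
   anchored at rank 1 never reaches them.
2. **Premature stops.**  One accuracy dip is often followed by a larger
   gain one or two features later; stopping at the first decrease forfeits
   that gain.

## The algorithm

All features are first ranked by the two-sided pooled-variance two-sample
t-test p-value (ties broken by original feature index, so the ranking is a
deterministic bijection).  The unit search `sifs(k, D)` then walks the
ranked list from start rank $k$:

* evaluate the prefix window $\{f_k\}, \{f_k,f_{k+1}\}, \dots$ with the
  cross-validated maximal accuracy (mAcc, below);
* maintain a counter of **consecutive strict decreases** — step $t$ counts
  iff $acc_t < acc_{t-1}$; a plateau ($acc_t = acc_{t-1}$) resets the
  counter.  Plateaus are common because pooled CV accuracy is a ratio of
  small integers, and treating them as decreases would stop on exactly the
  flat stretches that are worth crossing;
* stop when the counter reaches the tolerance $D$, the rank list is
  exhausted, or a safety cap on the window length (default 100) is hit;
* return the **best prefix ever seen**.  When several prefixes tie, the
  first occurrence (fewest features) wins.  Returning the global maximum
  rather than the last pre-stop prefix follows directly from the
  optimisation goal; the stopping rule only decides how far to look.

`rifs()` runs `sifs` from $\lceil p \cdot n\rceil$ start ranks (default
$p = 45\%$), drawn without replacement from *all* ranks as one seeded
permutation truncated at the budget.  Two consequences of that
construction are deliberate:

* **rank 1 is always included**, so the restarted search provably
  dominates the classical rank-1 search in search accuracy;
* **start sets are nested across budgets** under the same master seed, so
  the search accuracy is exactly monotone in the start percentage — a
  property the test suite asserts rather than assumes.

The winning trace is chosen by best accuracy, ties broken by fewer
features, then by smaller start rank (a smaller panel with equal accuracy
is clinically preferable).  The winning subset is finally re-scored with
the full report protocol.

## The evaluation protocol

For a candidate subset, each of `report_seeds` (default `0:19`) draws one
stratified k-fold split (default $k=10$): positives and negatives are
split separately into folds whose sizes differ by at most one, and all
classifiers share the same split.  Confusion counts are **pooled over the
folds of one run** — run-level accuracy is exactly
$(\sum TP + \sum TN)/m$ — then run-level metrics (Sn, Sp, Acc, Precision,
F-score) are averaged over seeds.  `mAcc` is the maximum of the
*seed-averaged* accuracies over the classifier set; maximising per seed
before averaging would bias `mAcc` upward.

The search phase inside `sifs` uses a single seed (one round of 10-fold
CV) for speed; only the final report uses the 20-seed protocol.  The
special case $k = m$ is leave-one-out and is seed-invariant.  Degenerate
metric denominators follow the usual conventions: Precision is 0 when
nothing is predicted positive, and the F-score is 0 when Precision + Sn
is 0.

Features are used as-is by default — normalised expression matrices are
already on a common scale — with an opt-in z-scaling fitted on training
folds only (never on the held-out fold).

## The classifier panel

`mAcc` is maximised over five classifiers, the panel conventional for this
kind of benchmark: SVM, KNN, DTree, NBayes, LR.  They are implemented in
compiled code inside the package (no suitable implementations are
guaranteed on a minimal R installation) with fixed, documented
hyperparameters and **no internal randomness** — ties are broken by index
everywhere, so identical inputs give bit-identical results:

| name   | model                                   | fixed defaults |
|--------|-----------------------------------------|----------------|
| SVM    | least-squares SVM, RBF kernel           | $C=1$, $\gamma = 1/(d\,\mathrm{var}(X))$ |
| KNN    | k nearest neighbours, Euclidean         | $k=5$, distance-then-index tie-break |
| DTree  | CART, Gini impurity, grown to purity    | depth cap 30 |
| NBayes | Gaussian naive Bayes                    | variance smoothing $10^{-9}\max_j \mathrm{var}(x_j)$ |
| LR     | logistic regression, IRLS               | ridge $\lambda=1$ on weights, free intercept |

The panel is open: `register_classifier()` accepts any
`train(X, y)` / `predict(model, X)` pair, which then participates in
`mAcc` exactly like the built-ins.  A training failure on a fold falls
back to majority-class predictions with a warning, so one fragile
classifier cannot abort a whole search.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pStartingPercentage` | 0.45 | start ranks as a fraction of *n*.  45% is the published operating point; the CLI quick profile uses 0.05 because 45% of a 50k-feature array is cluster-scale work (`--paper-defaults` restores 0.45) |
| `pStoppingDepth` | 4 | tolerated consecutive strict decreases |
| `folds` | 10 | CV folds in both phases |
| `search_seeds` | `0` | one CV round during the search |
| `report_seeds` | `0:19` | twenty CV rounds for the final report |
| `max_subset_size` | 100 | cap on window length; published panels never exceeded 27 features, the cap only bounds pathological flat traces |
| `restart_patience` | off | optional early exit after this many consecutive starts without improvement; off by default because the fixed start budget is the primary contract |
| `scale` | off | in-fold z-scaling |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces a normalised-expression-like matrix:
standard Gaussian background features in both classes, `n_strong` features
with a class-mean shift (default $\delta = 3$ at $m = 60$, an unambiguous
rank-1 signal), and planted **synergy pairs**.

A synergy pair starts from a low-variance "signal" axis $u$ (sd
`pair_separation/10`) and a high-variance nuisance axis $v$, mixed by a
45° rotation, so each coordinate looks like noise while the difference
direction recovers $u$, where the classes sit about `pair_separation`
apart — a ~10-sigma linearly separable margin.  The marginal camouflage is
then made *exact*: each member's realised class-mean difference is
re-imposed (with opposite signs) so that its pooled t-statistic equals
exactly the t value whose p-value sits at the `target_rank_zone` quantile
(default 0.1) of the uniform background p-value distribution.  Because
both members receive exactly the same $|t|$, their p-values coincide and
the stable tie-break places them on adjacent ranks — mirroring the
empirical motivation, where the interesting feature pairs appear at
consecutive ranks with p-values equal to several decimals.  Without this
calibration the two members' realised ranks drift apart by dozens of
positions at $m = 60$ and the planted phenomenon becomes a lottery.

The generator deliberately does **not** emulate probe-level noise, batch
effects, heavy-tailed expression, or correlated background blocks.  A
green test therefore establishes that the algorithm recovers the
phenomenon it targets under its stated statistical model — not that it
will do so on any particular real array.

## Numerical and degenerate-case choices

* Constant features get p-value 1 (ranked last) for every method; a
  feature with zero within-class variance but distinct class means gets
  p-value 0.  The ranking must be total: constant probes are routine
  post-filter artifacts.
* The Wilcoxon ranking uses the exact distribution when both groups are
  small and tie-free, the continuity-corrected normal approximation
  otherwise.
* The ANOVA-F ranking equals the squared pooled t; on two groups the two
  orderings are mathematically identical, which the suite uses as a
  cross-method oracle.
* All randomness is derived from explicit integer seeds through one
  helper that restores the caller's RNG state; repeated runs of any
  function with equal inputs are bit-identical.

## Scaled-down simulation sizes

Property checks whose nominal design calls for ~100 simulation replicates
run with fewer replicates in the test suite (e.g. the synergy-recovery
check uses 10 generator seeds with ≥ 9 required instead of 100 with
≥ 90) so that the whole suite fits a single-CPU budget.  The success
*proportion* demanded is unchanged, the seeds are fixed constants chosen
before the outcomes were measured, and each scaled test says so in a
comment at the test site.

## Known limitations

* **The ranking is computed once, on all samples.**  This follows the
  protocol the algorithm family uses, but it means the cross-validated
  accuracies are subject to feature-selection bias: with thousands of
  null features and a few dozen samples, the top few dozen ranked
  features can reach CV accuracy 1.0 with no real signal.  At that
  ceiling, genuinely informative windows can only *tie* such decoy
  windows, and the parsimony tie-break may then prefer a decoy.  The
  package reports search and report accuracies exactly as defined and
  leaves nested (per-fold) re-ranking out of scope; treat near-ceiling
  accuracies at large $n/m$ with the usual suspicion.
* The search evaluates one round of CV per prefix; on very small samples
  the winning window is sensitive to the search seed (this is by design —
  the seed sweep makes the sensitivity visible rather than hiding it).
* Wrapper baselines (e.g. the Lasso adapter) are off-the-shelf fits
  provided for orientation only and are not part of the validated
  surface.
* Multi-class problems, AUC reporting and any normalisation of raw array
  data are out of scope: the package consumes normalised matrices.
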