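---
title: "LR-PCA for breast-lesion CAD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LR-PCA for breast-lesion CAD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocad)
```

# The problem

Frozen convolutional networks turn a 32×32 mammogram patch into thousands of
features (4096 for AlexNet/VGG16, 1024 for GoogLeNet). Those features are
heavily multicollinear — most pairwise correlations are significant — which
destabilizes downstream classifiers, and only a small subspace carries class
information. `mammocad` implements a two-stage remedy: covariance PCA to
decorrelate, then a binomial logistic regression whose per-coefficient Wald
tests decide which principal components are worth keeping.

# Data preparation

ROIs are square patches in a normalized intensity domain `[0, 1]`
(quantized to 8 bits only on write, round-half-up). Circle-annotated lesions
are tiled with non-overlapping `side × side` squares whose four corners lie
inside the circle; box annotations are cropped whole and resized. Tiles
reaching outside the image are dropped rather than padded — padding would
fabricate tissue. Augmentation uses only 90°-multiple rotations by default
(exact pixel permutations, no interpolation), quadrupling the sample count;
up-down/left-right flips are available but opt-in, because the canonical
×4 arithmetic (144 ROIs → 576 samples) corresponds to rotations alone and
how flips would compose with rotations is underdetermined (×12 if composed,
×4 subsets otherwise).

The pseudo-color mapping stacks three deterministic views of one patch:

* channel 1 — the untouched patch (bit-identical, asserted in tests);
* channel 2 — CLAHE with an 8×8 tile grid, 256 bins, and a normalized clip
  limit of 0.01 (1% of the tile mass per bin). These are the common
  defaults across imaging toolkits; all are configurable.
* channel 3 — a percentile stretch saturating the bottom and top 1% of
  pixels, computed per image by linear interpolation between order
  statistics; if the two percentile values coincide (a constant patch) the
  input is returned unchanged.

Pseudo-coloring happens at native ROI resolution and the stack is resized
afterwards, so channel synthesis is independent of the backbone choice.
Resizing is bilinear; the anti-aliasing prefilter is applied only when
decimating (its purpose), which also keeps constant images exactly constant
under upscaling.

mini-MIAS-style annotations use a bottom-left coordinate origin; they are
converted to top-left raster coordinates at extraction time
(`y' = H − 1 − y`), when the image height is known.

# The backbone contract

The three classic architectures are represented as explicit layer tables
(AlexNet with its original grouped convolutions on layers 2/4/5 — the
variant whose parameter count rounds to 61M; VGG16, 138M; Inception-v1
without auxiliary classifiers, ≈7M). The tables serve three purposes: they
*prove* the printed feature dimensionalities (the tap is the last hidden
fully-connected layer for AlexNet/VGG16 and the global-average pool for
GoogLeNet — the only tap consistent with 1024 features), they give exact
parameter counts by arithmetic rather than quotation, and they back a real
forward pass. With `weights_source = "random_seeded"`, weights are drawn
once from a seeded He-normal initialization, so shape and determinism
properties of the true architectures are testable with no download;
pretrained weights can be supplied as a serialized layer list. The
`fallback` extractor (bilinear downsample to 16×16×3, flatten, seeded
random orthonormal projection) is the default for end-to-end runs: it is
deterministic, fast, and preserves enough geometry for the synthetic
classes.

# The LR-PCA model

Let `X` be the n×p training feature matrix and `y ∈ {0,1}`.

**Step 1 — covariance PCA.** Eigendecomposition of `cov(X)` (divisor
n−1), components ranked by decreasing `|λ|`. Ranking by magnitude is
faithful to the procedure's definition even though covariance eigenvalues
are non-negative, so it never changes the result. Mean-centering only — no
variance scaling — because the object decomposed is the covariance matrix;
standardization would change which directions dominate. When p > n the same
eigenproblem is solved through the n×n Gram matrix. Numerical conventions,
chosen once so a fit is bit-reproducible: eigenvector signs are fixed by
making the largest-magnitude entry positive; `|λ|` ties keep the original
eigen-index order.

**Step 2 — pooled or per-class fitting.** `mode = "pooled"` fits one basis
on all training rows. `mode = "per_class"` fits a separate basis per class
(each with its own mean), keeps the top `⌈K/n_classes⌉` components of each,
and concatenates the blocks in label-sorted order. Each component carries
the mean of its fitting class, so projection `vⱼᵀ(x − μⱼ)` is a fixed
affine map and a test sample never needs a class label to be projected.
Using the per-component fitting mean (rather than a pooled mean for all
blocks) is the convention adopted here; it makes each block's training
scores exactly centered within its own class.

**Step 3 — logistic Wald selection.** A binomial logistic regression with
intercept is fitted on the K score columns by IRLS (deviance tolerance
1e-8, ≤100 iterations). Standard errors come from the inverse observed
information at the optimum; `t = β/SE`; p-values are two-sided from the
standard normal — the conventional Wald scheme for binomial models, and the
one consistent with a printed `t = β/SE` column. Components with `p < α`
(default 0.05) are kept; the intercept never is; an empty selection is
legal and left to the caller (the bundled experiment driver then retains
all K columns, with a message).

## Separation and the Firth fallback

On well-separated data — precisely the regime a good CAD pipeline produces —
the training scores are often linearly separable once K is a substantial
fraction of n (with K = 50 and n ≈ 300–400, a handful of boundary errors
can be absorbed by the ~47 uninformative directions). The plain MLE then
diverges and Wald statistics degenerate: estimates and standard errors grow
without bound and every p-value drifts to 1, so significance-based
selection silently returns nothing. A token ridge penalty (1e-6) keeps the
algebra finite but not the statistics. The package therefore falls back to
Firth's bias-reduced logistic regression (Jeffreys-prior penalized
likelihood with the hat-value score adjustment) whenever the fitted
probabilities reach the double-precision boundary or IRLS fails to
converge: estimates are always finite and the Wald tests retain usable
power. The non-separated path is untouched — it is the exact MLE, verified
against `stats::glm` to 1e-6 in the tests — and a plain ridge fallback
remains available via `separation = "ridge"`.

Even with Firth, per-coefficient power under complete separation is
limited; in particular, per-class bases contain near-duplicate directions
across the two class blocks, which splits significance between twins. On a
perfectly separable fixture the selection is therefore conservative, often
empty. This is a property of Wald selection itself, not an implementation
artifact, and it is why the selection-behavior tests use feature-table
fixtures in the moderate-separation regime where the method is informative.

# Diagnostics

`pairwise_correlation()` quantifies the multicollinearity motivation:
Pearson r per feature pair with p-values from `t = r√((n−2)/(1−r²))` on
n−2 degrees of freedom, a 10-bin p-value histogram (last bin right-closed),
and the fraction of pairs below 0.1. Pair enumeration is capped at the
first 200 columns by default — 4096² pairs add nothing to a diagnostic.
Constant columns have undefined r and are excluded with a count.
`retained_energy()` reports `Σ|λ₁..k| / Σ|λ|` per fitting group, the
cumulative-energy curve that `plot.lrpca()` draws.

# Classification protocol and metrics

The split is stratified 70/15/15 (largest-remainder apportionment globally
and per class, so the printed sizes are hit exactly and class balance holds
within one sample). Six classifier families are tuned over small documented
grids by validation accuracy: CART depth {3,5,10,30}; LDA and QDA; SVM
linear/RBF with cost {0.1,1,10}; kNN with k {1,3,5,7}; Gaussian naive
Bayes; and the random-subspace ensemble of 30 1-NN learners, each on a
random half of the columns, majority vote. The winning *configuration* is
chosen by 5-fold cross-validation over train+validation with the entire
LR-PCA reduction refit inside each fold, for two reasons. First, a 15%
validation set routinely ties several families at 100%, and CV breaks
those ties on evidence rather than list order. Second, the experiment
driver lets two pipeline variants compete in the CV — classifiers on the
Wald-selected components versus classifiers on all K score columns —
because on separable data the Wald filter can retain a small,
weakly-informative subset (see the separation discussion above), and
whether the filter helps is an empirical question the data can answer.
Ties prefer the selected (smaller) pipeline. The held-out test set never
participates in any of this.

Metrics are the standard confusion-matrix panel in percent; AUC integrates
the score-threshold ROC by the trapezoid rule (a constant score yields
exactly 50, a perfect ranker 100). Scores feeding the ROC are
positive-class vote fractions (kNN, ensemble), posterior probabilities
(tree, discriminant, naive Bayes) or oriented decision values (SVM). Where
a printed operating point is internally inconsistent (an FNR cell that
contradicts `100 − SE`), the identity-consistent value is what this package
computes.

# What the synthetic generators emulate — and what they do not

`simulate_rois()` produces smoothed-noise backgrounds in a mid-gray band
with a centered Gaussian lesion: contrast 0.15 (benign) vs 0.5
(malignant), ±10% per-sample contrast jitter, σ=0.05 pixel noise, and a
sinusoidal radius modulation (spiculation) for the malignant class. These
values were fixed once to mirror the near-separable regime that published
ROI benchmarks occupy (test accuracies ≈98–99%); the desk-scale experiment
(200 patches/class) reaches ≥95% held-out accuracy across seeds.

`simulate_features()` emulates the two statistical properties the reduction
targets: grouped multicollinearity (disjoint feature groups loading on
latent factors) and a low-rank informative subspace (labels
Bernoulli-logistic in the first three factors, effect 15 per factor ⇒ Bayes
accuracy ≈98%). The factor spectrum is deliberately shaped: informative
loadings 2.6→1.1 times the base, background 0.55→0.4. Because the label
model is a single linear index, individual informative factors are only
separately identifiable when the sample eigenvectors align with the
factors; the wide eigen-gaps guarantee that alignment at n = 400, which is
what makes planted-subspace recovery a fair test (100/100 seeded
replicates; null selection rate 0.06 ≈ α).

Neither generator attempts realism: no breast anatomy, no pectoral muscle,
no acquisition physics, no learned texture. Passing tests demonstrate that
the pipeline's machinery is correct and leakage-free under the structural
assumptions (class-dependent low-rank signal plus correlated noise), not
that any particular accuracy will transfer to real mammograms.

# Problem sizes and numerics used by the test suite

The suite exercises PCA against an SVD oracle on 20×8 and 50×10 matrices
(1e-8 on eigenvalues), the logistic fit against `glm` on ≥20 random
problems of n = 30–90 (1e-6, both solvers run to tight tolerance), metric
identities to 1e-9, recovery and null-calibration on 100 replicates of the
n = 400, K = 50 fixture, and single-image forward passes through all three
architecture tables. The end-to-end experiment uses 200 patches per class
with the 256-dimensional fallback extractor. These sizes were chosen to
make every property measurable in seconds on one core while keeping the
statistical regime (K/n ratio, separation behavior) the same as at full
scale.

# Known limitations

* Binary classification only; the multinomial extension of the selection
  step is out of scope.
* Wald selection under complete separation is conservative even with the
  Firth fallback; likelihood-ratio or penalized-score selection would have
  more power there and could be added behind the same interface.
* The per-class basis duplicates shared directions across class blocks;
  coupled with Wald collinearity-splitting this can empty the selection on
  separable data (see above).
* DICOM inputs are not read; full-field images must be converted to
  PNG + box annotations first. No breast segmentation or pectoral-muscle
  removal is performed.
* `K` and `α` are fixed inputs (50, 0.05), not cross-validated.
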