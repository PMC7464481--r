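---
title: "Late-integration multi-omics subtype classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Late-integration multi-omics subtype classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixnet)
```

## The problem

Breast tumours are routinely stratified into molecular subtypes from three
immunohistochemistry (IHC) markers — estrogen receptor (ER), progesterone
receptor (PR) and HER2. The five-class scheme used here is: luminal A
(ER or PR positive, HER2 negative), luminal B (ER or PR positive, HER2
positive), HER2-positive (ER and PR negative, HER2 positive), triple-negative
(all three negative), and "unclear" for samples whose markers cannot resolve
one of those classes. Cohorts built this way are strongly imbalanced: a
typical 606-sample multi-omics cohort splits 277 / 40 / 11 / 70 / 208.

omixnet predicts these subtypes from three gene-level omics layers measured
on the same samples — mRNA expression, DNA methylation (beta values in
\[0, 1\]) and copy-number variation — using a *late-integration* neural
network: each omics layer is first transformed by its own encoding
subnetwork, and only the learned representations are combined.

## The model

Each omics type $o$ with $M_o$ selected features has an encoding subnetwork

$$ h_o = \mathrm{dropout}(\mathrm{ReLU}(\mathrm{BN}(x_o W_o + b_o))), \qquad
   W_o \in \mathbb{R}^{M_o \times K}, $$

a single fully connected layer with batch normalization, ReLU activation and
dropout. The per-omics representations are concatenated in a fixed order
(mRNA, methylation, CNV) and the concatenated row is divided by its
Euclidean norm, so a cohort of $N$ samples with three equal-width encoders
yields an $N \times 3K$ integrated representation with unit-norm rows. A
single linear classification layer with dropout and weight decay maps that
representation to the output: a sigmoid with binary cross-entropy for
pairwise subtype tasks, and a softmax with cross-entropy for the five-class
problem. The whole network — encoders and head — is trained jointly.

Class imbalance is handled in the sampler, not the loss: mini-batches are
drawn with replacement with per-sample probability proportional to the
reciprocal of the sample's class size, so every class is drawn uniformly in
expectation. This realizes simultaneous undersampling of large classes and
oversampling of small ones; one epoch is defined as $N$ draws, so epoch cost
is independent of the imbalance.

### Hyperparameters

The architecture leaves several knobs open; the package fixes deliberately
moderate, untuned defaults, all overridable through `omixnet_config()`:

| parameter | default | notes |
|---|---|---|
| encoder width $K$ | 64 | integrated width is $K \times$ number of omics |
| dropout | 0.5 | after each ReLU |
| learning rate | $10^{-3}$ | Adam (adaptive-moment) optimizer |
| weight decay | $10^{-4}$ | classification layer only |
| epochs | 100 | fixed budget, no early stopping |
| batch size | 32 | batches of size `< 2` are skipped (batch-norm statistics undefined) |
| decision threshold | 0.5 | binary tasks; $p \ge 0.5$ predicts the positive class |

Batch normalization sits between the affine map and the ReLU, dropout after
the ReLU — the conventional stack. Weight decay is restricted to the
classification layer; the encoders are regularized by dropout and batch
normalization. Running batch-norm statistics (momentum 0.1) are used at
prediction time, so evaluation is deterministic.

## Feature selection

With tens of thousands of genes and a few hundred samples ("large $p$,
small $n$"), each omics layer is reduced before training by a chi-squared
filter. The score is the *class-sum* form used throughout the
feature-selection tradition: for a non-negative feature, the observed
"counts" are the per-class sums of the feature, the expected counts are the
class frequencies times the total sum, and the statistic is
$\sum_c (O_c - E_c)^2 / E_c$ with $n_\text{classes} - 1$ degrees of freedom.
Genes are ranked by ascending p-value (ties: larger statistic, then
alphabetical gene symbol — fully deterministic) per classification task,
using only that task's samples, and the top $k$ genes per omics are kept.

Three points deserve emphasis:

* **Non-negativity.** The class-sum form requires non-negative inputs, so
  each gene is min–max rescaled to \[0, 1\] first (constant genes map to
  zero and rank last). This also settles how negative CNV log-ratios enter
  the test.
* **Calibration.** The chi-squared reference distribution is justified for
  Poisson-like count features (conditional on the total, the class sums are
  multinomial). For continuous rescaled features the p-values are *ranking
  scores*, not calibrated tail probabilities; the package's null-calibration
  tests therefore use Poisson count features, where permuted-label p-values
  are indeed uniform.
* **Leakage.** By default the ranking is recomputed inside every training
  fold (`selection_scope = "fold"`), so no information from held-out
  samples reaches the model. `selection_scope = "all"` reproduces the
  historically common whole-dataset selection for comparison.

The conventional default is $k = 5000$ per omics type. At the desk scale
used by the test-suite and acceptance script (2,000 genes per omics, 100 of
them informative), the suite uses $k = 100$ — matched to the planted signal
size. This matters: with only four or five training samples in the smallest
class, a selection much wider than the true signal admits enough noise genes
that the network can memorize the few minority samples in a private noise
subspace; held-out minority samples then land on the wrong side of the
decision boundary even though their ranking (AUC) is perfect. A
signal-dense selection removes that failure mode, which is the same reason
the filter helps on real data.

## Evaluation

Binary tasks are scored by balanced accuracy — the mean of sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$ — which is 0.5 for any constant
classifier however imbalanced the task, and by rank-based (Mann–Whitney)
AUC with tied pairs counting one half. The multiclass problem is scored by
plain accuracy $N_\text{correct}/N_\text{total}$; multiclass AUC is not
computed. Cross-validation is stratified (with an 11-member class,
unstratified 5-fold splits can lose a class entirely), fold assignment is
seed-controlled, and min–max scaling and feature selection are refit inside
each fold. With five subtypes there are $\binom{5}{2} = 10$ pairwise tasks;
the first-listed subtype of a pair is the positive class (balanced accuracy
is symmetric in the classes, so this affects reporting only).

The leave-one-subtype-out ablation removes each subtype in turn and reruns
multiclass CV on the remaining four classes, probing whether the weighted
sampler keeps accuracy stable as the class composition changes.

## The synthetic generator

Real cohort data cannot ship with the package, so a seeded generator
produces aligned three-omics datasets with known ground truth:

* **mRNA** — log-normal: per-gene baseline $\mathcal{N}(6, 1.5^2)$ on the
  log2 scale, unit-variance Gaussian noise, exponentiated.
* **Methylation** — beta-like values: logistic transform of a Gaussian with
  per-gene baseline $\mathcal{N}(0, 1.5^2)$; values are guaranteed in
  \[0, 1\].
* **CNV** — integer calls in $\{-2, \dots, 2\}$ from a standard Gaussian
  latent log-ratio thresholded at $\pm 0.5, \pm 1.5$.

A fraction (default 5%) of genes per omics is informative: their
transformed-scale class means are shifted by `effect_size` (default 1.5,
in within-class standard deviations) times a per-gene pattern in
$\{-1, 0, 1\}$ over classes, resampled if constant so every informative gene
carries at least one contrast. Missing values are inserted completely at
random (default 2%). Class shifts are applied on the log / logit / latent
scales so the output ranges are respected.

`signal_mode = "split"` makes each omics type *blind to one subtype pair*
(the pair shares its shift pattern there) while the pair remains separable
in another layer: expression cannot tell luminal A from unclear,
methylation cannot tell luminal A from TNBC, CNV cannot tell TNBC from
unclear. No single layer can then separate all five classes, but their
union can — the construction behind the multi-omics-advantage checks. The
blinded pairs deliberately involve the large classes so each single-omics
model pays a visible accuracy cost.

What the generator does **not** emulate: gene–gene correlation, batch
effects, methylation–expression coupling, platform-specific noise. Passing
tests demonstrate that the implementation recovers signal it is known to
contain and fails gracefully when there is none; they are not evidence
about any real cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run the CV-based checks at the
test scale — 300 samples in the 277/40/11/70/208 proportions
(137/20/5/35/103), 2,000 genes per omics, effect size 1.5 — with 40 training
epochs and $k = 100$ selected genes per omics, sizes chosen so the full
suite completes in minutes on one CPU while every class still has at least
`k_folds` members. Unit tests use smaller cohorts still.

Other numerical decisions:

* Binary positive-class probability threshold is inclusive
  ($p \ge 0.5$); multiclass prediction is argmax with first-index
  tie-break.
* Rows of the integrated representation with norm zero are left at zero
  rather than normalized.
* Batch-norm uses the biased (1/B) batch variance, a variance floor of
  $10^{-5}$, and skips batches smaller than 2.
* Constant genes min–max-scale to all-zero; zero-sum genes get chi-squared
  statistic 0 and p-value 1, ranking last deterministically.
* Held-out samples are scaled with the training fold's min–max parameters
  and clipped to \[0, 1\].
* Missing-gene filtering drops genes missing in more than a fraction 0.33
  of samples (the "more than 200 of 606" rule generalized to any cohort
  size); remaining gaps are mean-imputed per gene by default — mean
  imputation is neutral for the class-sum statistic in expectation.
* All randomness (generator, fold assignment, initialization, sampling,
  dropout) flows from user-supplied integer seeds; identical seeds give
  byte-identical reports.

## Known limitations

* The marker rule maps records with an unresolvable missing marker to
  "unclear"; records such as (ER missing, PR negative, HER2 positive) are
  genuinely ambiguous between two classes and are deliberately not guessed.
* The methylation input contract is gene-level values; summarizing probe-
  level 450k data to genes (e.g. promoter averaging) is out of scope.
* The class-sum chi-squared p-values on continuous features are ordering
  devices, not significance statements; no multiple-testing correction is
  applied because only the ranking is consumed.
* Single-layer encoders only; no hyperparameter search, early stopping, or
  GPU path. The defaults are moderate rather than tuned.
* With very small classes (a handful of training samples), hard-threshold
  accuracy is sensitive to the selection width as described above; AUC is
  the more stable summary there.
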