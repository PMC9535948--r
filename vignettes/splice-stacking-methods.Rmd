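---
title: "Stacked neural ensembles for splice-site detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked neural ensembles for splice-site detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spliceStack)
```

## The model

`spliceStack` classifies fixed-length genomic DNA windows as true or false
splice sites, separately for donor sites (intron 5′ end, consensus GT) and
acceptor sites (intron 3′ end, consensus AG). Both the positive and the
negative class carry the consensus dinucleotide at the declared window
positions — negatives are *decoys*, genomic GT/AG occurrences that are not
spliced — so all discriminative information lives in the flanking sequence.

The detector is a two-level stacked generalization:

* **Level 0**: eight small neural networks (four convolutional, CNN1–CNN4;
  four dense, DNN1–DNN4) consume the one-hot encoded window (L × 4, column
  order A, C, G, T; unknown bases all-zero) and emit a two-unit sigmoid
  score, argmax-thresholded into a binary vote (ties go to "false site").
  Each architecture is a fixed preset; see `preset_spec()`.
* **Level 1**: the member votes for each record form a row of an N × M
  binary matrix; a logistic regression on that matrix — never on the raw
  sequence — produces the final probability, thresholded at 0.5.

Ensemble composition is selected by stratified five-fold cross-validation
over six candidate member sets (`ENS1`–`ENS6`), scored by mean held-out
accuracy together with four pairwise diversity measures computed from the
members' correctness indicators on held-out folds: correlation, double
fault, disagreement, and Yule's Q. The all-CNN set `ENS2` is the package
default.

## Training

Members train with Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7) under an
inverse-time-decay schedule `lr(t) = lr₀ / (1 + r · t / s)` with `t`
counting optimizer updates from 0. Defaults: batch size 32, at most 30
epochs, CNN schedule (lr₀ = 0.001, s = 140, r = 0.1), DNN schedule
(0.002, 80, 1.4). The loss is two-unit binary cross-entropy against
one-hot (false, true) targets — the only standard choice for a two-unit
sigmoid head. A stratified fraction of the training split (default 0.1) is
held out for early stopping on validation loss (default patience 3) with
best-weights restoration.

Unstated details we had to fix, and why:

* **Convolution geometry** — ReLU, "same" padding, stride 1. Kernel widths
  of 3–9 on short windows would otherwise shrink the sequence ambiguously;
  "same" keeps every preset applicable to every window length that
  survives its pooling stack (pooling that collapses the length to zero is
  rejected at build time).
* **Initialisation** — Glorot uniform everywhere except DNN4, which uses a
  random-normal (sd 0.05) kernel initializer, per its preset definition.
* **Decay steps** are optimizer updates, not epochs, starting at 0 at the
  first update.
* **L2 penalties** — the documented search space contains dense-layer L2
  values {0.0025, 0.025, 0.036}, but the preset tables do not place them
  on specific layers; `dense()` exposes the knob, presets ship with it
  off.
* **Meta-model regularisation** — unstated; we use a weak ridge penalty
  (λ = 1e-4, intercept unpenalised) fitted by exact IRLS. On clean data
  members often agree perfectly, making the stack separable; the penalty
  keeps the fit well-posed without materially moving the 0.5 decision
  boundary. The fit is deterministic, so the `seed` argument is interface
  symmetry only.
* **Stacking split** — the meta-model is fitted on the same training
  partition's stacked predictions, matching the source procedure as
  described; out-of-fold stacking is a documented possible extension, not
  the default.
* **Selection rule** — the published selection of ENS2 was by joint
  inspection of accuracy and diversity; `select_best_ensemble()` codifies
  it as accuracy, then lower double fault, then lower Q, and always
  returns the full ranking table so users can apply their own criterion.
* **Ensemble-level diversity** is the unweighted mean over all unordered
  member pairs; the aggregation behind single-number-per-ensemble tables
  is not otherwise specified.
* **Q-statistic** — the printed formula in the source material has
  identical numerator and denominator (identically 1), contradicting its
  own reported values; we implement standard Yule's Q with the "+"
  denominator, which is consistent with those values.

## Reproducibility

All randomness (weight initialisation, minibatch shuffling, dropout masks,
fold assignment, subsampling, data generation) flows through R's own RNG,
seeded per call and restored afterwards. Identical data and seeds give
bit-identical weights and predictions — there is no framework
nondeterminism to document because the engine is plain R + BLAS. Fold RNG
is deliberately separate from training RNG, so fold structure is stable
across architecture changes, and per-(member, fold) training seeds are
derived deterministically so a sub-model shared by two ensembles is trained
exactly once conceptually (and `compare_ensembles()` trains it exactly once
in practice).

## The synthetic world

`generate_dataset()` emulates the structure the method assumes:

* fixed window length; exact class balance; positives first;
* the consensus dinucleotide planted at the declared positions in **both**
  classes (a flag can disable decoy consensus for smoke tests);
* positive flanks drawn per position from the mixture
  `signal_strength · PWM + (1 − signal_strength) · background`; negative
  flanks from the background alone;
* separate RNG streams per class derived from one master seed, so changing
  one class's count does not perturb the other.

`default_motif()` builds the PWM: uniform background rows except a ±6-nt
neighbourhood of the consensus where one position-dependent base is
enriched to `0.25 + 0.75 · sharpness` (default sharpness 0.8). The ±6-nt
extent mirrors the empirically enriched region flanking real donor and
acceptor sites; the mixture-of-PWM signal model was chosen over k-mer
insertion because per-position frequencies are then analytically checkable
(binomial sampling bounds).

What a green test on this world does **not** establish: real splice
windows have position-dependent GC content, branch-point structure,
long-range dependencies and class imbalance that the generator does not
model. Synthetic results validate the machinery (encoding, training,
stacking, selection bookkeeping), not biological accuracy; published-scale
accuracy claims require the external window collections, which this
package deliberately does not download.

Default generator scales used in the acceptance runs are the stated ones:
1,000 records per class, window 60 nt, `signal_strength` 1.0 for recovery
and 0.0 for the null control.

## Numerical choices

* Ratios with zero denominators (e.g. specificity when TN + FP = 0) return
  0 with a `degenerate` flag instead of erroring, so CV aggregation never
  aborts on a pathological fold.
* MCC and pair-correlation denominators are computed as one `sqrt` of the
  count product (in doubles; counts are coerced from 32-bit integers
  first), so perfect classifiers score exactly 1.
* The one-hot decoder treats any all-zero row as `N`; how non-ACGT
  characters were handled in the source datasets is unstated, and the
  all-zero convention keeps real files usable while contributing nothing
  to convolutions.
* Balanced subsampling seeds a dedicated RNG (default seed 123454, the
  convention of the public collections), permutes each class and takes a
  prefix; the named seed's exact sampling procedure is otherwise unstated.
* A per-cell 3σ binomial bound applied simultaneously to ~112 PWM cells is
  expected to be exceeded somewhere in ~30% of draws; the frequency-
  recovery test therefore asserts the bound family-wise (all cells < 4σ,
  ≤ 1% beyond 3σ, deterministic rows exact) rather than pretending a
  per-cell bound is simultaneous.

## Interpretability

Two mechanisms, deliberately separated:

* `position_frequencies()` — class-conditional position frequency
  matrices, the content of standard sequence logos; exported as TSV.
* `occlusion_importance()` — for a model or ensemble, the mean drop in
  predicted true-site probability when a sliding span (default 3 nt; the
  acceptance runs use 7) is zeroed out. Zeroing is in-distribution because
  it is the same code unknown bases receive.

The underlying "contribution score" mechanism in the source material is
unspecified (it shows frequency logos); we provide the frequency logos as
the faithful reading and occlusion as a clearly-labelled model-based
extension. On the synthetic world, occlusion peaks at the consensus
centre — not because the consensus itself is informative (it is present in
both classes) but because a 7-nt span centred there covers the most
enriched flank positions at once.

## Known limitations

* The engine is CPU-only and aimed at window lengths ≤ ~600 nt and
  datasets of 10³–10⁴ records; it is not a general deep-learning
  framework.
* Members emit hard votes to the meta-model by default (matching the
  source's worked example); probability stacking loses the published
  semantics and is not implemented.
* No ROC/AUC (none are reported in the source setting); no nested CV or
  hyperparameter retuning inside folds — the documented search-space
  constants (`hyperparameter_search_space()`) record where the presets
  came from, and the search is not re-run.
* Cross-validating all six ensembles with full 30-epoch training on
  published-scale data is hours of CPU; the test suite exercises the same
  code paths at reduced epochs and record counts, stated inline.
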