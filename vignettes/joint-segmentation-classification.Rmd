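---
title: "Joint segmentation and classification of clinical Chinese text: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segmentation and classification of clinical Chinese text: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`jointcws` implements a joint multi-task model for two coupled tasks on
unsegmented clinical Chinese text: character-level word segmentation
(cast as B/I/O sequence tagging) and binary syndrome classification
(Yang deficiency vs Yin deficiency).  This vignette is the package's
account of the model, its assumptions, the choices that were genuinely
open, and what the synthetic test bed does and does not demonstrate.

## The model

Each record is a character sequence.  A shared embedding matrix maps
characters to dense vectors; two heads consume the embedded sequence:

* **Segmentation head.**  A bidirectional LSTM (one forward and one
  backward pass, hidden states concatenated per position) followed by a
  linear map to three scores per character.  Tags are `B` (first
  character of a multi-character word), `I` (subsequent character) and
  `O` (single-character word) — the only consistent three-symbol
  convention in which every word is recoverable.  Prediction takes the
  per-position argmax and reverse-matches tags into words.  Ill-formed
  predicted sequences are repaired rather than rejected: an `I` at the
  sequence start or directly after an `O` opens a new word, so decoding
  always yields a total segmentation.
* **Classification head.**  A TextCNN: for each kernel width (3 and 5
  by default) a 1-D convolution over positions with 100 channels and a
  ReLU, max-pooled over positions, the pooled features concatenated and
  linearly mapped to two class scores.

Both heads backpropagate into the shared embedding, which is the entire
shared trunk: segmentation supervision teaches the embeddings word
structure that the classifier's n-gram filters can exploit, and class
supervision nudges embeddings of class-indicative symptom words apart.

### Losses and masking

Batches are right-padded to the batch maximum length.  The tagging loss
is a *masked* cross-entropy: the mean negative log-softmax probability
of the gold tag over real character positions only.  Padding positions
contribute exactly zero — appending padding leaves the loss
bit-identical, which the tests assert literally.  The same philosophy
is applied inside the classification head: max-pooling windows
consisting entirely of padding are excluded (filled with `-Inf` before
the max), so pooled features are invariant to padding; sentences
shorter than the widest kernel are padded up to that width, and the
padding embedding row is frozen at zero.  The classification loss is an
ordinary cross-entropy over records.

The joint objective is `Loss = r0*L0 + r1*L1`.  Four weighting
strategies are implemented:

* **Fixed** (grid search): constant weights; the default grid is
  `{0.1, ..., 0.5}` per task, searched by validation classification
  accuracy, with `r0 = r1 = 0.4` as the default fixed weights.
  Because the optimizer is Adam, whose steps are invariant to a global
  rescaling of the gradient, only the ratio `r0:r1` is material.
* **Gradient normalization.**  With per-task gradient norms
  `G_i = r_i * ||∇_emb L_i||` measured on the shared embedding (the last
  — and only — shared layer), inverse training rates
  `L_i(t)/L_i(0)` and their ratios `rho_i`, targets are
  `mean(G) * rho_i^alpha` (`alpha = 1.5`).  The weights descend
  `sum_i |G_i - target_i|` treating targets as constants.  The weight
  step uses its own Adam moments at learning rate 0.025: a raw signed
  step scaled by the task gradient norm oscillates whenever the norms
  are far from unit scale, whereas Adam's normalized step makes the
  update invariant to that scale.  Weights are clamped to `>= 1e-4` and
  renormalized to sum to 2 (the task count) after every update.
* **Dynamic weight averaging.**  Per epoch,
  `w_i = L_i(t-1)/L_i(t-2)` and `r_i = 2 exp(w_i/T)/sum_j exp(w_j/T)`
  with temperature `T = 2`; the first two epochs use uniform weights.
* **Uncertainty weighting.**  Per-task log-sigmas `s_i` are trained by
  the same optimizer as the network; the objective is
  `exp(-2 s0) L0 + s0 + exp(-2 s1) L1 + s1`.  Both tasks use the
  classification form of the weighting because both losses are
  cross-entropies.  The stationary point of `s_i` is
  `0.5 * log(2 L_i)`, so the task with the larger irreducible loss —
  the noisier task — ends with the larger sigma; the additive `s_i`
  regularizer prevents weight collapse.

### Optimization protocol

Adam (learning rate 0.001), 50 epochs and a 60/10/30
train/validation/test split are the default protocol; the model is
checkpointed at the epoch with the minimum validation joint loss and
that checkpoint is what the test set sees.  Batch size defaults to 32.  Gradients are globally
clipped at norm 5 (with a counter of clip events) to protect the
recurrent pass.  Training batches are bucketed by sentence length —
records of similar length share a batch and the batch order is
shuffled per epoch — which reduces wasted computation on padding
without changing what any record contributes to the loss.  GradNorm
and uncertainty weights update per optimizer step, DWA per epoch.

"Seven-fold cross-validation" combined with a fixed 60/10/30 split is
not a standard fold scheme; `run_cross_validation()` therefore
implements it as seven independently reseeded 60/10/30 splits whose
test metrics are averaged (mean and standard deviation reported, per-
fold seeds logged).  The splits themselves are stratified by class
label — not strictly required by the protocol, but with corpora of
this size an unstratified test set can become degenerate.

### The two-stage baseline

The non-joint comparator trains the Bi-LSTM tagger alone (stage 1),
then trains a TextCNN classifier (stage 2) on sentences re-represented
using stage-1's *predicted* segmentations — on train, validation and
test alike, so the classifier never sees gold boundaries.  How the
predicted segmentation should condition stage 2 is genuinely open; the
package appends a learned 8-dimensional boundary-tag embedding (indexed
by the predicted B/I/O tag) to each character embedding.  This keeps
the classifier architecture identical across modes, so joint-vs-two-
stage comparisons isolate the effect of joint learning rather than an
architecture change.  A word-level alternative (classifying over
predicted word units) would change the classifier's input space and is
deliberately not implemented.  Each sentence undergoes feature
extraction twice in this mode (`feature_passes_per_sentence = 2` in the
run result), the efficiency cost the joint model avoids.

## Architecture sizes

Embedding dimension (128), recurrent hidden size (128 per direction),
convolution channels (100 per width) and dropout (0.1 on the tag-head
input and the pooled classification features) are engineering defaults
chosen so the default configuration lands near half a million
parameters; the kernel widths (3 and 5) are the fixed design points.  `count_parameters()` gives the closed-form count for any
configuration and is tested against the actual array sizes.  The
package's own test bed and the acceptance script run a compact
32/32/32 configuration: on corpora of one or two thousand synthetic
records it trains to the same ceilings in a few minutes of CPU time,
and nothing in the tested properties depends on the larger sizes.

## The synthetic test bed

The clinical corpus the design targets (about 1200 annotated records,
two roughly balanced syndrome classes) is not redistributable, so the
generator in `synthetic_spec()`/`generate_corpus()` emulates its
structure: sentences of 5–30 words drawn from a lexicon of 1–4
character words (length distribution 0.15/0.50/0.25/0.10, two-character
words dominating as in Chinese), a balanced latent class per record,
one informative slot per sentence filled with a class-indicative word
with probability `class_word_strength`, and optional label noise.  Two
properties are enforced by construction:

* **Prefix-free lexicon.**  No word is a prefix of another, which
  guarantees a unique segmentation of every sentence and makes perfect
  segmentation an achievable ceiling; a greedy longest-match oracle
  (`oracle_segment()`) provably recovers the gold words, and the tests
  use it as such.
* **Disjoint class-word sets.**  With full signal strength and no label
  noise a rule-based oracle classifier is exact, pinning the Bayes
  ceiling of classification at 1.

What passing tests on this bed show is that the implementation learns
what it is supposed to learn: the ceilings are reachable, masking and
decoding are exact, the weighting strategies obey their laws, and the
statistical machinery is calibrated.  What they do not show is clinical
performance: real records have ambiguous segmentations, heavy-tailed
character frequencies, shared vocabulary between classes, and
annotation disagreement, none of which the generator imitates.

The joint-vs-two-stage comparison behaves accordingly.  On small noisy
corpora (a few hundred records with label noise) the joint model's
seed-averaged classification accuracy exceeds the two-stage baseline's
— the multi-task signal acts as a regularizer exactly where data is
scarce and noisy, which is where multi-task learning is expected to
help.  On the full clean synthetic scale the advantage disappears and
can even reverse: stage-1 segmentation of prefix-free synthetic text is
near-perfect, so the two-stage classifier receives essentially gold
boundaries and plentiful noiseless labels.  Both regimes are computed
by the acceptance script and the test suite; neither says anything
about the noisier, more ambiguous clinical setting beyond the direction
of the small-data effect.

## Numerical choices and degenerate inputs

* Weight matrices use Glorot-uniform initialization; LSTM forget-gate
  biases start at 1; embeddings start uniform in (-0.1, 0.1) with the
  padding row frozen at zero.  All initialization derives from the
  configuration seed.
* Max-pooling ties are broken toward the earliest position, making the
  backward pass deterministic.
* An all-padding row (no valid pooling window) is a degenerate input:
  the head warns once and pools over the padding-only windows rather
  than failing.
* A mask selecting no positions is an error for the tagging loss —
  there is nothing to supervise.
* Divergence (a non-finite joint loss) aborts training with a
  diagnostic rather than continuing silently.
* The recurrent forward/backward loops are compiled (RcppArmadillo);
  the package keeps an identical plain-R implementation of the same
  recurrence as an internal reference, and the test suite checks the
  two against each other and against finite differences.
* Single-threaded runs are bit-reproducible: every stochastic step
  (generation, splitting, shuffling, dropout, initialization,
  bootstrap, permutation) flows from explicit seeds through one RNG
  discipline, and repeated runs compare `identical()`.

## Statistical comparison machinery

`bootstrap_accuracy()` resamples per-item correctness with replacement
(1000 resamples by default) and reports the mean resampled accuracy
with the 2.5–97.5 percentile interval.  `permutation_test()` compares
two classifiers evaluated on the same items: the statistic is the
accuracy difference, and the null distribution is built by
independently swapping each item's pair of correctness indicators with
probability one half (10,000 permutations by default).  The reference
description does not fix the permutation scheme or sidedness; the
paired sign-flip scheme is the standard exact test for paired
classifiers, the test is two-sided to match the symmetric null, and
the p-value carries the add-one correction so it is never exactly
zero.  Calibration — interval coverage, type-I error at the nominal
level, and power for a 15-point accuracy gap — is asserted by
simulation in the acceptance tests.

## Known limitations

* Two tasks only; the weighting algebra generalizes but is untested
  beyond two.
* No CRF layer on the tagger and no pretrained transformer trunks —
  the model is the plain joint Bi-LSTM + TextCNN.
* Word-level segmentation F1 is not reported (metrics are
  character-tag based); the per-record predicted words are available
  for any downstream scoring.
* Pure-R training is CPU-bound; the practical range is corpora of a
  few thousand records at the compact configuration.
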