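# jointcws

Joint multi-task learning for Chinese word segmentation and binary
clinical text classification, in base R.

## The problem

Syndrome differentiation in traditional Chinese medicine (TCM) reads a
free-text medical record and assigns a syndrome class — here the binary
distinction between *Yang deficiency* (label 0) and *Yin deficiency*
(label 1).  Automating it from unstructured Chinese text involves two
coupled tasks:

1. **Chinese word segmentation (CWS)** — Chinese text has no spaces, so
   the character sequence must be cut into words.  Cast as per-character
   sequence tagging with three symbols: `B` begins a multi-character
   word, `I` continues it, `O` marks a single-character word.
2. **Text classification** — mapping the record to its syndrome class.

The two tasks are mutually informative: good segmentation exposes the
symptom words the classifier needs, and class evidence hints at word
boundaries.  `jointcws` trains them *jointly*: a shared
character-embedding trunk feeds

* a **bidirectional LSTM segmentation head** producing three tag scores
  per character (decoded by argmax and reverse-matched into words), and
* a **TextCNN classification head** — 1-D convolutions of kernel widths
  3 and 5 over the embedded characters, masked max-pooling over valid
  positions, and a linear layer to two class scores —

optimized end-to-end with the weighted joint objective

```
Loss = r0 * L0 + r1 * L1
```

where `L0` is a masked cross-entropy over real (non-padding) character
positions and `L1` an ordinary cross-entropy over records.  Four
strategies set the weights: fixed grid-searched weights (default
`r0 = r1 = 0.4`), **gradient normalization** (GradNorm),
**dynamic weight averaging** (DWA), and **homoscedastic uncertainty
weighting**.  The non-joint **two-stage baseline** (a standalone
Bi-LSTM tagger whose *predicted* segmentation feeds a standalone
TextCNN) is included for comparison, along with bootstrap confidence
intervals and a paired sign-flip permutation test for comparing two
classifiers on the same test set.

The clinical corpus this design targets is not redistributable, so the
package ships a synthetic-corpus generator that reproduces the
statistical structure the model assumes — multi-character lexicon
words, class-indicative symptom words with controllable signal
strength, label noise — and makes every stage testable.  The entire
network stack (embedding, Bi-LSTM, TextCNN, backpropagation, Adam) is
implemented from scratch — vectorized R with the recurrent inner loops
in RcppArmadillo — with no deep-learning framework.

## Worked example

```r
library(jointcws)

# a synthetic annotated corpus: 600 records, mild label noise
spec <- synthetic_spec(n_records = 600, label_noise = 0.05, seed = 42)
records <- generate_corpus(spec)
cat(format_annotation_line(records[[1]]), "\n")
#> yin#乊乃乢/丟丩/万乞乁/両/三乔么/...   (class name, '#', '/'-separated words)

splits <- split_dataset(records, seed = 42)   # stratified 60/10/30
vocab  <- build_vocabulary(splits$train)

mc <- joint_model_config(vocab$size, embedding_dim = 32,
                         recurrent_hidden = 32,
                         conv_channels_per_width = 32, seed = 1)
tc <- train_config(epochs = 15, batch_size = 16, seed = 1,
                   strategy = "gradnorm")
run <- train_joint(splits, vocab, mc, tc)

run$test_report$segmentation$accuracy   # fraction of characters tagged right
#> [1] 0.8264568
run$test_report$classification          # confusion-matrix metrics + AUC
#> classification metrics (n = 180)
#>   accuracy:    0.7222
#>   specificity: 0.7701
#>   sensitivity: 0.6774
#>   AUC:         0.8105

# compare against the two-stage baseline on the same split
base <- train_two_stage(splits, vocab, mc, tc)
cmp <- permutation_test(
  base$test_report$predictions$label == base$test_report$predictions$predicted,
  run$test_report$predictions$label  == run$test_report$predictions$predicted,
  n_perm = 10000, seed = 1)
cmp
#> Model A accuracy: 0.6434 (95% CI 0.5722, 0.7111)
#> Model B accuracy: 0.7245 (95% CI 0.6611, 0.7833)
#> Difference (B - A): 0.0784 (95% CI 0.0111, 0.1444)
#> Permutation test: t = 0.0778, p = 0.041 (10000 permutations)
```

The segmentation report gives character-tag accuracy plus
macro-averaged specificity and sensitivity over the three tags; the
classification report gives accuracy, specificity (recall of Yang
deficiency), sensitivity (recall of Yin deficiency) and the trapezoidal
AUC of the class-1 score.  `cmp` reports each model's bootstrap mean
accuracy with its 2.5–97.5 percentile interval (model A is the
two-stage baseline, model B the joint model), the accuracy difference,
and the two-sided permutation p-value with the add-one correction —
here the joint model's eight-point advantage is significant at the 5%
level.

A command-line wrapper over the same functions lives at
`inst/cli/jcs.R` with subcommands `generate`, `train`, `evaluate`,
`predict` and `compare`; every run writes a JSON manifest sufficient to
reproduce it.

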