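---
title: "Recommending publication venues from abstracts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending publication venues from abstracts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venuecast)
```

## The problem

Choosing where to submit a biomedical manuscript is a ranking problem: out
of hundreds of candidate journals, which ones publish work most like this
abstract? venuecast treats it as large-scale multiclass text
classification. Each journal is a class, identified by an NLM-catalog-style
unique ID so that a journal's print and electronic ISSNs collapse to one
label; each training example is one published abstract; and a
recommendation is the top-N tail of the fitted class-probability vector.
The central difficulty of the real corpus is class imbalance — journal
sizes span roughly 100 to over 100,000 papers — which is why evaluation
here is always reported both overall and stratified by journal size.

## Corpus construction

`parse_jats_record()` extracts the abstract, ISSNs, and publication date
from one JATS XML article, rejecting (with a machine-readable reason, never
an error) documents that are malformed or missing an abstract or ISSN.
`filter_corpus()` then applies the inclusion rules:

* abstracts of at least 200 characters, counted after collapsing runs of
  whitespace to single spaces (the raw XML often contains layout
  whitespace; counting before normalisation would make the rule depend on
  formatting);
* publication dates within an inclusive month window, by default
  2007-01 to 2017-04. Dates are handled at month precision; a `<pub-date>`
  with no `<month>` is treated as January, since JATS date granularity
  varies;
* journals left with at least 100 papers.

The journal-size rule runs once, *after* the per-paper rules, on the
surviving counts: a journal with 105 papers of which 10 fail the abstract
rule drops to 95 papers and is removed entirely. We do not iterate to a
fixpoint — removing a journal cannot invalidate another journal's count, so
one pass suffices. The rejection log is a first-class output rather than
optional logging: every input record is either kept or logged with the rule
that removed it, and the tests assert this conservation exactly. Records
whose ISSNs are absent from the journal list are rejected with reason
`no_issn` (the upstream behaviour for such papers is undefined; rejection
is the conservative choice).

## Representation

Abstracts are tokenized by a deterministic segmenter that lowercases (a
switch exists, but pretrained biomedical embedding vocabularies are
predominantly lowercase), splits punctuation into single-character tokens,
and keeps internal hyphens, apostrophes and slashes inside a word, so
"p53-mediated" is one token. No stop-word removal or stemming is applied.
Each abstract becomes a fixed-length sequence of `m` token ids: shorter
abstracts are zero-padded at the tail, longer ones keep their first `m`
tokens. The default `m = 350` reflects the abstract-length distribution of
a large PMC corpus, in which only about 5% of abstracts exceed 350 words;
`length_histogram()` reports the corpus statistics in the standard bands.
Word counts are taken post-tokenization (after punctuation splitting),
which is the only place a "word" is defined in this package.

Id 0 is reserved: it encodes both padding and out-of-vocabulary tokens, and
resolves to the all-zero vector at embedding time. Padding and OOV
therefore become indistinguishable downstream — intentional, since both
should contribute nothing to the convolution.

The embedding table maps tokens to `k`-dimensional vectors (`k = 200` by
default, matching the common pretrained biomedical word2vec tables, which
`load_word_vectors()` reads in both the text and the little-endian-float32
binary dialect). `train_skipgram()` provides a from-scratch alternative —
skip-gram with a Huffman-tree hierarchical softmax, window 5, subsampling
threshold 10⁻³, per-centre-word window radius drawn uniformly, linear
learning-rate decay. It is a faithful but pure-R trainer, practical at the
corpus sizes used in tests (thousands of tokens); for full-size corpora,
pretrained vectors are the intended route. The abstract matrix `V` stacks
the vectors of the encoded sequence into `m × k`; rows beyond the true
length are zero.

## The network

Three convolution/pooling stages followed by a dense head:

| parameter | default | meaning |
|---|---|---|
| `conv_stages` | (256, 3), (128, 4), (96, 5) | kernels `r_t` and window `h_t` per stage |
| pooling | width 2, stride 2 | fixed; other geometries rejected |
| activation | ReLU | applied after every convolution and dense layer |
| `hidden_sizes` | 512, 256 | fully connected and hidden layer widths |
| `dropout_rate` | 0.2 | on dense-layer activations, training mode only |
| `l2_coefficient` | 10⁻⁴ | on convolution and dense weights (not biases or embeddings) |
| `learning_rate` | 10⁻³ | Adam, with β₁ = 0.9, β₂ = 0.999 |
| `batch_size` / `max_epochs` | 64 / 10 | minibatch SGD schedule |

Stage 1 kernels have shape `k × h₁` (all embedding channels × window);
stages 2 and 3 span all channels of the previous stage (`r_{t−1} × h_t`),
the standard stacked 1-D convolution. Convolutions are "valid" — no
padding — so stage `t` maps length `L` to `L − h_t + 1`; pooling halves
with `floor`, dropping a trailing unpaired element. `layer_length_plan()`
exposes this arithmetic and errors at the first stage whose feature map
cannot be built or pooled. With the defaults the plan is (348, 174),
(171, 85), (81, 40).

The head widths are genuinely open — no reference values exist for them —
so they are surfaced in `venue_cnn_config()` rather than hard-coded. Two
other open choices are handled the same way:

* **Flatten vs. global max pool.** The final representation can either
  flatten stage 3 (96 × 40 = 3840 values, the default) or globally
  max-pool to one value per kernel (`global_max_pool = TRUE`, 96 values).
  Both readings are defensible; flattening preserves positional
  information and is the default.
* **Embedding fine-tuning.** Whether word vectors should be frozen during
  classifier training is unstated in the usual description of such
  systems; the default is trainable (`embedding_trainable = TRUE`), with
  frozen vectors one flag away. Fine-tuning matters most when embeddings
  are randomly initialised, as in the synthetic experiments.

Training minimises the L2-regularised cross-entropy with Adam. Class
imbalance is *not* reweighted by default — the realistic condition is
training on the raw imbalanced corpus — but
`class_weighting = "inverse_frequency"` is available as an extension.

## Numerical choices

* Softmax is computed with max-subtraction and the loss through
  log-sum-exp, so scores of any magnitude stay finite. (At extreme score
  gaps the winning probability rounds to exactly 1.0 in double precision;
  the tests assert strict inequality only at moderate scales.)
* The softmax head is zero-initialised, so the epoch-0 loss on any batch
  is exactly `log T` — a useful built-in sanity check — while hidden
  layers use He initialisation. Gradients of every parameter group,
  including the embedding rows, are verified against central finite
  differences in the test suite (tolerance 10⁻⁵, at a point nudged off
  ReLU kinks, where the loss is legitimately non-differentiable).
* Max-pooling ties take the earlier position; ranking ties take the
  ascending journal label. Both choices make reruns bitwise identical.
* Dropout is inverted (scaled at training time), active only in training
  mode; two inference passes are identical.
* All randomness — initialisation, shuffling, dropout, corpus generation,
  splitting — flows from explicit integer seeds through R's RNG, so a
  fixed seed reproduces corpora, splits, losses and reports exactly under
  single-threaded execution.
* Degenerate inputs fail loudly and early: impossible layer geometries at
  configuration time (naming the stage), non-finite training loss with a
  diagnostic, empty corpora and malformed vector files with specific
  errors.

## Evaluation

`acc@N` is the fraction of test abstracts whose true journal appears in
the first N entries of the ranked list; it is non-decreasing in N and
reaches 1 at N = T. For macro/micro metrics, a top-N selection is treated
as N predicted labels per sample: per class, `tp` counts its members that
include it, `fp` the non-members that include it, `fn` its members that do
not. Macro averages the per-class metrics with equal weight; micro computes
the metrics from the summed counts. Two consequences are worth stating
plainly:

* At N = 1, micro precision = micro recall = micro F1 = accuracy, an
  identity the tests assert on arbitrary fixtures.
* At N > 1 this convention forces micro precision = micro recall / N,
  because every sample contributes exactly N predicted labels. Published
  micro-precision figures at N > 1 that do not satisfy this relation use
  some other (unstated) false-positive convention; we implement and
  document this one and do not attempt to match such figures.

A precision or recall with an empty denominator is defined as 0 and the
affected classes are flagged on the result. Size-stratified accuracy
groups test samples by the size bin of their *true* journal, with bins
taken from the catalog's (training-corpus) paper counts at the 400 / 2000
/ 10,000 boundaries; the bin-weighted mean of per-bin accuracies equals
the overall accuracy by construction, and the tests assert the identity.

## The synthetic corpus

`generate_corpus()` draws each document from a per-class unigram mixture:
with probability `topic_sharpness` a word comes from the class's own
vocabulary (classes have disjoint vocabularies), otherwise from a shared
pool. A unigram mixture, rather than a topic model, keeps the
Bayes-optimal baseline analytic: at sharpness 1 a naive vocabulary-overlap
classifier (`vocab_overlap_classify()`) is perfect, which upper-bounds
what the network should approach. Abstract lengths follow a banded
distribution whose default mirrors the PMC length profile; ISSNs carry
valid check digits so the catalog code paths are realistic, and
`make_fixture_xml()` emits round-trippable JATS files.

`imbalanced_preset()` fixes the imbalanced study condition: six journals
of 150, 150, 600, 600, 2,500 and 10,500 papers — one or more per catalog
size bin at the true bin boundaries — 14,500 documents in total, the
largest corpus a workstation test run should carry.

What the generator does *not* emulate: real biomedical language (topical
overlap between related journals, multi-topic documents, word order and
syntax that convolution windows could exploit), scope drift over time, and
new journals appearing in the test period. Passing the synthetic
experiments therefore demonstrates that the pipeline is correct and that
the network can learn a separable signal through this exact architecture —
not that it reaches any particular accuracy on PMC-scale data.

## Problem sizes in the tests

The package defaults (`m = 350`, `k = 200`, 256/128/96 kernels) describe
the full-scale system and are exercised by the shape and encoding tests.
Training tests use desk-scale configurations chosen once: `k = 24`,
16–24 kernels per stage, hidden sizes 64/32 or 48/32, `m` of 60–120, and
corpora of 200 (capacity), 2,000 (generalization, 20 journals) and 14,500
(imbalance) documents. These sizes make the whole suite run in minutes on
one core while leaving each experiment large enough to be meaningful.

## Limitations

* The trainer is CPU-bound base R; it is built for correctness,
  determinism and desk-scale experiments, not for the 10⁵–10⁶-document
  corpora of the full-scale system.
* The skip-gram trainer is likewise desk-scale; use pretrained vectors
  for real corpora.
* Checkpoints are R serialisations, not a cross-language format.
* The JATS parser extracts the fields this pipeline needs (abstract,
  ISSNs, date, article id); it is not a general JATS toolkit.
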