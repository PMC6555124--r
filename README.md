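# venuecast

**venuecast** recommends publication venues for biomedical abstracts. Given
the abstract of a manuscript, it returns a ranked list of the journals whose
published papers the abstract most resembles — the kind of tool an author
uses to shortlist where to submit, built for the PubMed Central (PMC)
ecosystem where journal labels are NLM-catalog identifiers unifying print
and electronic ISSNs.

It is an R implementation of the full recommendation pipeline:

1. **Corpus ingestion** — parse PMC/JATS XML into paper records
   (`<abstract>`, `<issn>`, `<pub-date>`), map ISSNs to unique journal
   labels, and apply the standard inclusion filters: abstracts of at least
   200 characters, journals with at least 100 papers, publications from
   Jan 2007 to Apr 2017 (all configurable).
2. **Text preparation** — deterministic tokenization, corpus length
   statistics, and encoding of each abstract as a fixed-length sequence of
   `m = 350` token ids (zero padding, tail truncation).
3. **Word embeddings** — word2vec text/binary tables (read and write), a
   skip-gram + hierarchical-softmax trainer (window 5, subsampling
   threshold 10⁻³), and the abstract matrix
   `V = v₁ ⊕ v₂ ⊕ … ⊕ v_m ∈ ℝ^{m×k}` with `k = 200` and the zero vector
   for out-of-vocabulary words.
4. **A three-stage convolutional network** — at stage *t*, `r_t` kernels of
   window `h_t` ((256, 3), (128, 4), (96, 5) by default) slide over the
   sequence ("valid" convolution, feature map length `L − h_t + 1`),
   followed by ReLU and width-2 stride-2 max pooling; with the defaults the
   lengths run 348→174, 171→85, 81→40. The flattened 3840-value feature
   feeds a fully connected (512) and hidden (256) layer with dropout 0.2,
   then a softmax over the `T` journals. Training minimises the
   L2-regularised cross-entropy `−log S_y` with Adam. The forward and
   backward passes are implemented here in base R matrix algebra (im2col
   batching), with gradients verified against finite differences.
5. **Ranking and evaluation** — top-N recommendation lists, top-N accuracy
   (acc@N), macro/micro precision/recall/F1 over top-N selections, and
   accuracy stratified by journal size bin (tiny ≤ 400 < small ≤ 2000 <
   medium ≤ 10,000 < large papers).
6. **A synthetic corpus generator** — journal-labelled abstracts from
   per-class unigram mixtures with controllable topic sharpness, class
   imbalance, and a PMC-like abstract-length profile, so the entire
   pipeline is testable without downloading anything.

## Worked example

A desk-scale run on a synthetic five-journal corpus (the same code works on
records parsed from real JATS XML):

```r
library(venuecast)
library(dplyr)

spec <- synthetic_spec(n_classes = 5, class_sizes = 60, vocab_size = 1500,
                       topic_sharpness = 0.9, seed = 42)
corpus <- generate_corpus(spec)
split <- split_corpus(corpus$records, seed = 42)

cfg <- venue_cnn_config(n_classes = 5, m = 100, k = 24,
                        conv_stages = list(c(24, 3), c(16, 4), c(16, 5)),
                        hidden_sizes = c(64, 32), learning_rate = 3e-3,
                        max_epochs = 25, seed = 42)
model <- split |> filter(split == "train") |> venue_cnn(config = cfg)
model
#> <venue_cnn> 5 classes, 52,125 parameters
#>   trained 25 epochs; final loss 0.0152, accuracy 1.0000

report <- evaluate_model(model, filter(split, split == "test"),
                         catalog = build_journal_catalog(corpus$records),
                         n_values = c(1, 3, 5))
report
#> <venue_eval> 30 samples
#>   acc@1 = 1.000    acc@3 = 1.000    acc@5 = 1.000
#>   stratified by journal size:
#>  size_bin n_papers acc_at_1 acc_at_3 acc_at_5
#>      tiny       30        1        1        1

recommend(model, filter(split, split == "test")$abstract_text[1], n = 3)
#> # A tibble: 3 × 3
#>    rank journal_label probability
#>   <int> <chr>               <dbl>
#> 1     1 NLM00001        1.000e+ 0
#> 2     2 NLM00005        1.58 e-12
#> 3     3 NLM00002        2.92 e-22
```

`acc@N` is the fraction of held-out abstracts whose true journal appears
among the top N recommendations; the per-bin table shows how accuracy
varies with journal size (here all five synthetic journals are "tiny").
`tidy()`, `glance()` and `autoplot()` methods are available for fitted
models and reports, and `?run_cli` documents the command-line interface
(`simulate` / `ingest` / `train` / `evaluate` / `recommend`, wrapped by the
script in `inst/cli/`).

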