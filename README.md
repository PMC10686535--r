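# radrelex

Two-stage entity and relation extraction for radiology reports, in R.

Free-text radiology reports carry most of their clinical content in
unstructured prose. `radrelex` turns them into a structured
representation for downstream reuse (cohort building, quality
measurement, longitudinal tracking). It is aimed at clinical-NLP
researchers and informatics teams who need a trainable, fully
inspectable pipeline rather than a black box.

The system has two trainable stages over a seven-type information model
— concepts (`Observation`, `ClinicalFinding`) and modifiers
(`AnatomicalLocation`, `Certainty`, `Change`, `Characteristics`,
`Size`) — linked by two directed relation types (`Modifier`:
concept → modifier; `Evidence`: observation → clinical finding):

1. **Entity extraction** — a BiLSTM-CRF tagger over IOB2 tags. Per-token
   emission scores from a bidirectional LSTM feed a linear-chain CRF;
   training maximizes the exact sequence log-likelihood
   `score(y) − log Σ_y' exp(score(y'))` via the forward algorithm, and
   prediction is Viterbi decoding.
2. **Relation extraction** — for every admissible entity pair in a
   report (candidates are enumerated at report scope, so relations may
   cross sentences), the token sequence is marked with four typed
   entity-span tokens (`… <OBS> nodule </OBS> … <AE> right upper lobe
   </AE> …`) and classified by an attention-pooled BiLSTM
   (`α = softmax(v·tanh(h_t))`, context `Σ α_t h_t`, logistic output).

Everything around the models is included: BRAT standoff and IOB2 I/O,
regex sentence segmentation with a pluggable tokenizer, a synthetic
annotated-corpus generator (so training and evaluation run with no
external data), strict entity/relation micro-F1, annotation coverage,
Cohen's κ, major/minor mention analysis, and a seeded multi-run
experiment driver. The neural layers (LSTM, CRF, attention) are
implemented in RcppArmadillo with hand-derived gradients; training is
deterministic given a seed.

## Worked example

Generate a 120-report synthetic corpus, split it 0.7/0.1/0.2, train both
stages, and evaluate the three metric tables:

```r
library(radrelex)

corpus <- generate_corpus(generator_config(n_reports = 120, seed = 42))
sp <- split_corpus(corpus, c(0.7, 0.1, 0.2), seed = 42)

ner <- train_ner(sp$train, sp$dev,
                 ner_hyperparams(embedding_dim = 32, hidden_dim = 64,
                                 max_epochs = 6, seed = 1))
rel <- train_rel(sp$train, sp$dev,
                 rel_hyperparams(embedding_dim = 32, hidden_dim = 48,
                                 max_epochs = 8, max_len = 32,
                                 batch_size = 32, seed = 1))

metrics <- evaluate_two_stage(ner, rel, sp$test)
print(metrics$pipeline)
```

```
                        class  tp fp fn precision recall    f1
    Evidence: ClinicalFinding  68  5  4      93.2   94.4  93.8
 Modifier: AnatomicalLocation 115  0  0     100.0  100.0 100.0
          Modifier: Certainty  68  2  1      97.1   98.6  97.8
             Modifier: Change  38  1  3      97.4   92.7  95.0
    Modifier: Characteristics  62  3  2      95.4   96.9  96.1
               Modifier: Size  68  0  0     100.0  100.0 100.0
Microaverage: P 97.4  R 97.7  F1 97.6  (TP 419 FP 11 FN 10)
```

On this run the tagger alone scores 98.8 micro-F1 and the relation
classifier on *gold* entities 99.9; the end-to-end pipeline lands at
97.6 — lower than the gold-entity score because entity mistakes cascade
into the second stage. Applying the trained pair to raw text returns a
schema-valid annotated report, serializable to BRAT or to structured
JSON records (one per concept entity, with nested modifiers and evidence
links):

```r
out <- run_pipeline(sp$test[[1]]$text, ner, rel, id = "example")
str(structure_report(out)[[1]], max.level = 2)
#> List of 8
#>  $ report   : chr "example"
#>  $ id       : chr "T2"
#>  $ type     : chr "Observation"
#>  $ text     : chr "nodule"
#>  $ start    : int 10
#>  $ end      : int 16
#>  $ modifiers:List of 2
#>  $ evidence : list()
```

Annotation coverage over the same corpus (excluding flagged out-of-scope
sentences, then additionally punctuation and stop words):

```r
print(coverage(corpus))
#> Coverage of annotated tokens
#> Entire sequence                      4214/9944 (42.4)
#> Without punctuations and stop words  4214/4312 (97.7)
#> Excluded: 102 sentences, 5632 tokens
```

A thin command-line front end with `generate`, `split`, `train-ner`,
`train-rel`, `predict`, `evaluate`, `coverage` and `experiment`
subcommands is installed at `inst/cli/radrelex.R`.

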