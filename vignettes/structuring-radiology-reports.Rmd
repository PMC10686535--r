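---
title: "Structuring radiology reports: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structuring radiology reports: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiology reports are written as free text, which makes the clinical
information they carry — what was observed, where, how certain the reader
was, how it changed, what diagnosis it supports — hard to reuse at scale.
`radrelex` converts such text into a structured representation in two
stages:

1. **Entity extraction.** A sequence labeler finds mentions of seven
   entity types: two *concept* types (`Observation`, e.g. "nodule", and
   `ClinicalFinding`, e.g. "cancer") and five *modifier* types
   (`AnatomicalLocation`, `Certainty`, `Change`, `Characteristics`,
   `Size`).
2. **Relation extraction.** A binary classifier decides, for every
   admissible ordered entity pair in a report, whether a directed relation
   holds: `Modifier` (concept → modifier) or `Evidence`
   (observation → clinical finding). Enumerating pairs at *report* scope,
   not sentence scope, is what allows evidence links that cross sentence
   boundaries.

Both stages are trainable from a BRAT standoff corpus and evaluated with
strict entity-level and relation-level micro-F1.

## The models

### BiLSTM-CRF tagger

Sentences are tokenized and tagged in IOB2. Each token's embedding is fed
through a single-layer bidirectional LSTM; the concatenated hidden states
are projected to per-tag emission scores, and a linear-chain CRF with
learned transition, start and stop scores defines a distribution over tag
sequences. Training maximizes the exact log-likelihood computed by the
forward algorithm in log space; decoding is Viterbi with ties broken
toward the lowest tag index, which makes predictions deterministic. IOB2
constraints are enforced softly: transitions are learned rather than
masked, and any residual invalid sequence (an `I-` tag with no matching
run head) is repaired at decode time by promoting it to `B-`, the usual
conlleval convention.

The optimizer is minibatch SGD with momentum (defaults: learning rate 0.1,
momentum 0.9, batch size 16, gradient-norm clipping at 5.0) with dropout
0.1 on the encoder input and output vectors, and default dimensions of 100
(embeddings) and 512 (hidden units per direction). The learning rate is
halved after 3 epochs without development-set F1 improvement (floor
`1e-4`), and the checkpoint with the best development F1 is returned.
Unknown tokens share a single UNK embedding trained by randomly replacing
1% of training tokens; out-of-vocabulary tokens at prediction time map to
it. Batches are processed as gradient accumulation over individual
sentences, which is mathematically identical to padded-and-masked batching
and avoids any padding bookkeeping.

### Attention-BiLSTM relation classifier

For each candidate pair, the report's sentences are concatenated in
document order (no separator token — a flagless, minimal reading of
sentence concatenation) and the four typed *entity span markers* (e.g.
`<OBS> … </OBS>`, `<AE> … </AE>`) are inserted immediately around the two
entity token runs. Markers are atomic vocabulary items. The marked
sequence runs through a bidirectional LSTM; attention weights
`softmax(v · tanh(h_t))` pool the hidden states into a context vector,
and a logistic output maps it to the probability that the relation holds.
Candidates at or above a fixed threshold of 0.5 become predicted
relations; the threshold is deliberately not tuned on the development set.

All admissible candidates are used for training — positives are the gold
pairs, negatives every other admissible pair, with no down-sampling. A
`max_len` window (default 256 tokens) bounds the encoded sequence; when a
pair cannot fit, the candidate is logged and scored 0. The window is
centered on the two spans, so a small window acts as a locality prior:
distant pairs — which in practice are negatives — are rejected outright,
and training focuses on the hard, nearby candidates. The relation model
uses a larger-scale uniform initialization (±0.5) for its embeddings and
attention vector than the tagger: with the small-scale init the pooled
classifier's loss surface is near-flat and SGD spends many epochs before
the attention begins to separate classes, which we observed directly on
planted-token probe tasks.

### Numerical choices

* CRF forward/backward and attention softmax are computed in log space /
  with max-subtraction; `-Inf` transition scores are legal and propagate
  correctly, so hard masking is available by configuration.
* Viterbi tie-break: lowest tag index at every backpointer.
* Gradient clipping is by global L2 norm across all parameter blocks.
* All randomness (initialization, shuffling, dropout, token dropout) is
  driven by R's RNG, so a single seed makes an entire training run
  reproducible on one CPU thread.
* Empty sentences, empty reports and entity-free reports are legal inputs
  everywhere and yield empty outputs rather than errors.

## The synthetic corpus

The annotated corpus the models were designed around (in-house CT reports)
cannot be redistributed, so the package ships a generator that emulates
its *structure*, not its language:

* ~12 sentences per report (Poisson, truncated at 3), matching the
  ~12-sentence reports of the emulated corpus;
* observation sentences carrying 0–4 modifier entities with gold
  `Modifier` relations;
* finding sentences whose `Evidence` observation is in the same sentence,
  or — with probability `p_cross_sentence_evidence` (default 0.25, a
  value chosen once as clinically plausible; the emulated corpus does not
  publish this fraction) — the nearest preceding observation in an
  earlier sentence;
* out-of-scope technique/procedure/recommendation sentences with no
  annotations, with probability 0.084 (the emulated corpus excluded 8.4%
  of sentences as out of scope);
* a long-tailed mention vocabulary: curated clinical terms head each
  type's frequency distribution (Zipf, exponent 1.0) and deterministic
  pseudo-terms populate the tail, so corpora of ≥100 reports contain both
  *major* mentions (surface strings seen ≥2 times in training) and
  *minor* ones (≤1), enabling the frequency-stratified error analysis.
  Size mentions are compositional (number + unit), so unseen sizes remain
  recognizable from context — mirroring how size modifiers behave in real
  reports;
* unrelated observation–finding pairs within the same report, so relation
  classification cannot be solved by type constraints alone.

Entities are token-aligned, never cross sentence boundaries, and every
report passes schema validation and a BRAT write/read round trip by
construction.

What the generator does **not** emulate: real report language (word order,
anaphora, negation scope), misspellings and abbreviations, annotation
noise, and mention ambiguity across types. Passing the package's tests
therefore demonstrates that the *pipeline machinery* — tagging, candidate
enumeration, marker encoding, classification, evaluation — is correct and
trainable, not that the models would reach the same scores on clinical
text.

## Benchmark configuration

The package's acceptance benchmark trains on a 650-report synthetic corpus
split 500/50/100 (train/dev/test). To keep the full suite comfortably
runnable on a single CPU, the benchmark uses reduced model sizes chosen
once: the tagger runs with 50-dimensional embeddings and 128 hidden units
for 8 epochs; the relation classifier with 32/48 dimensions, a 32-token
window and 4 epochs (every gold pair in the generated corpora spans fewer
than 29 tokens, so the window never discards a learnable positive). The
directional checks — pipeline F1 below gold-entity relation F1, and
major-mention F1 above minor-mention F1 — run over five seeds at
60 reports each. These problem sizes are the package's benchmark
definition; the defaults users see (`ner_hyperparams()`,
`rel_hyperparams()`) remain the full-size configuration.

## Known limitations

* Word-level features only: no character-level encoder and no subword
  units, so novel surface forms lean entirely on the UNK embedding and
  context. The minor-mention stratum quantifies the cost.
* The tokenizer contract is pluggable but the default is a simple
  alphanumeric/punctuation splitter; Japanese text requires registering a
  morphological analyzer as the tokenizer.
* Evidence candidates are generated in the schema direction only
  (observation → clinical finding); the reverse direction is never
  scored.
* One modifier may legitimately attach to several concepts (the schema
  imposes no uniqueness), and candidate classification is per-pair, so
  mutually exclusive attachments are not arbitrated.
* Term normalization (mapping mentions to a terminology) is out of scope.
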