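---
title: "Extracting adverse drug reactions from patient reviews: model and methods"
author: "adrminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting adverse drug reactions from patient reviews: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrminer)
```

## The problem

Patients describe unwanted effects of their medication in free-text reviews
("a few hours after I experienced shortness of breath, a sense of
depression, cramping, upset stomach"). Pharmacovigilance pipelines want
those *adverse drug reaction* (ADR) mentions as character-offset spans.
`adrminer` treats this as sentence-level sequence labeling: each token gets
a tag from `{O, B-ADR, I-ADR}` (BIO scheme), and maximal `B (I)*` runs are
decoded back into spans.

## The model

The tagger scores a tag sequence $y_1 \dots y_n$ for a sentence
$x_1 \dots x_n$ with a linear-chain conditional random field,

$$
p(y \mid x) = \frac{1}{Z(x)} \prod_{t=1}^{n}
  \exp\!\big(\lambda_{y_{t-1},y_t} + u_t(y_t)\big),
$$

where $\lambda$ is a learned tag-transition matrix (row = from-tag,
column = to-tag), $Z(x)$ is the partition function over all $|Y|^n$
sequences, and the unary score $u_t(\cdot)$ is *not* a linear function of
hand-crafted features but the output of a neural encoder:

1. each token is looked up (lowercased) in a word-embedding table, and
   optionally concatenated with a character-level CNN feature vector
   (embed characters, convolve with filters of several widths, max-pool
   per filter);
2. the sequence of vectors passes through 1–4 stacked bidirectional
   recurrent layers (LSTM or GRU); each layer's output is the
   concatenation of its forward and backward hidden states, and deeper
   layers consume that concatenation;
3. the top layer's output passes through dropout and a dense linear layer
   with $|Y|$ outputs.

Training minimizes the exact negative log-likelihood
$\mathrm{NLL} = \log Z(x) - s(y^{gold})$ by mini-batch Adam (default
parameters, batch size 128); the gradient of $\log Z$ is the vector of
posterior marginals, computed by the forward–backward recursions. Decoding
uses the Viterbi algorithm. A *softmax head* baseline replaces the CRF with
independent per-token cross-entropy and arg-max decoding; it can emit
invalid sequences such as an `I-ADR` after `O`, which the span decoder
repairs (an orphan `I-` opens a span). The structural motivation for the
joint model is exactly those coherence errors: with a CRF the score of a
tag depends on its neighbours, so fragmentary or ill-formed span
predictions are penalized globally.

All CRF computation is carried out in log space with log-sum-exp
stabilization; probabilities are never multiplied. The $t=1$ transition
term, which the product above leaves undefined, is handled by learned
start and stop score vectors (equivalent to a virtual BOS/EOS tag); zero
vectors recover the plain chain. Viterbi ties break toward the lowest tag
index — with `O` first in the tag inventory, an untrained all-zero model
deterministically predicts `O` everywhere.

### Backpropagation

No deep-learning framework is used: the GRU/LSTM cells, the char-CNN, the
dense layer, dropout, Adam, and the full reverse-mode gradients are
implemented directly in base R matrix code (BLAS-backed), with batches
padded to the longest sentence and an explicit length mask so padding
contributes nothing to any score, loss, or gradient. The test suite checks
every configuration (GRU/LSTM × char-CNN on/off × both heads) against
central finite differences, and the CRF recursions against exhaustive path
enumeration.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cell` | `gru` | recurrent unit (GRU merges input/forget gates and exposes its full state; LSTM keeps a separate cell state) |
| `num_layers` | 2 | stacked bidirectional layers (1–4) |
| `hidden_size` | 100 | hidden units per direction |
| `dropout` | 0.5 | applied only to the recurrent output before the dense layer |
| `use_char_cnn` | TRUE | concatenate char-CNN features to word embeddings |
| `char_dim`, `filter_widths`, `filters_per_width` | 25, (2,3,4), 25 | char-CNN geometry: 75-dimensional word feature |
| `head` | `crf` | `crf` (joint) or `softmax` (baseline) |
| `batch_size` | 128 | mini-batch size |
| `max_epochs` | 100 | fixed epoch budget; with a dev corpus the best-epoch parameters are returned (no patience-based early stopping) |
| `lr` | 0.001 | Adam learning rate (other Adam parameters at their defaults) |
| `seed` | 1 | controls parameter init, OOV embedding draws, dropout and shuffling |

Hidden sizes and char-CNN geometry are community-standard values for this
architecture family; they are deliberately configurable because none of
them is forced by the task. Words are lowercased for embedding lookup but
the char-CNN sees the original casing, so shape information survives.

Word embeddings arrive in word2vec text format. Vocabulary words missing
from the file are initialized i.i.d. uniform on the `[min, max]` range of
the loaded weights — the standard recipe when a pretrained table covers
most but not all of the vocabulary (typically ~97% in this domain).

## Corpus handling

* **brat standoff**: `T<id>  LABEL start end  text` records; 0-based
  half-open character offsets everywhere. Discontinuous annotations
  (`start end;start end`) are collapsed to their minimal covering interval
  before resolution, consistent with keeping the longest continuous span.
  If a record's quoted text disagrees with the document substring, the
  offsets win and a warning is raised.
* **Overlap resolution**: transitively overlapping ADR spans are replaced
  by the union interval of their group — one annotation covering the
  longest continuous stretch. Strictly touching spans (`end == start`) are
  not merged. The operation is idempotent.
* **Tokenization** is unspecified by the annotation format, so the package
  uses a rule-based tokenizer (whitespace split, then peel leading/trailing
  punctuation) and a punctuation-based sentence splitter, both
  offset-true: evaluation always happens in original-document coordinates.
  A token belongs to a span if their character intervals intersect at all,
  which maximizes agreement with offset-level annotations when boundaries
  fall mid-token.
* **Splits** are document-level (never sentence-level), deterministic
  given a seed: 1250 documents at 70% give 875 training and 375 test
  documents.

## Evaluation

*Exact* mode follows the CoNLL convention: a predicted span counts only if
its boundaries and label match a gold span exactly, with counts pooled
over the corpus (a per-sentence macro variant is available behind
`macro_exact`). *Partial* mode credits token overlap per intersecting
(gold, predicted) pair — precision normalizes by predicted-term length,
recall by gold-term length — computed per sentence and averaged over
sentences; F1 is the harmonic mean of the averaged P and R. Two
conventions required decisions the metric definitions leave open:

* a sentence with neither gold nor predicted terms contributes (1, 1) by
  default (a perfectly handled sentence should not drag the macro average
  down); `empty_sentence = "skip"` drops such sentences instead;
* one-sided 0/0 ratios (gold but no prediction, or vice versa) are
  excluded from the corresponding average, and the other side contributes
  0;
* a predicted term intersecting several gold terms sums its overlap
  credits but is capped at 1, so precision cannot exceed 1.

## The synthetic corpus

Real ADR corpora are licensed, so the package generates its own:
sentences are drawn from carrier templates with `{ADR}` slots
("i experienced {ADR} and {ADR} after two days"); each slot receives, with
probability `p_adr_per_slot` (default 0.7), a phrase from a ~60-entry
lexicon of real patient-reported reaction surface forms (1–4 tokens:
"headaches", "weight gain", "shortness of breath", "ringing in my ears"),
recorded as a gold span with exact offsets, and a neutral filler phrase
otherwise. With probability `transition_noise_rate` a carrier token is
replaced by a single-token lexicon word *used in a non-ADR sense* and left
unannotated — this makes the task genuinely contextual: a pure lexicon
lookup reaches recall 1 but precision < 1 (a property the test suite
asserts). `inject_overlaps()` adds raw overlapping duplicates of gold
spans (sub-spans or one-token extensions) and records the intended
post-resolution span set, so the overlap resolver can be checked against
generator-known truth. The emitted toy embedding file covers ~97% of the
generated vocabulary, mirroring the partial-coverage regime of real
pretrained embeddings.

The generator emulates the *statistical* structure the tagger relies on —
multi-token spans, realistic B/I transition statistics, contextual
ambiguity, 0–4 mentions per sentence — and deliberately nothing else: no
grammar, no misspellings, no negation scope, no discontinuous mentions.
Passing tests on this corpus demonstrate that the architecture, the
objective, and the decoding are implemented correctly and can recover a
known annotation process; they do not certify performance on real
clinical or social-media text.

### Reference study conditions

The package's reference experiment trains the 2-layer GRU + char-CNN + CRF
tagger on the default corpus: 250 documents × 10 sentences = 2500
sentences, document-split 80/20 into 2000 training and 500 held-out
sentences (generator seed 13). Ten epochs suffice for held-out exact F1
≥ 0.90. The head-to-head CRF-vs-softmax comparison uses a harder,
deliberately scaled-down setting where neither model saturates: 100
documents with `transition_noise_rate = 0.35` (700/300 sentences at a 0.7
split), a 1-layer GRU with 40 hidden units, no char-CNN, 25 epochs, 10
seeds. In that regime both heads reach mid-range F1 and the CRF head's
exact F1 matched or beat the softmax head's in every seed we ran — the
structured decoder's advantage is largest exactly while span coherence is
not yet learned. These sizes were chosen once as the package's reference
conditions so the whole experiment reruns in minutes on one CPU.

## Demographic term mining

Given per-review extracted terms and author metadata, a term is reported
for a demographic group when it occurs in **more than four** reviews of
that group (each review counted once per term) and its exact normalized
form (lowercase, collapsed whitespace — no stemming) never occurs in a
review carrying a different tag of the same dimension. The "all authors"
row applies the threshold without the exclusivity filter. Decisions the
rule leaves open: counting is review-level by default (configurable to raw
occurrences), and reviews whose tag is `"unknown"` are dropped from that
grouping dimension rather than treated as a competing tag.

## Numerical choices and degenerate inputs

* log-sum-exp guards all partition/marginal computation; `-Inf`
  transition scores (decoding constraints) are legal and propagate
  correctly, but an all-infeasible constraint set raises an error;
* Viterbi and arg-max tie-breaks are "lowest index wins", making every
  decode deterministic;
* empty sentences cannot be encoded (error); empty span sets, empty
  corpora and empty annotation files are legal and produce empty outputs;
* sequences of length 1 take the start + unary + stop path with no
  transition term;
* words longer than `max_word_length` (20) are truncated for the
  char-CNN; words shorter than the widest filter are zero-padded;
* unknown words map to `"<unk>"` (always present in the vocabulary),
  unknown characters to the `"<unk>"` character.

## Known limitations

* Single entity type (ADR). Corpora with additional types are filtered.
* The recurrent stack concatenates directional states between layers; the
  alternative (summing) is not implemented.
* No semi-Markov or higher-order CRF, no n-best decoding.
* The normalization subtask (mapping extracted mentions to a controlled
  vocabulary) is out of scope.
* Training is single-threaded R; the reference experiments are sized for
  minutes-scale runs, not for corpus-scale hyperparameter sweeps.
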