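---
title: "Extracting drug-drug interactions with Gaussian-noise-augmented neural models"
author: "ddigauss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting drug-drug interactions with Gaussian-noise-augmented neural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task

A drug-drug interaction (DDI) is a change in one drug's effect caused by
co-administration of another. Sentence-level DDI extraction is a relation
classification task: given a sentence with annotated drug mentions, decide
for each pair of mentions whether they interact and, if so, how. The standard
benchmark annotation scheme distinguishes four positive classes —
*mechanism* (a pharmacokinetic process is described), *effect* (an outcome is
described), *advice* (a recommendation is given), *int* (an interaction is
asserted without detail) — plus the *negative* class for co-occurring but
non-interacting pairs. `ddigauss` implements two neural classifiers for this
task together with the full corpus-to-score pipeline, and a synthetic-corpus
generator so that everything is exercisable offline.

## Corpus representation

Input corpora use the SemEval-2013 Task 9 XML dialect:
`document` > `sentence[text]` > `entity[charOffset, type]` and
`pair[e1, e2, ddi, type]` elements. Two conventions of that dialect matter
numerically and are preserved internally:

* **Inclusive character offsets.** `charOffset="0-11"` covers twelve
  characters. All validation and slicing uses inclusive ends.
* **Discontinuous mentions.** A `charOffset` may contain several
  `;`-separated spans; the surface form joins the span fragments with a
  single space. Downstream anchoring uses the first span — the annotation
  gives no guidance on how models should treat the remainder, so the extra
  spans stay in the text as context.

Entity types outside `{drug, brand, group, drug_n}` are accepted with a
warning and mapped to `drug_n`; unknown XML attributes ride along in an
`attrs` list so that `write_ddi_xml(read_ddi_xml(f))` is an identity.

## Candidate generation and negative filtering

A sentence with $n$ drug mentions yields $\binom{n}{2} = n(n-1)/2$ candidate
instances, one per unordered pair in offset order. In each candidate the
earlier target mention is marked `DRUG1`, the later `DRUG2`, and every other
drug `DRUGN`, so the classifier generalizes over drug identities. Two
anonymization styles are supported, because both exist in practice: the
default `"tag"` style keeps the surface form and appends the role symbol
after it (matching the worked corpus examples the test suite checks), while
`"replace"` substitutes the symbol for the mention. Both satisfy the same
anchor invariants (`tokens[p1] == "DRUG1"`, `p1 < p2`) and the choice is a
single argument to `generate_candidates()`.

Two classic rules flag likely-false negatives:

1. **Same drug** — the two target surfaces are identical after case folding,
   or fall in the same user-supplied synonym group.
2. **Coordination** — every token strictly between the two target mention
   blocks is a comma, `and`/`or`, or part of another drug mention, i.e. the
   pair sits in a pure enumeration list.

`filter_negatives()` only *flags*; removal happens in `training_instances()`
and touches only negative-labeled instances, so a gold positive can never be
lost. Whether flagged instances are also bypassed at evaluation time (and
auto-predicted negative) is a switch (`filtered_as_negative` in
`mcpcnn_predict()`), off by default: the published systems do not state their
test-time behavior, so both modes are available and the conservative one is
the default.

Tokenization is a deterministic whitespace split after isolating the
punctuation characters `. , ; : ( ) " /`. The fixed-length limit of 150 is
interpreted in **tokens**, not characters: every model quantity (windows,
position indices, padding with embedding row zero) is defined on token
sequences, and padding "with 0" only makes sense for embedding indices.
Truncation keeps the smallest window containing both anchors, extended
symmetrically — anchors are mandatory for piecewise pooling, so any
truncation that loses one is an error, reported as such.

## Model 1: multichannel piecewise CNN

Each token $i$ is represented per channel as
$x_i = w_i \oplus p^{(1)}_i \oplus p^{(2)}_i$: a $k$-dimensional word vector
(default $k = 200$) concatenated with two learned position embeddings
indexed by the clipped signed distances to the two anchors. Up to five
embedding channels — word-vector tables trained on different corpora —
are stacked like the RGB planes of an image; one convolution filter spans
all channels jointly. For a window size $h$, filter $(w, b)$ and
nonlinearity $f = \tanh$,

$$c_i = f(w \ast x_{i:i+h-1} + b), \qquad c \in \mathbb{R}^{n-h+1},$$

with the reference geometry $h \in \{3, 5, 7, 9\}$ and 128 filters per size.
Global max-over-time pooling $\hat c = \max[c]$ discards where a feature
fired; piecewise max pooling instead splits each feature map at the two
anchor coordinates — left of the first entity, between the entities, right
of the second — and takes one maximum per segment, preserving the coarse
sentence structure. A window starting at token $i$ belongs to segment 1 iff
$i \le p_1$, segment 2 iff $p_1 < i \le p_2$, and segment 3 otherwise; an
empty segment contributes the 0 sentinel so the pooled vector $z$ always has
length $3 \times$ (number of filters). Ties inside a segment resolve to the
first position, which makes gradients and reproducibility exact.

**Attention.** The architecture includes an input-level attention mechanism
that reweights tokens before convolution. No published equations accompany
it, so this package uses the standard additive form
$s_i = v^\top \tanh(W x_i)$, $\alpha = \mathrm{softmax}(s)$ masked over
padding, with rows scaled by $\alpha_i \cdot n$ so that the uniform
initialization is approximately the identity. This is a documented stand-in;
it can be disabled with `attention = FALSE`.

**Gaussian noise.** The data-augmentation layer adds
$w'_j = w_j + x_j$ with $x_j$ drawn from a centered normal. Two schemes are
implemented because both are described for these models:

* *embedding site*: each element is selected with probability 0.3 and
  perturbed by a draw from $\mathcal N(0, \sigma)$ truncated to $[0, 0.3]$ —
  small, positive nudges that keep the word vector near its neighborhood;
* *pre-classifier site* (the default): plain $\mathcal N(0, \sigma)$ on the
  pooled feature vector just before the softmax, with $\sigma = 0.1$ for
  this model and $\sigma = 0.3$ for the encoder-based one — the values that
  performed best in the reference experiments' $\sigma$ sweep.

The layer is active only in training passes; with $\sigma = 0$ (or element
probability 0) it consumes no randomness at all, so a seeded training run
with the layer "at zero" is bit-identical to one without the layer — the
property the noise-neutrality tests assert. `truncnorm_moments()` provides
the closed-form mean and variance of the truncated draw used to validate the
sampler.

**Classifier.** Dropout (default rate 0.45, inverted so expectation is
preserved) followed by an affine map to $K = 5$ classes and a softmax:
$o = z_d W_s + d$. With zero weights the output is exactly uniform (0.2 per
class).

**Training.** Adam on the mean cross-entropy, default learning rate
$3 \times 10^{-4}$ (the reference settings list this value; a ten-times
larger one also appears in the accompanying prose, and is one config key
away), batch size 64, up to 100 epochs with early stopping on validation
micro-F1 (patience 10, ties to the earliest epoch). All gradients are
derived by hand and checked against finite differences in development; the
batched training path is asserted equal to the single-instance forward pass
in the test suite. Word-embedding channels stay frozen during training;
position tables, attention, filters and the classifier are trained. Batches
are bucketed by sentence length (padding rows are never materialized beyond
the longest real sentence in a batch plus one window), which changes nothing
numerically per batch and roughly halves the epoch cost.

## Model 2: entity-marker relation head

The second model wraps a bidirectional sequence encoder. The input is the
unanonymized sentence with control tokens:
`[CLS] c0 $ e1 $ c1 # e2 # c2 [SEP] [PAD]…`. Distinct markers for the two
entities (`$` and `#`) are used — the published description prints only
`#`, but identical markers cannot disambiguate the pair, so distinct
(configurable) markers are the default. The two entities partition the
sentence into five parts: the entity spans and three contexts $c_0, c_1,
c_2$. An entity positional encoding (1 on the first entity's tokens, 2 on
the second's, 0 elsewhere) is added to the encoder's input embedding
pathway and fine-tuned with everything else.

The head pools each selected part (`average`, `max`, `self_attention`, or
`start` pooling; empty context spans pool to zero), passes each pooled
vector through a learned affine+tanh projection, concatenates them into a
fixed-length relation representation $h_r$ — whose length depends only on
the head configuration, never on sentence length — optionally appends an
entity interaction block (elementwise product or absolute difference), and
classifies through Gaussian noise ($\sigma = 0.3$), dropout 0.1 and a
softmax. The default feature set is `[CLS]` (start pooling) plus the two
entities (average pooling), contexts off and no interaction: the reference
description singles out the entity average explicitly, and is silent about
the rest, so the defaults follow the explicit part.

The encoder is an *interface*: any `function(tokens, entity_pos_ids)`
returning one hidden row per token plugs in. The package ships
`tiny_encoder()`, a seeded two-layer single-head self-attention encoder
(d = 16, tanh feed-forward, residual connections, no layer
normalization — at this width it is unnecessary and its omission keeps the
backward pass compact). It exists so the head's mathematics can be
exercised and trained end-to-end on a CPU in seconds; loading real
pretrained biomedical transformer weights is an optional path outside the
test surface, since those weights are external artifacts requiring GPU
fine-tuning.

## Evaluation

`evaluate_predictions()` computes one-vs-rest precision/recall/F1 per class
and micro-averaged metrics pooling TP/FP/FN **over the four positive classes
only** — the DDI challenge's detection-and-classification convention, in
which predicting `negative` everywhere scores zero. Published summaries of
these models do not state whether the negative class was pooled, so an
all-class micro variant and macro averages are also returned; the
positive-class micro-F1 is the headline number everywhere in this package.
F1 uses the 0/0 → 0 convention. The 5×5 confusion matrix (fixed class order
`negative, mechanism, effect, advice, int`) and its row-normalized
proportions support the usual error analysis, and `write_eval_report()`
emits JSON plus a TSV confusion matrix.

Validation splitting is at the **sentence** level (10% by default): all
candidates of a sentence land on one side, so no sentence leaks between
training and validation.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the models rely on,
with no external data:

* each positive sentence embeds exactly one class-specific trigger template
  around its target pair (e.g. *"the half-life of X was prolonged in the
  presence of Y"* for mechanism, *"X should not be administered to patients
  receiving Y"* for advice); negatives use distractor predicates or pure
  coordination lists;
* with probability `p_coordination` a comma/conjunction drug list is
  inserted (fodder for filter rule 2) and with `p_duplicate_name` a mention
  repeating the first target's surface is appended (fodder for rule 1);
  every such constructed pair is recorded in the generator's ledger, which
  is the ground truth all stochastic tests compare against;
* drug names are pronounceable consonant-vowel strings, not a real lexicon;
* `generate_channel_embeddings()` draws Gaussian word vectors and adds a
  shared class-offset direction (with per-channel jitter) to each class's
  trigger words, making the classes linearly separable by construction.

Defaults: balanced class proportions (0.2 each), 2–4 drugs per sentence,
`p_coordination = 0.25`, `p_duplicate_name = 0.05`, vocabulary 300. These
are deliberate simplifications: real DDI corpora are heavily imbalanced
(negatives dominate by an order of magnitude), sentences are longer and
noisier, trigger vocabulary is not disjoint across classes, and entity
mentions can nest. A model that recovers the synthetic classes has
demonstrated that the architecture, gradients and pipeline are correct —
not that it reaches any particular score on real corpora.

## Problem sizes in the test suite

The parameter-recovery tests train the full-geometry CNN (five k = 200
channels, 128 filters per window size) on a 2,000-sentence generated corpus
with a 10% sentence-level validation split, asserting validation micro-F1
≥ 0.9 within 3 epochs, and the relation head with the tiny encoder on a
200-sentence two-drug toy set within 30 epochs. Unit and property tests use
corpora of 2–50 documents and reduced embedding widths; the pooling and
scoring oracles run 1,000 and 200 random cases respectively, and the noise
sampler is checked against the closed-form truncated-normal moments on
$10^5$ draws.

## Known limitations

* The attention form and the entity-marker scheme are documented stand-ins
  for under-specified parts of the architectures they reproduce.
* Nested or overlapping entity pairs are flagged (`same_drug`) rather than
  modeled; discontinuous mentions anchor at their first span.
* The word2vec reader handles the text format only; binary embeddings
  should be converted externally.
* Training is single-threaded CPU linear algebra; it is sized for
  thousands of sentences, not millions.
* Reproducing published scores on the licensed DDI benchmark requires the
  real corpus, pretrained biomedical embeddings/encoder weights and GPU
  fine-tuning, all outside this package's scope.
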