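---
title: "Sentence-graph pointer networks for relation extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentence-graph pointer networks for relation extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the model

`gpnre` implements sentence-level biomedical relation extraction: given a
sentence in which two entity mentions are marked (`@mention#`), predict which
relation, if any, holds between them. The canonical instantiation is
chemical–protein interaction classification over the CHEMPROT label scheme,
where five relation groups (CPR:3 up-regulation, CPR:4 down-regulation,
CPR:5 agonism, CPR:6 antagonism, CPR:9 substrate/product) are evaluated as
positive classes and everything else — the five non-evaluated groups and
unannotated pairs — collapses to `False`. A two-label scheme covers binary
tasks such as gene–disease association.

The architecture combines three token-level feature streams:

1. **Contextual features** `X`: one vector per word-piece from a token
   encoder (a pre-trained transformer in production settings; the package
   ships a trainable toy encoder and a precomputed-vector backend).
2. **Local graph features** `X̂`: a one-hop graph convolution over the
   *sentence graph*, the undirected graph whose nodes are word-pieces, with
   an edge between the first pieces of two dependency-linked words and
   between consecutive pieces of one word. With adjacency `A` (symmetric,
   zero diagonal) and degrees `d`, the propagation is
   `X̂ = σ(D^{-1/2} A D^{-1/2} X W)`; degree-0 factors are clamped to 1.
3. **Multi-hop pointer features** `Z`: for every node, an ordered
   breadth-first sample of up to `L` neighbors within `k` hops
   (hop-by-hop, random order within a hop) is encoded by a recurrent
   encoder `e_t = cell(W[e_{t-1}, x̂_{n_t}])`; a recurrent decoder started
   from a trainable sentinel scores all `L` positions with pointer
   attention `softmax(vᵀ tanh(W₁ e_q + W₂ d_p))` and greedily selects `M`
   distinct positions; the selected vectors pass through a same-padded 1-D
   convolution and are reduced (element-wise max by default) into one
   vector per center node.

A fused per-token representation `ReLU(W_f [X | X̂ | Z])` is zero-padded to
`max_len` tokens, flattened in token order, mapped to a sentence vector and
classified by softmax. Training minimizes cross-entropy with AdamW under a
linear warmup/decay schedule; the best development-set micro-F1 epoch is
retained.

## Design choices where the design was open

* **Graph details.** No self-loops are added (self-information re-enters
  through the `X` stream of the fusion); entity markers are attached to
  their mention's token rather than becoming nodes; punctuation nodes are
  kept; dependency relation labels are ignored by construction. Parses that
  fail validation (cycles, multiple roots) or whose words disagree with the
  sentence tokenization are dropped with a logged reason, never guessed.
* **Sampler.** Hop depth `k` defaults to 2: with the default cap `L = 32`,
  two-hop neighborhoods of typical sentence graphs are almost always fully
  sampled (the `two_hop_coverage()` diagnostic measures exactly this), so
  deeper sampling mostly adds padding. Sequences shorter than `L` are padded
  with a zero-vector sentinel and masked out of the encoder; BFS order
  guarantees lower hops are exhausted before the cap truncates. Sampling is
  re-drawn each training epoch (a mild regularizer) from counter-based
  per-(seed, sentence, node) streams, and fixed at inference, so every run
  is reproducible and independent of iteration order.
* **Recurrent cells.** The pointer encoder/decoder uses LSTM cells by
  default; a `cell = "tanh"` mode implements the bare
  `tanh(W[state, input])` recurrence instead, which is the form the
  hand-checkable unit tests pin down.
* **Hard selection with straight-through gradients.** Selection is hard
  argmax over the masked attention row (pad slots and already-selected
  positions are excluded, making the `M` choices distinct). The forward
  value is the selected vector; the backward pass adds the gradient of the
  attention-weighted mixture of the sequence, so both the gathered
  representations and the attention weights receive gradient despite the
  discrete choice. If every position is exhausted before `M` picks, the
  remaining slots are the zero sentinel.
* **Aggregation.** The convolution is width-3 and same-padded by default
  with a shared kernel across center nodes, followed by element-wise max
  over the `M` positions; width and reduction (max/mean) are configurable
  because no canonical choice exists.
* **Sentence representation.** The fused tokens are flattened (stacked in
  the token dimension) and affinely mapped; flattening keeps position
  information, which the classifier needs to localize the marked pair.
* **Evaluation.** Micro precision/recall/F1 sum TP/FP/FN over the positive
  classes only; the negative label contributes false positives and false
  negatives but its diagonal cell is never a true positive. This is the
  only reading under which published CHEMPROT confusion matrices reproduce
  their printed micro scores, and the package verifies that arithmetic in
  its test suite. Percentages are rounded to 2 decimals at report
  boundaries only.

## The synthetic corpus: what it emulates and what it does not

Real corpora for this task cannot be redistributed inside a package, and a
pre-trained encoder cannot run here, so the generator builds a corpus in
which the *topological* signal the architecture targets is planted by
construction:

* Sentences are random-attachment dependency trees of 9–14 words over a
  small vocabulary; about 30% of filler words split into two word-pieces,
  exercising the alignment and first-piece wiring rules. Each instance
  marks one chemical-like and one protein-like mention whose tree path is
  a planted 4-edge backbone.
* The gold label is a deterministic topological rule: a trigger word is
  decisive when it hangs within one hop of the *interior* of the
  dependency path joining the two entities; the decisive trigger nearest
  the path interior names the class, and with none the instance is
  negative. Every sentence carries exactly one trigger of each class,
  both at least 4 positions from both entities in the linear order;
  in a positive instance one of them (chosen at random) attaches under
  the middle of the backbone and the other ≥ 3 hops off the path, while
  in a negative instance both sit off-path. The token multiset and the
  linear placement of the triggers are therefore identically distributed
  across the classes — a bag-of-tokens classifier (provided as
  `bow_baseline()`) and purely sequential position cues carry no label
  information; only the tree topology does. Crucially, path membership is
  not a one-hop property: no single node's immediate neighborhood reveals
  whether it lies between the marked entities, so the one-hop GCN stream
  alone cannot express the rule, while a 2-hop pointer ball centered on
  an interior node contains both entity markers and the trigger at once.
  This is what makes the `Z`-ablation comparison informative.
* Labels are then flipped to a different class with probability
  `noise = 0.05`, so Bayes-optimal accuracy is exactly `1 - noise = 0.95`.

The corpus emulates the *shape* of the task (trees, subwords, marked pairs,
a topology-dependent label) and deliberately not the lexical statistics,
class imbalance, annotation noise structure or sentence lengths of real
biomedical text. Passing the end-to-end test shows the architecture learns
a graph-topological decision rule end to end; it does not certify CHEMPROT
performance, which requires the external corpus and a fine-tuned
pre-trained encoder.

## Problem sizes and numerical choices

The shipped end-to-end experiment trains on a 2000-instance corpus
(1400/300/300 train/dev/test split) with the toy encoder at `d1 = 16`,
GPNN `L = 8`, `M = 2`, one layer, 10 epochs of AdamW (peak learning rate
2e-3, batch 16, warmup proportion 0.1, classifier dropout 0), the
mean-pooling sentence mode (selected on the development split; the
position-aware flatten needs more data to generalize on this corpus), and
5 fixed sampling draws averaged at prediction time — sizes chosen so the
whole pipeline trains on one CPU in a few minutes while leaving the
planted signal learnable. The same settings back the Z-ablation comparison
(`ablate_gpnn = TRUE` forces the pointer stream to zero while keeping `X`
and `X̂`), which isolates the contribution of multi-hop pointer selection
on the graph-near/sequence-far configuration.

Numerical details: Glorot-uniform initialization; attention masking by
additive `-1e9` before the softmax; softmax rows renormalize over the
unmasked positions by construction; degree clamping avoids division by
zero for isolated nodes; cross-entropy clamps probabilities at `1e-12`;
all randomness (initialization, shuffling, sampling, simulation) derives
from explicit integer seeds kept below 2^31.

## Known limitations

* The `@`/`#` marker characters are literal and unescaped in the TSV
  dialect; sentences containing them as ordinary characters are rejected.
* Self-pairs (an entity paired with its own duplicate mention) are
  excluded during pair expansion.
* Sentences longer than `max_len` word-pieces are right-truncated only
  when both mentions survive, otherwise rejected; truncation operates on
  the piece graph and can disconnect it (the sampler tolerates forests).
* The pre-trained-transformer path is consumed through the
  `precomputed_encoder()` vector interface; no transformer runs
  in-process.
* Tenfold cross-validation (`gpnre_cv()`) follows the
  merge-train-dev/refit-per-fold/fixed-test protocol but is only exercised
  at toy scale in the test suite.
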