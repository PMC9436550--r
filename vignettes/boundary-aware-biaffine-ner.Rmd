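---
title: "Boundary-supervised biaffine recognition of nested entities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-supervised biaffine recognition of nested entities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open when building it, and what the test
suite does and does not establish.

## The task and the model

Nested named-entity recognition must return typed spans that may contain
one another — "colon" (an anatomical entity) inside "colon cancer" (a
disease) — which rules out plain BIO sequence tagging. The package takes
the span-enumeration view: every interval `(i, j)` with `i ≤ j` of an
`N`-token sentence is a classification instance over `C + 1` classes
(the entity types plus non-entity).

The pipeline is:

1. **Embedding.** `X_t = [X_t^lm ; X_t^char ; X_t^word]`: an optional
   frozen contextual block (interface only — the package never trains a
   language model), a character CNN (one 1-D convolution per filter
   width, max-pooled, concatenated), and a word-vector lookup that can be
   seeded from a pretrained text-format vector file. A disabled block is
   omitted, not zero-filled, so downstream widths always reflect the
   active configuration.
2. **Shared encoder.** A stacked BiLSTM produces `h_t`; two independent
   one-layer MLPs (affine + ReLU) produce the head and tail
   representations `s(t)`, `e(t)`. These are *shared* between the two
   tasks — that sharing is the mechanism by which boundary supervision
   improves span classification.
3. **Span classification.** The biaffine form
   `r_m(i,j) = s(i)ᵀU₁e(j) + U₂[s(i)⊕e(j)] + b` scores every enumerated
   span for every class; softmax cross-entropy over spans gives `loss_b`.
4. **Boundary detection.** Per token,
   `O_t = U·ReLU([s(t), e(t)]) + b`, `d(t) = softmax(O_t)` over the fixed
   class order (O, I); cross-entropy against gold labels gives `loss_d`.
5. **Joint objective.** `Multi_Loss = loss_b + α·loss_d`. Training
   targets use *gold* boundary labels; at decoding time the *predicted*
   `P(I)` gates candidates (teacher forcing for the auxiliary task).
6. **Decoding.** Per-span argmax, discard non-entity, gate (both
   endpoints need `P(I) ≥` threshold), then a greedy sweep in descending
   score order that rejects any candidate *crossing* a kept one. Two
   spans cross iff one starts strictly inside the other and ends strictly
   beyond it; containment and disjointness never block, so nesting
   survives by construction.

## Parameters that matter

Reference defaults (`model_config()`): BiLSTM width 200 in 3 layers with
dropout 0.4; MLP width 150 with dropout 0.2; character embeddings of
width 50 under filters of widths 3–5; word vectors of width 300; dropout
0.5 on the concatenated embedding; Adam at learning rate 0.001. These are
the published operating point of this model family on GPU-scale
benchmark corpora and are kept verbatim as defaults.

Choices the reference setting leaves open, fixed here:

- **α (mixing ratio):** default 1. No value is published; 1 treats the
  two losses symmetrically, and `run_ablation()` sweeps it — `α = 0`
  with gating off is bit-for-bit the single-task baseline (a tested
  invariant).
- **Batch size 16, early stopping on held-out F1 with patience 5:**
  unpublished; ordinary small-corpus practice.
- **CharCNN filters per width: 50** (so the character block is 150 wide),
  configurable.
- **Maximum span length `L`:** unbounded for sentences up to 64 tokens,
  else 16, because enumeration is `O(N²)`; gold mentions longer than `L`
  are excluded from the loss with a warning.
- **`small_model_config()`:** one BiLSTM layer of width 64, MLP 32,
  32-wide trainable word embeddings, character CNN off, lighter dropout
  (0.2 embedding / 0.1 MLP). This is the package's CPU-scale operating
  point for synthetic experiments, where the type signal is word-level by
  construction and character features are redundant.

## Interpretation decisions

Three points in the model's published description are ambiguous or
internally inconsistent; the package resolves them as follows and keeps
the literal readings as flags.

- **Softmax on the projections.** The head/tail formulation wraps the
  MLP outputs in a softmax, yet the same vectors serve as the span
  *representations* fed to the biaffine layer; normalizing a 150-wide
  representation to the simplex would destroy most of its information.
  Default: the pre-softmax activations are the representations, and the
  per-token softmaxes are exposed as auxiliary begin/end predictor
  outputs. `span_repr = "post_softmax"` restores the literal reading.
- **ReLU in the boundary head.** The boundary equation is affine, but
  the accompanying description inserts a ReLU. Default: ReLU on the
  concatenated input before the linear map
  (`boundary_activation = "none"` for the plain affine form).
- **Loss reduction.** The written objectives sum over spans/tokens; the
  package averages so that `α` has a length-independent meaning across
  batches (`loss_reduction = "sum"` restores the literal form).

Other resolved points: the span loss sums over *spans* ("each valid
interval"), not tokens; `s, e` in the boundary head means the per-token
concatenation `[s(t), e(t)]` (the per-token output forces this reading);
bias augmentation appends a constant-1 coordinate to `s` and `e` inside
the bilinear term, standard biaffine practice that lets `U₁` absorb
head-only and tail-only interactions (`bias_aug = FALSE` for the strict
bilinear form); the crossing predicate is applied symmetrically in both
orders, and a shared endpoint with partial overlap
(`s_i < s_j = e_i < e_j`) *blocks*, while boundary-sharing containment
does not; sort ties in decoding break by (score desc, start, end, label)
for determinism; gold-boundary gating during training affects decoding
only — the span loss still covers all enumerated spans, with
`train_gate = "loss"` available to restrict it; boundary labels default
to IO tagging over the union of mention intervals (`"inside"`), with
`"endpoints"` marking mention starts/ends instead. Tokenization is taken
as given: corpora arrive pre-tokenized and no sub-word handling is
attempted.

## The synthetic generator

Real nested corpora are licensed and GPU-sized, so the test bed is a
generator (`synth_config()`, `generate_corpus()`) whose corpora are
*decodable by construction*: each mention opens with a trigger token of
its type, its remaining tokens come from a type-specific content
vocabulary, a nested child uses a *different* type (disjoint trigger and
content vocabularies; a same-type child would make its right boundary
surface-ambiguous), and filler tokens outside mentions come from a
separate vocabulary. A word-level model can therefore reach near-perfect
F1, which is the point: end-to-end tests measure the architecture and the
optimization, not world knowledge.

Generation walks each sentence left to right, opening a top-level
mention with probability `p_mention` at any position with enough room,
and decides nesting by an independent `p_nest` coin per mention
(recursing to depth `D`). Eligibility always leaves room for a child, so
the fraction of top-level mentions with a child is an unbiased Bernoulli
estimate of `p_nest` — a property the suite checks at three standard
errors, alongside determinism under the seed and the absence of crossing
mentions.

What the generator does **not** emulate: realistic token frequency
distributions (GENIA-like Zipf tails), out-of-vocabulary effects,
boundary ambiguity, annotation noise, crossing or discontinuous
mentions, and mentions whose type is only resolvable from context.
Passing the synthetic bar therefore shows the implementation learns and
decodes correctly; it does not predict benchmark scores on real corpora.

## Numerical and engineering choices

The neural core (character CNN, BiLSTM, projections, biaffine scorer,
boundary head, and full reverse-mode gradients) is hand-written in
RcppArmadillo; the analytic gradients are validated against central
finite differences in the test suite (tolerance 1e-3 at step 1e-5,
including every parameter group). Further choices:

- Glorot-uniform weight initialization, zero biases except LSTM forget
  gates at 1; embeddings drawn uniform on (−0.1, 0.1).
- Adam with global-norm gradient clipping at 5.
- Batching is per-sentence gradient accumulation (one Adam step per
  batch of averaged gradients), which avoids padding entirely, so
  "batched" and per-sentence encodings agree exactly by construction.
- All randomness — initialization, shuffling, dropout (drawn from R's
  RNG inside the compiled code) — flows from `config$seed`; fixed-seed
  training traces reproduce bit for bit, a tested guarantee.
- Softmaxes subtract the row maximum; log-probabilities are floored at
  1e-300 before `log`.
- Degenerate inputs: length-1 sentences, mention-free sentences and
  empty corpora are all legal everywhere except vocabulary construction,
  which refuses an empty corpus. Crossing *gold* mentions are accepted
  with a warning (annotation noise exists in real data); the generator
  never produces them.

## Problem sizes used by the checks

The suite's end-to-end blocks use sizes chosen to make the properties
sharp on one CPU: parameter recovery trains on 2000 sentences and
evaluates on 200 (the default study condition; held-out micro-F1 must
reach 0.90 within 20 epochs at `small_model_config()` widths); the
boundary-head accuracy check uses 400/60 sentences over three seeds; the
ablation uses 600/150 sentences, eight epochs and five paired seeds —
deliberately *partial* training, because at convergence both arms
saturate and the recall difference that boundary supervision produces is
no longer visible. The ablation is reported at warn level: it is a
stochastic trend, not a theorem.

## Known limitations

- Span enumeration is `O(N²)` per sentence; very long inputs need the
  span-length cap, which silently bounds recallable mention length.
- The contextual-embedding interface accepts frozen per-token vectors
  only; there is no fine-tuning path.
- Discontinuous mentions are out of scope; crossing mentions can be read
  but never predicted.
- The greedy overlap resolver is the specified decoder; it is not a
  maximum-weight non-crossing selection, and with adversarial score ties
  it keeps the lexicographically earliest candidate.
- Training is single-threaded CPU; the reference-width configuration on
  benchmark-scale corpora is out of reach here by design.
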