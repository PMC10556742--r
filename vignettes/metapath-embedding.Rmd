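---
title: "Meta-path attention embedding for disease association prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-path attention embedding for disease association prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaPathDD)
```

## The network and its assumptions

MetaPathDD predicts disease–disease associations under the
guilt-by-association hypothesis: diseases whose molecular neighborhoods
overlap — shared susceptibility genes, interacting proteins, or mouse
orthologs producing common phenotypes — are more likely to co-occur. The
input is a typed, undirected, four-layer network:

* `DG` human disease–gene associations,
* `GG` gene–gene links from protein–protein interactions,
* `GM` human–mouse homologous genes,
* `MP` mouse gene–phenotype associations.

PPI links carry an integer confidence score (STRING-style, 0–999); links
scoring below 400 are removed and every retained edge is weighted 1.0.
The threshold is boundary-inclusive (a score of exactly 400 is kept).
Identifiers are treated as opaque strings per node type; no ontology
resolution or hierarchy traversal is attempted, so the protein-to-gene
mapping is supplied as an explicit table and unmapped links are dropped
(and counted). Assembly is fatal on a type collision — an identifier
claimed by two node types means corrupt inputs, not something to repair
silently.

## Meta-paths

Four disease-anchored meta-path schemas drive the embedding: M1 (D–G–D),
M2 (D–G–G–D), M3 (D–G–M–G–D) and M4 (D–G–M–P–M–G–D). Because the network
has no mouse–mouse edge type, the homolog-bridged path is realized as the
five-node D–G–M–G–D template (two `GM` hops around a shared mouse
ortholog). Instances are typed walks; nodes may repeat across positions,
so the degenerate walk d–g–d back to the target is a valid instance.
Including it keeps every connected disease inside its own neighborhood,
which the attention aggregation expects, and gives diseases with no
second-disease connection a non-empty instance set. A disease with no
instances at all for a schema contributes the activated zero vector and
is reported as starved.

M4 walk counts grow multiplicatively in the degrees along the path, so
enumeration accepts a per-(target, schema) cap (default 128): if a target
exceeds it, a seeded uniform subsample is kept. The subsample preserves
the attention aggregate in expectation while bounding memory; with a
fixed seed it is deterministic. Only disease-anchored schemas are
enumerated — disease pairs are the prediction target, and gene- or
phenotype-anchored aggregation would multiply cost without entering the
loss.

## Embedding model

Node content is projected per type into a shared d′-dimensional space,
`h'_v = W_A x_v`. The association tables ship no node attributes, so the
default initial features `x_v` are free learnable vectors per node
(one-hot and user-provided matrices are config options).

Each instance is encoded by relational rotation: vectors are read as
d′/2 complex components (first half real parts, second half imaginary),
and each step rotates the accumulator by the edge type's unit-modulus
relation vector before adding the next node:

    o_0 = h'_{t_0},  o_i = h'_{t_i} + o_{i−1} ⊙ r_i,  h = o_n / (n+1).

Position 0 of the stored walk is the target disease; traversing an edge
against its canonical orientation conjugates the relation vector (negated
phases), which makes the two reading directions equivalent up to a global
rotation that attention absorbs. Relation vectors are parameterized by
their phase angles, so unit modulus holds by construction after any
gradient update; the two `GM` hops of M3/M4 share one phase vector per
direction. With all phases zero the encoder reduces exactly to the mean
of the walk's node vectors — a closed form the tests exploit.

Intra-path aggregation is multi-head graph attention: per head, logits
`LeakyReLU(a_Pᵀ [h'_d ‖ h_P(d,g)])` on the head's slice, softmax over the
target's instances, attention-weighted sum, ELU, heads concatenated.
Inter-path aggregation computes one global weight per schema from
summaries `s_P = mean_d tanh(M h^P_d + b)` and a query vector, softmaxed
across schemas, and the weighted sum passes through a final projection
with ELU. The generic activation is ELU throughout (configurable);
the link scorer and the loss use the logistic sigmoid exactly.

Pairs are scored `σ(h_d1ᵀ h_d2)` on the raw dot product — embeddings are
not L2-normalized, since the sigmoid scorer operates on the dot product
itself and normalization would discard the learned magnitudes.

## Training

The negative-sampling log-sigmoid loss is minimized by full-batch Adam.
The true negative class (all non-associated pairs) is quadratic in the
disease count, so it is sampled: each epoch draws `negRatio` negatives
per positive (default 1, configurable; `negRatio = Inf` uses the whole
complement, practical on small graphs) from the unordered disease pairs
outside the positive set and outside any caller-supplied exclusion list.
Positive pairs link diseases while the graph layers link diseases to
genes, so held-out evaluation pairs never need to be removed from the
graph — supervision and graph are disjoint by construction.

Defaults: 100 epochs, learning rate 5e-3, and optional early stopping on
a held-out validation slice of the training positives (patience 10),
disabled unless `valFraction > 0`. Dropout (default 0.5) is applied to
attention coefficients and projected features during training only;
evaluation-mode forward passes are deterministic. A non-finite loss
aborts immediately with the epoch and learning rate in the message.

Gradients are computed by a hand-written vectorised backward pass that
mirrors the forward computation (no autodiff framework is involved). The
test suite verifies every parameter group against central finite
differences at 1e-4 relative error, and the whole forward pass against an
independent scalar implementation that uses R's complex arithmetic.

## Evaluation protocol

Cross-validation partitions the **positive** pairs into seeded folds;
each fold is held out in turn, the model trains on the remaining
positives, and AUC / average precision are computed on the held-out
positives against an equal-sized seeded sample of negative pairs drawn
from the complement and disjoint from every pair the training run could
sample as a negative. (Partitioning the *unconnected* pairs instead would
leave no positives to train on in the extreme; partitioning positives
with matched negatives is the standard link-prediction protocol, and is
what this package implements and documents.) The AUC is the midrank
Mann–Whitney statistic; AP is the step-sum over distinct thresholds.
Reports store values on [0, 1] and print percentages with two decimals.
Ranked prediction lists sort by descending score with lexicographic
tie-breaks, so output is total-ordered and reproducible.

## The synthetic generator

The generator emulates the *shape* of the real inputs — five tab-separated
tables plus a positive pair list — with planted community structure as
the recoverable signal. Defaults: 4 communities, 8 diseases and 20 human
genes each, 5 phenotypes per community, 60% homolog coverage,
within-community disease–gene probability 0.25 (about five genes per
disease, enough shared genes for M1/M2 signal without saturating), PPI
within/between probabilities 0.15 / 0.005, mouse-phenotype attachment
0.5, disease–gene noise 0.01, positive-pair rate 0.5 (≈ 55 positives, so
10-fold CV keeps 5–6 held-out pairs per fold), and one community in four
*phenotype-only*. In a phenotype-only community each disease owns private
genes, PPI links stay inside one disease's gene set, and orthology is
1-to-1 — community signal then flows only through shared mouse
phenotypes (M4), which is what the ablation tests exercise. Confidence
scores are drawn uniformly from 600–999 within communities and 1–399
between, so the ≥ 400 filter is exercised meaningfully: it admits exactly
the within-community interactions.

The shuffled-null control permutes disease labels inside the positive
list through a seeded random permutation: the graph is untouched and each
disease keeps its pair degree, but alignment between positives and
communities is destroyed. Two honest caveats follow. First, the permuted
positive-pair graph is isomorphic to the original, so a model with free
per-node features can still generalize to held-out pairs by transitivity
within trained clusters — the null AUC therefore sits above 0.5, and the
meaningful comparison is *paired* (full vs. null on the same seed).
Second, a random permutation leaves a minority of pairs inside some
community by chance, which also lifts the null. What the generator does
**not** emulate: real degree distributions (MGI/STRING layers are heavily
right-skewed), ontology semantics, weighted confidence structure above
the threshold, or literature-validated positives. Passing the recovery
tests therefore demonstrates correct mechanics and genuine use of
cross-species signal at desk scale, not performance on curated
database extracts.

## Desk-scale configuration

The model's reference configuration (d′ 64, 8 heads, inter-path
attention dim 128, output 64, dropout 0.5) targets database-scale
networks. For the synthetic study conditions (~180 nodes, ~55 positives)
the package's tests and the acceptance script use a proportionate
configuration chosen once for this problem size: hidden 16, 4 heads,
attention dim 32, output 16, dropout 0.1, instance cap 128, Adam at
lr 0.01 for up to 100 epochs with 2 negatives per positive and early
stopping on a 15% validation slice (patience 12). Early stopping matters
here: it halts each fold near its best generalization, which stabilizes
fold-level AUC on graphs this small.

## Numerical choices

* Softmax uses max-subtraction; `log σ(z)` is computed in the
  overflow-safe branch form and propagates NaN rather than masking it.
* LeakyReLU slope 0.01; ELU with unit scale.
* Relation phases are angles, so |r| = 1 is exact at all times.
* Undirected edges are stored once in canonical orientation (`GG`
  lexicographically); duplicate rows, reversed duplicates and self-loops
  are dropped at parse/assembly time, with skipped-row counts reported.
* All randomness flows through small derived integer seeds
  (reproducible across platforms with R's default RNG); identical master
  seeds reproduce fixtures, training traces and CV reports bitwise.
* Empty instance sets, single-schema aggregation (β = 1), an exhausted
  negative complement and single-class AUC inputs are all explicit,
  tested code paths (the first three degrade gracefully, the last is an
  error by definition).

## Limitations

Training is full-batch and CPU-bound; the enumeration cap, not minibatch
neighbor sampling, bounds cost on dense graphs, so very high-degree nodes
are represented by a subsample of their walks. Free per-node features
mean transductive embeddings: unseen diseases cannot be embedded without
retraining. The evaluation negatives are uniform non-positives; under
heavy degree skew a degree-matched negative sampler would be a sterner
test than the one implemented here.
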