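---
title: "Cross-domain herbal prescription recommendation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain herbal prescription recommendation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presrec)
```

## The problem

A TCM clinical record pairs a set of free-text symptom terms with the set
of herbs the physician prescribed. Treating symptoms as features and herbs
as labels makes prescription recommendation a multi-label ranking task,
but one with brutal sample-level sparsity: a record touches perhaps
fifteen symptoms out of tens of thousands of distinct terms, and twenty
herbs out of several hundred. A model trained on one disease corpus alone
sees far too few co-occurrences per term to learn stable representations.

The approach implemented here borrows statistical strength across two
disease corpora — a *source* and a *target* domain — that share part of
their herb and symptom vocabularies. Shared herbs carry most of the
cross-domain signal: the same herb prescribed for different diseases links
the two corpora's co-occurrence structure.

## Model stages and their assumptions

**Co-occurrence reduction.** Each domain is reduced to an integer
herb-by-symptom matrix; a patient contributes at most one count per
(herb, symptom) pair, so counts are bounded by the record count and the
matrix is insensitive to within-record term repetition. This reduction
discards record-level herb-herb interactions; the recommender recovers
patient-level structure later from the multi-hot symptom vector.

**Autoencoders (one for herbs, one for symptoms).** The per-entity
profiles of *both* domains, zero-padded to a common input dimension, are
encoded to `d` latent dimensions and decoded back with ReLU on both
layers. The loss is a masked square error: only *observed* positions —
nonzero counts, the implicit-feedback convention — contribute, plus an L2
penalty `alpha` on all four parameter blocks. A zero count is thus treated
as "unobserved", not "negative evidence", which is the defensible reading
for co-occurrence data where absence mostly reflects sparsity.

**Adversarial refinement.** The encoder features of both domains feed a
feature extractor, a rating predictor, and a domain classifier under the
composite objective `loss_pred - mu * loss_dom + lambda * R`. The minus
sign is implemented as a gradient-reversal layer: a single optimizer
descends the composite objective as written, with the classifier branch's gradient
negated (and scaled by `mu`) where it enters the extractor. The rating
targets default to the input features themselves — latent
self-reconstruction — because the predictor's job is to preserve rating
structure while the extractor suppresses domain identity; callers can
supply explicit targets instead.

**Embedding assembly.** Union-vocabulary tables are built per term. A term
seen in one domain keeps its refined vector verbatim; a term seen in both
gets the elementwise mean, which keeps the dimension fixed and is
symmetric in the domains. Concatenation is available behind
`overlap = "concat"` for users who prefer to preserve both views at twice
the dimension.

**Recommender.** The patient vector mean-pools the embedding rows of the
active symptoms — the only reading under which average pooling is
non-trivial — then passes through the symptom-branch MLP; herbs pass
row-wise through the herb-branch MLP; both branches end at a shared width
with a final ReLU, and per-herb probabilities are the sigmoid of the dot
products. Training minimises the mean binary cross-entropy against the
full herb multi-hot (no negative sampling), averaged over herbs and
patients so the learning rate is insensitive to vocabulary size, plus L2
weight decay. Embedding tables stay frozen during recommender training;
fine-tuning them would entangle the stages and is deliberately not done.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent_dim` / `d` | 500 | embedding dimension (32 is plenty for desk-scale synthetic runs) |
| `alpha` | 0.01 | autoencoder L2 strength |
| `mu` | 1 | adversarial weight in the composite objective |
| `lambda` | 0.001 | L2 weight for the pattern predictor and the recommender |
| `depth_s`, `depth_h` | 7, 5 | weight layers of the symptom and herb branch MLPs |
| `out_width` | 128 | shared branch output width (makes the dot product well defined) |
| `dropout` | 0 | off by default; it degrades this model |
| `lr` | 1e-3 | Adam learning rate, all stages |
| `patience` | 20 | early-stopping patience, epochs |

## Numerical choices

* **Initialisation.** He-style fan-in uniform weights; biases start at 0.1
  rather than 0, and the autoencoder's decoder bias starts at the column
  means of the profiles. Both choices keep ReLU units out of the dead
  region at the start of training — with a ReLU output layer and squared
  loss, a unit whose pre-activation goes negative for every input receives
  no gradient and never recovers.
* **Early stopping.** All trainers stop after `patience` epochs without
  improvement. The autoencoder and recommender return the best parameters
  seen, so the final loss never exceeds the initial one. The pattern
  predictor monitors only the prediction component (`loss_pred +
  lambda*R`) — an adversary can lower the composite loss without bound by
  degrading the classifier — and returns the final-epoch parameters,
  because the useful domain confusion accumulates over epochs and a
  best-prediction rollback would discard it.
* **Probability geometry.** Both branch outputs are ReLU-nonnegative, so
  every logit is `>= 0` and every predicted probability is `>= 0.5`. The
  optimum for a non-prescribed herb is a zero logit, and ranking is
  carried by small positive margins above it. This is a property of the
  specified architecture, not a bug; readers should treat the outputs as
  ranking scores, not calibrated probabilities.
* **Ties and determinism.** Herbs with equal scores are ordered by
  ascending vocabulary index, so top-K lists are prefix-nested in K and
  reproducible. Every stochastic function takes a seed and restores the
  caller's RNG state; a pipeline run is a pure function of (records,
  config, seed), which the test suite checks bit-identically.
* **Degenerate inputs.** Empty corpora, empty gene sets, all-unknown
  symptom sets, zero-sd nulls and infeasible generator specs raise errors
  that name the offending term or quantity. Unknown symptoms at inference
  are dropped with a warning (clinical vocabularies are open); unreachable
  node pairs in graph statistics are dropped from means with a warning by
  default, or raise under `unreachable = "error"`. BCE probabilities are
  clipped to `[1e-7, 1 - 1e-7]`.

## Network proximity statistics

Distances are unweighted breadth-first shortest paths. The separation
score uses the closest-distance convention: within-set terms average each
node's distance to the nearest *other* member (0 for singletons), the
cross term averages each node's distance to the nearest member of the
opposite set, and a node in both sets contributes 0. The z-score compares
observed `d_AB` with `n_rand` uniformly drawn node-set pairs of matching
sizes; a degree-binned null is available behind `degree_binned = TRUE`
since network-medicine practice often degree-matches, but uniform drawing
is the default to keep the null assumption-free. The
edge permutation test estimates a per-pair connection probability from the
null mean, `p_hat = mean(null)/(|A||B|)`, and reports the upper-tail
binomial probability of at least the observed inter-set edge count among
`|A||B|` pairs — the binomial reading of a permutation null whose rounds
are far fewer than the tail resolution needed.

The sample-level sparsity statistic is `1 - mean set size / vocabulary
size`. The per-corpus vocabulary is the default denominator: the reported
herb sparsities of the two reference corpora cannot both follow from the
union vocabulary, while the per-corpus reading reproduces them; the union
denominator stays available as an option.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws record set sizes from a truncated Poisson
(minimum one) around the target means, samples terms from a Zipf-skewed
frequency law (exponent 1.1, matching the long-tailed frequency profiles
of real corpora), and plants a symptom-to-herb rule table — identical
across domains for the shared herbs, domain-specific elsewhere — which is
the minimal structure under which cross-domain transfer can help. Every
vocabulary term is injected into at least one record so generated
vocabularies and overlap counts match the spec exactly; injected symptoms
still fire their rules. The presets carry the reported profiles of the two
reference corpora (mean symptoms 13.58/17.39, mean herbs 20.98/7.89,
overlaps 328 symptoms and 285 herbs, a 928-herb union vocabulary);
per-domain symptom vocabulary sizes, which are not reported anywhere, are
chosen to sum with the overlap to the reported 42,975-term union.

The generator does *not* emulate: correlated symptom clusters (real
syndromes), physician-specific prescribing styles, dosage, or the
open-vocabulary noise of clinical free text. Passing tests on this corpus
therefore show that the pipeline recovers planted co-occurrence structure
at the stated sparsity — not that it reaches any particular accuracy on
real clinical data.

`generate_ppi()` plants two disjoint node sets in an Erdős–Rényi graph
with inter-set edge probability multiplied by `boost`; `boost = 1` leaves
the sets indistinguishable from background, which is what makes the
calibration check of the edge test meaningful.

## Problem sizes used by the checks

The test suite and the acceptance script run the full pipeline at 200
records per domain with `d = 32` and branch width 32, the edge-test
calibration and power sweeps at 150-node graphs over 50 seeds, and the
planted-rule ranking check at 300 records with width 128 — sizes at which
every property of interest is already expressed and a complete run takes
seconds.

## Known limitations

* A freshly trained cross-validated probe can still separate the domains
  of corpus-derived refined features even after adversarial training:
  gradient reversal defeats the classifier it trains against, and the
  reconstruction targets themselves carry domain-scale information. The
  domain-confusion property is therefore demonstrated on two-domain
  Gaussian feature sets, where the adversarial dynamics are observable in
  isolation.
* Predicted probabilities concentrate just above 0.5 (see above); use
  ranks.
* The two-layer autoencoder and fully connected stacks are faithful to
  the specified architecture but are not the strongest possible density
  models for count profiles; a Poisson likelihood would be the natural
  next step and is out of scope.
* Full-batch training is used throughout; at the full reference scale
  (d = 500, tens of thousands of records) a mini-batch schedule would be
  required.
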