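# presrec

Herbal prescription recommendation by cross-domain neural collaborative
filtering, for researchers working with Traditional Chinese Medicine (TCM)
clinical records. Given a patient's symptom set, the model scores every
candidate herb and returns a ranked prescription. Because a single
disease-specific corpus is extremely sparse (each record touches a handful
of the tens of thousands of recorded symptom terms), the model first learns
symptom and herb representations *across two corpora* — a source domain and
a target domain that share part of their herb and symptom vocabularies —
and only then trains the recommender on top of those shared
representations.

The package also ships the network-pharmacology side of the analysis
(proximity statistics between symptom-gene and herb-target sets on a
protein–protein interaction network) and a seeded synthetic-corpus
generator, so the whole pipeline runs and is testable fully offline.

## The model

Each domain's records are reduced to a herb-by-symptom co-occurrence
matrix, `C_ij` = number of patients in which herb *i* and symptom *j*
appear together (each patient counts once per pair). The stages are:

1. **Cross-domain autoencoders.** Per-entity co-occurrence profiles from
   both domains, zero-padded to a shared input dimension, train one herb
   autoencoder and one symptom autoencoder:
   `ŷ = ReLU(W₂ ReLU(W₁ y + b₁) + b₂)`, fitted by the regularised square
   loss restricted to observed (nonzero) positions,
   `Σ ‖ŷ − y‖²_O + α(‖W₁‖²_F + ‖W₂‖²_F + ‖b₁‖² + ‖b₂‖²)`.
2. **Adversarial pattern predictor.** The encoder features
   `f = ReLU(W₁ y + b₁)` of both domains pass through a feature extractor
   θ_f, a rating predictor θ_r, and a domain classifier θ_c trained on the
   composite objective `L = loss_pred(θ_f, θ_r) − μ·loss_dom(θ_c) + λR`,
   realised with a gradient-reversal layer, so the refined features
   predict ratings while hiding their domain.
3. **Embedding assembly.** Union-vocabulary tables `E_s` (symptoms) and
   `E_h` (herbs); an entity present in both domains gets the elementwise
   mean of its two refined vectors.
4. **Neural collaborative filtering.** Patient representation
   `Z_p = ReLU(MLP_s(avg_pool(P·E_s)))` (mean over the active symptoms'
   embedding rows), herb representations `Z_h = ReLU(MLP_h(E_h))`, and
   per-herb probabilities `R̂_j = σ(⟨Z_p, Z_h[j]⟩)`, trained with binary
   cross-entropy against the patient's full herb multi-hot.

Evaluation uses micro-averaged top-K metrics,
`P@K = Σ|R(i)∩T(i)| / Σ|R(i)|`, `R@K = Σ|R(i)∩T(i)| / Σ|T(i)|`, and their
harmonic-mean F1. The network-pharmacology module computes the separation
score `S_AB = d_AB − (d_AA + d_BB)/2` (closest-distance convention), a
randomization z-score of `d_AB` against uniformly drawn node sets, the
average shortest path length over all cross-set pairs, and an inter-set
edge-count permutation test whose significance comes from an upper-tail
binomial test.

## Worked example

```r
library(presrec)

spec    <- corpus_spec(n_source = 150, n_target = 150, seed = 42)
records <- generate_corpus(spec)
cfg <- pipeline_config(simulate = spec, latent_dim = 32, depth_s = 3,
                       depth_h = 2, out_width = 32, hidden = 32,
                       cpm_hidden = 32, max_epochs = 300,
                       k_list = c(5, 10), seed = 7)
res <- run_pipeline(cfg, "run1", quiet = TRUE)
dplyr::filter(res$metrics, domain == "union")
#> # A tibble: 2 × 6
#>   domain     k precision recall    f1     n
#>   <chr>  <int>     <dbl>  <dbl> <dbl> <int>
#> 1 union      5     0.303  0.103 0.153    60
#> 2 union     10     0.27   0.183 0.218    60
```

Held-out micro precision@5 of 0.30 means that pooled over the 60 test
patients, 30% of all recommended herbs were actually prescribed; recall
rises with K as more of each prescription is covered. A ranked
prescription for one patient:

```r
recommend(res$model, records$symptoms[[1]], k = 5)
#>    rank       herb probability
#> 1     1 H_src_0028       0.500
#> 2     2 H_src_0036       0.500
#> 3     3  H_sh_0009       0.500
#> 4     4  H_sh_0001       0.500
#> 5     5 H_src_0025       0.500
sum(recommend(res$model, records$symptoms[[1]], k = 5)$herb %in%
      records$herbs[[1]])
#> [1] 5
```

All five top herbs are in this patient's true prescription. The
probabilities sit barely above one half at this reduced scale: both branch
outputs are ReLU-nonnegative, so every logit is ≥ 0 and ranking is carried
by small positive margins rather than by spread-out probabilities (see the
methods vignette).

Proximity of two planted gene sets on a synthetic interaction network:

```r
fx   <- generate_ppi(150, 0.05, size_a = 15, size_b = 15, boost = 4, seed = 9)
prox <- network_proximity(fx$graph, fx$set_a, fx$set_b,
                          n_rand = 1000, n_rounds = 1000, seed = 3)
tidy(prox)[, c("s_ab", "z", "aspl", "observed_edges", "edge_p_value")]
#> # A tibble: 1 × 5
#>     s_ab     z  aspl observed_edges edge_p_value
#>    <dbl> <dbl> <dbl>          <int>        <dbl>
#> 1 -0.267 -1.71  2.31             39     1.68e-10
```

The negative separation score and z-score, and the binomial p-value of the
39 observed inter-set edges, all flag the planted association.

A thin CLI over the same functions is installed at
`system.file("scripts", "presrec", package = "presrec")` with subcommands
`simulate`, `run-all` and `netpharm`.

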