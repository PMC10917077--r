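# po2go

Partial-order contrastive embeddings for Gene Ontology (GO) terms, and a
joint term/protein predictor for multi-label protein function prediction,
with the full embedding-quality and CAFA-style evaluation suite — all
runnable end to end on synthetic ontologies and proteins, offline.

**Who it is for.** Computational biologists who need GO term vectors that
respect the ontology's hierarchy (for semantic similarity, annotation
transfer, or as features), and who want a function predictor that scores
proteins against *all* terms jointly from fixed protein feature vectors.

## The method

Supervision comes from the **shortest reachable path (SRP)** over the
`is_a`/`part_of` DAG: ancestrally related pairs are *direct* with length =
minimum edge count; pairs joined only through a common ancestor are
*indirect* with length = minimum connecting edge count + 0.5 (siblings:
2.5); cross-domain pairs are *unreachable* (+∞). Embeddings `e(t) ∈ R^{d'}`
are trained so that similarity is ordered inversely to SRP: for each anchor
`t`, a positive `t⁺` at SRP 1 or 2.5 is contrasted against `k` negatives
stratified over the three reachability classes (every graded negative
strictly farther than the positive), under the balanced InfoNCE loss

    L = -Σ_t log[ s(t, t⁺) / (s(t, t⁺) + C_GO) ],
    C_GO = (k/3) Σ_{R ∈ {dr, ir, ur}} mean_{n ∈ N_R} s(t, n),
    s(e_i, e_j) = exp(e_iᵀ e_j / τ),

which weights the scarce direct-negative class equally with the abundant
ones. The predictor projects term embeddings and fixed protein vectors into
a shared space with two small MLPs, scores term `j` for protein `p` as
`s_j = e_proj(t_j)ᵀ f_proj(p)`, and maps the score vector through a final
sigmoid layer trained with multi-label binary cross-entropy; the term table
is tuned during training (freezable for the ablation).

Evaluation: protein-centric **Fmax**, IC-weighted **Smin**, micro-**AUPR**,
annotation specificity (mean IC of true positives), few-shot binned
term-centric F1; and on the embedding side depth probing, ancestor vs
non-ancestor distinguishability by the 1-Wasserstein distance, domain
silhouette, and best-match-average (BMA) semantic similarity correlations.

## Worked example

```r
library(po2go)

# a 2-domain, 80-term synthetic ontology with known structure
dag <- generate_dag(dag_spec(domains = 2, terms_per_domain = 40, seed = 0))

fit <- train_embeddings(
  dag,
  train_config(tau = 0.1, d_prime = 16, epochs = 100, learning_rate = 0.01, seed = 1),
  sampler_config(k = 16, u = 0.5, seed = 2)
)
glance(fit)
#>   n_terms d_prime epochs initial_loss final_loss   tau     k     u
#> 1      80      16    100         5.08     0.0138   0.1    16   0.5

idx <- build_index(dag)
partial_order_satisfaction(fit$embedding, idx, n_triples = 5000, seed = 3)
#> [1] 0.5982        # random baseline at the same seeds: 0.5

d <- ancestor_similarity_distributions(dag, fit$embedding, 500, seed = 7)
wasserstein_1(d$ancestor, d$non_ancestor)
#> [1] 0.2104868     # ancestors are measurably closer than non-ancestors

# proteins with recoverable annotation signal, then the joint predictor
y <- generate_annotations(dag, annotation_spec(n_proteins = 60, seed = 4))
P <- generate_protein_vectors(y, signal_spec(d = 24, noise_sd = 0.1, seed = 5))
model <- train_predictor(P, y, fit$embedding, predictor_config(epochs = 150, seed = 6))
scores <- predict(model, P)

f_max(scores, y)$fmax      #> 1         (training fit; label-prior baseline: 0.59 AUPR)
aupr(scores, y)            #> 1
ic <- information_content(y)
s_min(scores, y, ic)$smin  #> 0
avg_ic_true_positives(scores, y, ic, f_max(scores, y)$threshold)
#> [1] 1.530691     # mean specificity (bits) of the recovered annotations
```

The loss drop (5.08 → 0.014), the above-chance constraint satisfaction
(0.598 vs 0.5) and the positive Wasserstein separation show the embedding
absorbing the partial order; the perfect training-set recovery of the
near-noiseless separable task shows the predictor wiring is sound — held-out
behaviour on real data is out of scope here (see the vignette for what the
synthetic generators do and do not emulate).

A command-line wrapper covering `simulate`, `train-embeddings`,
`eval-embeddings`, `train-predictor` and `evaluate` ships at
`system.file("cli", "po2go", package = "po2go")`.

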