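---
title: "Partial-order contrastive GO term embeddings and joint function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-order contrastive GO term embeddings and joint function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(po2go)
```

## The problem

The Gene Ontology (GO) organizes terms describing gene-product function as a
directed acyclic graph in three domains (biological process, molecular
function, cellular component). Distributed representations of GO terms feed
many downstream analyses — semantic similarity, annotation transfer,
multi-label protein function prediction — but a good embedding must respect
the DAG: a term should sit closer to its parent than to its grandparent,
closer to a sibling than to an unrelated term, and far from every term of
another domain. This package learns such embeddings contrastively (the
PO2Vec objective) and couples them with fixed protein feature vectors in a
joint projection predictor (PO2GO).

## The shortest reachable path

All supervision comes from one graph distance. For terms $t_i, t_j$:

* **direct**: a directed path exists between them (an ancestral relation, in
  either orientation); the SRP length is the minimum edge count of such a
  path.
* **indirect**: no ancestral relation, but the two share a common ancestor
  $a$; the length is $\min_a\,[d(t_i\!\to\!a) + d(t_j\!\to\!a)] + 0.5$, so
  siblings score $2.5$. The $+0.5$ offset makes every indirect pair strictly
  farther than a direct pair with the same edge count.
* **unreachable**: no common ancestor (in practice, different domains);
  length $+\infty$.

Only `is_a` and `part_of` edges count — the two transitive relations
through which annotations propagate safely — and both are weighted
identically, since no per-relation weighting is defined for the distance.
`srp(t, t)` is defined as 0/direct; self-pairs are never sampled, and 0
preserves the ordering. Indirect reachability is evaluated through common
*ancestors* only; common-descendant routes are excluded (a literal reading
of the definition; flagged as a possible future extension). Term depth — the
target of the probe below — is the **longest** child-to-parent path to the
domain root, not the shortest, so a term reachable by both a near and a far
route is counted at its most specific position.

## Contrastive objective

For each anchor term, the positive is drawn uniformly from the union of
SRP-1 neighbors (parents/children) and SRP-2.5 neighbors (siblings — any
pair at exactly 2.5, including sibling-like multi-parent pairs). Negatives
are stratified over the three reachability classes using the per-term sorted
lists $Q_{dr}, Q_{ir}, Q_{ur}$: with budget $k$ and direct-fraction cap $u$,

* $|N_{dr}| = \min(\lfloor k u\rfloor, |\{q \in Q_{dr}: \mathrm{srp}(t,q) >
  \mathrm{srp}(t,t^+)\}|)$,
* $|N_{ir}| = \min(\lfloor (k - |N_{dr}|)/2 \rfloor, \text{eligible } Q_{ir})$,
* $|N_{ur}| = k - |N_{dr}| - |N_{ir}|$,

with deficits spilling toward $Q_{ur}$ (and back to the graded classes when
the other domain is small). Every graded negative is strictly farther from
the anchor than the positive, which is what turns the loss into a
partial-order constraint rather than a generic contrastive one. The floor in
$\lfloor ku \rfloor$ keeps the cap conservative on the scarce direct class.

The loss balances the three classes explicitly. Per anchor,
$$\mathcal{L} = -\log\frac{s(t,t^+)}{s(t,t^+) + C}, \qquad
C = \frac{k}{B}\sum_{R \in \{dr, ir, ur\},\, N_R \neq \emptyset}
\overline{s}(t, N_R),$$
where $\overline{s}$ is the class-mean similarity and $B$ the number of
non-empty classes (so the weighting degrades gracefully on small
ontologies). Without this balancing, the abundant indirect/unreachable
classes drown out the rare direct negatives that carry the fine-grained
hierarchy signal.

### The similarity kernel and a typesetting ambiguity

The similarity is an exponentiated dot product with temperature $\tau$. The
source formula can be read either as $\exp(e_i^\top e_j/\tau)$ or as
$\exp(e_i^\top e_j)/\tau$. The package defaults to the first — the standard
InfoNCE temperature placement — and exposes the literal second reading via
`train_config(sim_variant = "literal")`. The two are less different than
they look: in the balanced loss the literal $1/\tau$ factor cancels between
numerator and denominator, so under that reading $\tau$ has no effect on the
loss or its gradients at all. That cancellation is itself a reason to prefer
the scaled placement, where $\tau$ genuinely sharpens the contrast.

### Numerical choices

* Loss and gradients are computed in log space (a log-sum-exp over the
  positive and the weighted negatives), so large dot products at small
  $\tau$ cannot overflow.
* Embeddings initialize i.i.d. Gaussian with sd $1/\sqrt{d'}$, seeded;
  `random_embeddings()` reproduces exactly this initialization and is the
  baseline in every embedding-quality comparison.
* Optimization is per-anchor SGD; each epoch visits every term once in a
  shuffled order with fresh samples. At $\tau = 0.1$ gradients carry a
  $1/\tau$ factor, and step sizes near $0.05$ made the iteration diverge
  (exploding norms); $0.01$ is stable and is used for all bundled
  partial-order runs. `train_config()`'s default remains the conservative
  $10^{-3}$.
* Anchors whose eligible negative pools are all empty (possible only on
  tiny single-domain ontologies) are skipped rather than failing the run;
  the explicit `balanced_infonce_loss()` still errors on a fully degenerate
  anchor.
* Defaults $k = 64$, $u = 0.5$, $\tau = 0.1$, $d' = 128$ are package
  choices (the reference values are not public); all are configurable.

## The joint predictor

Protein feature vectors are *inputs*: any fixed per-protein vector works
(mean-pooled protein-language-model features in the original setting). The
shipped `toy_protein_embedder()` is deterministic hash-seeded mean pooling —
test plumbing, not biology — and the synthetic generator below is the
recommended source for experiments. Two two-layer ReLU perceptrons project
term embeddings ($d' \to h$) and protein vectors ($d \to h$) into a shared
space; the joint score is the dot product $s_j = e_{proj}(t_j)^\top
f_{proj}(p)$, and a final linear layer over the whole score vector followed
by a sigmoid yields $\hat y \in (0,1)^m$, trained with multi-label binary
cross-entropy by full-batch Adam. The term table itself is tuned by default
and frozen with `predictor_config(freeze_terms = TRUE)` (the
fixed-embedding ablation); `multi_hot_embedding()` provides the naive
self-plus-ancestors indicator features for the remaining ablation arm. Head
widths (hidden 64, $h$ 32 by default) are package choices — the reference
architecture is unpublished — and sit in `predictor_config()`.

Prediction scores are *not* forced to be monotone along the hierarchy
(parent score at least child score): the training labels are true-path
closed, but no such constraint is stated for the scores themselves, so any
post-hoc propagation is left to the caller.

## Evaluation suite

* **Fmax** — protein-centric CAFA metric: at each threshold on a 0.01 grid
  over (0,1], precision averages over proteins with at least one
  prediction, recall over proteins with truth; Fmax is the best harmonic
  mean.
* **Smin** — minimum over thresholds of
  $\sqrt{ru^2 + mi^2}$, where remaining uncertainty $ru$ and
  misinformation $mi$ weight missed and spurious terms by information
  content $IC(t) = -\log_2(\text{count}(t)/n)$ on propagated counts
  (never-observed terms inherit the rarest observed IC; base configurable).
* **micro-AUPR** — all protein-term cells pooled, step-wise integration
  with tied scores collapsed to single PR points.
* **annotation specificity** — mean per-protein IC of true positives at the
  Fmax threshold.
* **few-shot binned F1** — per-term binary F1 at the Fmax threshold,
  averaged within annotation-count bins (default 1–10, 11–30, 31–100,
  101–300, >300; empty bins are reported absent, not zero).
* **embedding quality** — depth probing (a small `nnet` regressor on an
  80/20 split, reporting held-out MSE and Spearman $\rho$; both reported
  because the reference metric is not identifiable), ancestor vs
  non-ancestor cosine distributions compared by the 1-Wasserstein distance
  (same-domain non-ancestors only, so the contrast measures hierarchy
  rather than trivial domain separation), domain silhouette under cosine
  distance (a quantitative stand-in for a 2-d projection figure;
  `project_2d()` remains as a plotting hook), and best-match-average (BMA)
  semantic similarity correlated against protein-pair benchmarks with
  Pearson and Spearman coefficients.

All evaluation routines are deterministic given their seeds. The depth
probe compares against a seed-matched random-embedding baseline rather than
an absolute threshold, because absolute probe error depends on ontology
shape.

## Synthetic data: what it emulates and what it does not

`generate_dag()` grows each domain by sequential attachment with optional
extra parents — acyclic and single-rooted by construction. Defaults (3
domains, bounded depth 8, branching 4, multi-parent probability 0.2) give
DAGs with the qualitative features the method needs: multiple depths,
diamonds from multi-parent terms, disconnected domains.
`generate_annotations()` draws per-protein direct terms with weight
$(1+\text{depth})^{\text{leaf\_bias}}$ (default bias 2, favouring specific
terms as real curation does) and closes under the true path rule.
`generate_protein_vectors()` makes the protein signal linear and
recoverable by construction: a hidden Gaussian loading per term, proteins
as the mean of their true-term loadings plus noise. Pair benchmarks score
the Jaccard overlap of true annotation sets (continuous for the
family-similarity analogue, quantile-binarized for the interaction
analogue) — chosen as the simplest target for which "similar annotations
should mean similar proteins" is true by construction.

None of this mimics real GO topology statistics, real annotation bias, or
real protein-language-model geometry. Passing tests therefore demonstrate
that the algorithms are implemented correctly and behave as designed on
structurally faithful inputs — not that the learned embeddings reach any
particular quality on the real ontology.

## Study conditions used by the bundled checks

The test suite exercises the partial-order claims on a 300-term,
three-domain DAG (seed 0) trained for 200 epochs with $d' = 32$, $k = 32$,
$u = 0.5$, $\tau = 0.1$, step size 0.01 — sizes chosen so the full suite
runs comfortably on one CPU — and checks that the trained table beats the
seed-matched random baseline on constraint satisfaction (10 000 triples),
ancestor distinguishability, depth probing and domain silhouette. Predictor
recovery uses 80 proteins over an 80-term two-domain DAG across a noise
sweep ($\sigma \in \{0, 0.1, 0.3\}$), requiring the trained model to beat
the label-prior baseline on Fmax and AUPR at every level. Oracle
equivalence checks run brute-force SRP enumeration on twenty 50-node DAGs
and exhaustive metric enumeration on hand-sized fixtures.

## A minimal run

```{r example, eval = FALSE}
dag <- generate_dag(dag_spec(domains = 2, terms_per_domain = 40, seed = 0))
fit <- train_embeddings(
  dag,
  train_config(tau = 0.1, d_prime = 16, epochs = 100, learning_rate = 0.01,
               seed = 1),
  sampler_config(k = 16, u = 0.5, seed = 2)
)
idx <- build_index(dag)
partial_order_satisfaction(fit$embedding, idx, n_triples = 5000, seed = 3)

y <- generate_annotations(dag, annotation_spec(n_proteins = 60, seed = 4))
P <- generate_protein_vectors(y, signal_spec(d = 24, noise_sd = 0.1, seed = 5))
model <- train_predictor(P, y, fit$embedding,
                         predictor_config(epochs = 150, seed = 6))
scores <- predict(model, P)
f_max(scores, y)$fmax
```

## Known limitations

* Indirect SRP ignores common-descendant routes; on ontologies where those
  matter the distance is an upper bound.
* The contrastive trainer is plain SGD in R: ample for the hundreds-of-terms
  scale the package targets, but a full GO run (tens of thousands of terms)
  would want a compiled or GPU implementation behind the same interfaces.
* The depth probe's architecture (single hidden layer) and the predictor's
  head sizes are package defaults, not tuned values.
* Cross-domain similarity is assumed smaller than any within-domain
  ancestral similarity; embedding all domains in one space is a modelling
  convenience with limited direct biological meaning.
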