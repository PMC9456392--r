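---
title: "Predicting drug-combination synergy from structural network embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-combination synergy from structural network embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Whether two anticancer drugs act synergistically in a particular cell line
depends on how their molecular targets relate inside the cell's interaction
machinery. This package predicts the sign of a drug-pair/cell-line synergy
score (Loewe or ZIP scale; positive = synergistic, negative = antagonistic)
using **only** the topology of a protein-protein interaction (PPI) network
and the sets of proteins each drug and each cell line is associated with —
no chemical descriptors and no genomic profiles.

The premise is structural: two proteins whose local network neighbourhoods
look alike should receive similar latent features, even when they are far
apart in the network. The pipeline has four stages.

**1. Structural distances.** For a node $u$, let $R_k(u)$ be the set of
nodes at exactly $k$ hops and $s(R_k(u))$ its ordered (ascending) degree
sequence. The cumulative structural distance between $u$ and $v$ is

$$f_k(u,v) = f_{k-1}(u,v) + g\big(s(R_k(u)), s(R_k(v))\big), \qquad f_{-1} = 0,$$

where $g$ is the dynamic-time-warping (DTW) alignment cost between the two
degree sequences under element cost $\max(x,y)/\min(x,y) - 1$. The ratio
cost treats degree 1 vs 2 as seriously as degree 10 vs 20, which matches
how biological hubs behave. DTW is computed by the full dynamic program —
no warping window — because sorted degree-ring sequences are short. The
cost is zero exactly on automorphism orbits, and $f_k$ is symmetric,
non-negative and non-decreasing in $k$; both properties are enforced by
tests against a brute-force path-enumeration oracle.

**2. Multilayer graph.** Layer $k$ is a complete weighted graph over the
node pairs that still have non-empty rings at hop $k$, with intra-layer
weight $w_k(u,v) = e^{-f_k(u,v)} \in (0,1]$. Node $u$ in layer $k$ connects
to its own copies one layer up and down with weights
$\log(\Gamma_k(u) + e)$ and $1$, where $\Gamma_k(u)$ counts the intra-layer
edges at $u$ heavier than the layer's mean edge weight. We keep layers
complete (no pair pruning): the approximation of restricting to
similar-degree pairs is useful at genome scale but changes the model, so
it is not applied here.

**3. Walks and Skip-Gram.** A biased walker starts at layer 0; with
probability $q$ it moves within its layer to $v$ with probability
$e^{-f_k(u,v)} / Z_k(u)$ and emits $v$; with probability $1-q$ it switches
layer (up/down proportional to the inter-layer weights; layer 0 forces up,
the node's top layer forces down) and emits nothing. Each node starts 20
walks of 80 emitted tokens over a 4-layer graph, and the corpus trains
Skip-Gram with negative sampling (window 5, 64 dimensions by default).

**4. Features and classification.** A drug (or cell line) with targets
$P_1,\dots,P_n$ gets the mean vector $(P_1 + \dots + P_n)/n$. A record
(drug A, drug B, cell line) is the $3d$-wide concatenation of the three
entity vectors (192 columns at $d=64$), classified by gradient-boosted
trees (depth 7, learning rate 0.1, subsample and column subsample 0.9,
$\gamma = 0.1$, 100 rounds) under stratified five-fold cross-validation,
with accuracy, recall, precision, F1, AUC-ROC (trapezoidal) and AUC-PR
(average precision) reported per fold.

## Decisions the method leaves open

Several details are not pinned down by the construction above; the choices
made here, and why:

* **Stay probability $q$.** The walk bias parameter has no canonical value;
  0.3 is the customary structural-embedding default and is exposed as
  `walk_config(stay_prob=)`. It is logged by the CLI at embed time.
* **Emission convention.** A layer switch consumes a walk iteration but
  emits no token; `walk_length` counts emitted tokens, and the start node
  is emitted once. This keeps sentence lengths constant across nodes with
  different layer occupancy.
* **Layer count.** The multilayer construction allows as many layers as the
  network diameter; in practice 4 layers (plus layer 0) carry the usable
  signal and the default `k_max = 4` reflects that. The table is capped at
  the diameter automatically.
* **Drug-order symmetry.** Concatenation is order-sensitive but synergy is
  not. Each record therefore contributes both orderings (A,B,C) and
  (B,A,C) to the training folds — created *after* fold splitting, so the
  two orderings of one record never straddle train and test — and
  prediction averages the two orderings, making `predict()` exactly
  symmetric.
* **Skip-Gram regime.** Negative sampling (5 negatives) rather than
  hierarchical softmax, 5 epochs, initial learning rate 0.025 with linear
  decay; `min_count` is fixed at 1 because every protein must be
  featurisable. These are conventional word2vec settings; none is
  prescribed by the method itself.
* **Boosting rounds.** The tuned booster parameters do not include the
  number of trees; 100 is the conventional default and is grid-searchable
  via `grid_search()`.
* **Zero synergy scores.** Only the sign of the score is used; records at
  exactly zero belong to neither class and are dropped with a count.
* **Unmapped targets.** Drug or cell-line proteins absent from the PPI
  network are filtered; entities whose whole target set is unmapped are
  dropped with a warning. Isolated network nodes are removed at load time
  because the DTW element cost is undefined at degree 0.
* **Repeats.** "Repeat five-fold CV five times" is read as 5 independent
  repetitions of a 5-fold split (25 fits); `repeats` is configurable, so
  the other reading (a single 5-fold pass) is `repeats = 1`.

## Determinism

Every stochastic stage takes a seed, and all seeds derive from one root via
a fixed integer hash: each walk has a private substream keyed by
(seed, pass, node), so corpus generation is stable under any execution
order; Skip-Gram runs single-threaded with its own LCG and reproduces
vectors bit-identically; fold assignment and the booster (with
`nthread = 1`) are seeded likewise. Regenerating a synthetic study from the
same seed reproduces its files byte-identically.

## What the synthetic generator emulates

Real drug-combination screens cannot be redistributed with the package, so
`make_synergy_study()` builds a self-contained study with a *planted,
role-borne* signal:

* The network is `make_role_graph()`: several copies of one random
  connected motif, sparsely bridged. Corresponding nodes across copies play
  the same structural role, which is exactly the equivalence a structural
  embedding must recover (bridges perturb it slightly).
* Each role $r$ carries a latent activity $v_r \in \{-1, +1\}$. Each drug
  and cell line prefers one role and draws its targets mostly (80%) from
  that role's nodes.
* A record's latent score is
  $\text{effect} \cdot s_c \cdot v(\text{cell role}) \cdot \max(v(\text{role A}), v(\text{role B})) + \mathcal{N}(0, \text{noise})$,
  with $s_c$ an optional per-cell-line strength. The statistic is symmetric
  in the two drugs, yields ~50/50 class balance, and — crucially — depends
  on node identity only through structural role, so a proximity-based
  embedding could not exploit it. At the defaults (20 drugs, 8 cell lines,
  2000 records, effect 1, noise 0.5) the positive fraction is 47.3% and
  the planted signal supports held-out AUC-ROC well above 0.9.

What the generator does **not** emulate: dose-response surfaces and the
computation of Loewe/ZIP scores from them, realistic degree distributions
of curated interactomes (the motif graph is small and regular-ish),
literature bias in drug-target annotation, and batch effects between
screens. Passing the synthetic end-to-end checks therefore demonstrates
that the machinery recovers structure-borne signal, not that it attains
any particular accuracy on a real screen.

## Problem sizes and numerical notes

The bundled studies are deliberately small so that the whole validation
suite — including three full pipeline runs for the dimension sweep —
completes in a few minutes on one core: a 48-node role network (6 motifs
of 8), 2000 records, 20 × 80 walks, dims 32/64/128. The structural
distance stage is all-pairs and scales as $O(n^2)$ DTW alignments per
layer; for genome-scale networks (~16k nodes) the same code applies but
the distance stage dominates and would call for the degree-pruning
approximation deliberately omitted here.

Numerical corner cases: pairs leave a layer when either ring empties
(beyond a node's eccentricity), and a walker stranded without same-layer
partners is forced to switch layers, so walks cannot stall; transition
normalisers $Z_k(u)$ are strictly positive wherever a partner exists;
ties in grid search resolve toward the simpler model (smaller depth, then
lower learning rate); groups with one class in stratified reporting give
`NA` AUC explicitly rather than disappearing.

## Known limitations

* All-pairs distances make genome-scale embedding expensive (hours, not
  seconds); this implementation favours exactness over the compression
  heuristics of large-scale structural-embedding codebases.
* The classifier sees only network-derived features; cell lines with few
  or unusual target annotations are hard to rank, which is visible in the
  per-cell-line AUC spread of `stratified_performance()`.
* Replicate records with conflicting signs are kept as-is; no attempt is
  made to reconcile inconsistent screen measurements.
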