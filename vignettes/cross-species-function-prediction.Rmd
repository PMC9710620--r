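---
title: "Cross-species protein function prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species protein function prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfun)
```

# The problem

Network-based function prediction assigns Gene Ontology (GO) terms to a
protein from the annotations of its neighbours in a protein-protein
interaction (PPI) network. When the species of interest (the *target*) is
sparsely annotated, a single network carries little labelled signal, but a
related, better-annotated species (the *model*) carries a great deal —
provided its proteins can be placed in a common space with the target's.
`crossfun` implements a dual-source scheme: a diffusion-state-distance
(DSD) embedding of the target network supplies within-species neighbours,
a landmark-anchored co-embedding of the target network into the model
network's similarity space supplies cross-species neighbours, and a
weighted k-nearest-neighbour vote over both neighbourhoods assigns ranked
GO labels.

# The models

## Diffusion state distance

For a connected network with row-normalised adjacency (random-walk) matrix
$P$, the diffusion state of node $u$ at walk length $t$ is

$$He^{t}(u) = e_u^\top \sum_{k=0}^{t} P^k,$$

the vector of expected visit counts of a $t$-step simple random walk
started at $u$ (the start counts as one visit, so each row sums to
$t + 1$). The DSD between $u$ and $v$ is
$\mathrm{DSD}(u,v) = \lVert He(u) - He(v)\rVert_1$; it is a metric and is
markedly less dominated by hub nodes than shortest-path or raw-walk
proximities.

Counting the start visit is a convention the literature leaves open; we
fix it because it makes $He^{0} = I$ (so the $t = 0$ state is well
defined) and it cancels in every difference $He(u) - He(v)$ for the same
$t$, hence never changes a DSD.

As $t \to \infty$ the visit counts themselves diverge (each row sums to
$t+1$) while all row *differences* converge, so DSD has a well-defined
limit. With stationary distribution $\pi$ (degree over twice the edge
count) and $W = \mathbf{1}\pi^\top$, the limiting differences are exactly
the row differences of the walk's fundamental matrix

$$Z = (I - P + W)^{-1},$$

so `converged_state()` returns $Z$ as the converged diffusion-state
object and `dsd_matrix()` of it is the closed-form converged DSD.
`converged_dsd(method = "iterative")` instead iterates the finite-$t$
definition until the DSD matrix moves less than `tol` (default `1e-8`,
step cap $10^6$) and serves as the independent check of the solve.

One caveat the convergence theorem hides: on a *bipartite* graph the walk
has eigenvalue $-1$ and the iterated DSD oscillates forever (on the
3-node path, $\mathrm{DSD}_t(a,b)$ alternates between 1 and 2; the
closed form returns the Cesàro value 1.5). The `lazy = TRUE` option
(stay-probability $1/2$) removes the periodicity and makes the iterative
and analytic routes agree on bipartite graphs; PPI networks in practice
contain triangles and are unaffected.

## Landmarks

Cross-species anchors are reciprocal best sequence hits: a pair $(u, v)$
such that $v$ is $u$'s best hit (by bitscore; ties broken by percent
identity, then lexicographically) and $u$ is $v$'s best hit, with both
direction rows meeting a percent-query-coverage threshold $q$ and a
percent-identity threshold $p$. Thresholds apply to *both* directions —
the stricter, reproducible reading of thresholding "the reciprocal best
hits". Defaults $(q, p) = (90, 85)$ suit closely related species
(human/mouse scale); the documented relaxed preset $(75, 50)$ is for
distant pairs such as the two yeasts, where the stringent setting leaves
too few landmarks to anchor an embedding. Raising either threshold can
only remove landmarks, and each protein appears in at most one pair.

## Co-embedding

The model network's similarity kernel $D_1$ is factorised through its
eigendecomposition as $N = \Upsilon \Lambda^{1/2}$, so that
$N N^\top = D_1$ and row $u$ of $N$ is the model protein's vector. Writing
$N_L$ for the landmark rows of $N$ and $T_L$ for the landmark rows of the
*target* kernel, the target vectors $\hat C_2$ are asked to satisfy
$N_L \hat C_2^\top = T_L$ — each target node's inner product with a model
landmark should equal its similarity to the corresponding target
landmark. The system is underdetermined; we take the minimum-norm
solution $\hat C_2^\top = N_L^{+} T_L$ (Moore-Penrose pseudoinverse via
SVD, singular values below $10^{-10}\sigma_{\max}$ treated as zero).
Cross-species similarities are then $D_{12} = N \hat C_2^\top$, a
(model × target) matrix.

Two numerical choices deserve note:

* **Kernel.** A diffusion-state matrix is neither symmetric nor positive
  semi-definite, but the factorisation needs real square roots of
  eigenvalues. We symmetrise ($\tfrac12(He + He^\top)$) and clip the
  negative part of the spectrum to zero; the `kernel` field stores the
  PSD matrix actually factorised, so $N N^\top$ reconstructs it to
  machine precision. In converged mode the state fed to the kernel is the
  fundamental matrix $Z$ (the finite-$t$ matrices have no limit); a
  regularized-Laplacian kernel $(I + \lambda L)^{-1}$ is exposed as an
  option for fidelity with the original co-embedding formulation.
* **Similarity vs distance.** $D_{12}$ holds *similarities*:
  cross-species neighbours are the columns' largest entries (descending).
  The within-target matrix `p_mat` is the pairwise $L_1$ distance matrix
  of target diffusion states — the target DSD — and neighbours there are
  *ascending*. Mixing these conventions up is the classic bug; the
  accessors `cross_neighbors()` and the vote code keep them straight.

When $N_L$ has full row rank the reconstructed landmark similarities are
exact ($N_L \hat C_2^\top = T_L$ to $10^{-8}$), and co-embedding a network
with itself using every node as a landmark returns the model kernel in
$D_{12}$, with each node's own copy as its top cross-neighbour — two
identities the test suite checks.

## The vote

For a target protein, the `d` nearest target-network nodes under DSD and
the `c` model-network nodes with highest co-embedding similarity are
polled. Each labelled target neighbour contributes weight `alpha` to each
of its GO terms; each labelled model neighbour contributes weight 1. A
term's confidence is its vote mass over the total polled mass, the top
`top_r` terms are emitted, and ties break lexicographically by term id
(then node id), making every prediction bit-reproducible. Defaults
`d = 20`, `c = 10`, `alpha = 1.5`, `top_r = 3` follow the recommended
settings from the original human/mouse tuning and transfer unchanged to
other species pairs. `c = 0` reduces the method exactly to single-network
DSD k-NN; `d = 0` to co-embedding-only k-NN.

**Neighbourhood semantics.** "The d nearest neighbours" can be read two
ways when some nodes are unlabelled. The default here is the *strict
window*: the neighbourhood is the d nearest nodes, and the labelled ones
among them vote. The alternative (`neighbor_mode = "labeled"`) skips
unlabelled nodes until d labelled voters are found. We default to the
strict window because it is the plain reading and because it keeps
neighbourhoods local: under sparse training labels the skip rule widens
the window until it swallows most of the training set, at which point the
target source degenerates into a constant global-majority prior that no
longer reflects network proximity at all. The effect is mild on large
networks (where d labelled neighbours are found nearby anyway) and severe
on the few-hundred-node networks of the synthetic study.

Six simple homology-transfer baselines are included for comparison; all
keep the α-weighted target-side vote and differ in the model-side voters:
the query's top hit; the top hit plus its `c` nearest model-DSD
neighbours; the first 100 hits; those plus each hit's neighbours; hits
passing the $(p, q)$ thresholds; and those plus neighbours. Model-side
voters are deduplicated and all carry weight 1 (the description of the
baselines does not distinguish hit from neighbour weights, so we do not
either). A query with no usable hits falls back to the target-only vote.

# Evaluation

Three measures, each computed per namespace (BP and MF are always
independent experiments):

* **Percent accuracy** — the share of test proteins whose rank-1 label is
  among their true labels; abstentions count as wrong.
* **Protein-centric F1-max** — precision at threshold $\tau$ averages
  only over proteins with at least one prediction at confidence
  $\ge \tau$, recall averages over all test proteins, and $F_1^*$
  maximises the harmonic mean over $\tau$. Since $F_1(\tau)$ is piecewise
  constant, the default grid is the sorted set of distinct emitted
  confidences, which attains the exact maximum.
* **Resnik similarity** — term information content is accumulated
  information accretion, $i(\ell) = \sum_{v \in \mathrm{anc}(\ell)}
  -\log \Pr(v \mid \mathrm{parents}(v))$; term-term similarity is the
  information content of the most informative common ancestor (the DAG
  generalisation of the least common ancestor, which is ambiguous on a
  DAG); set-set similarity averages the two directed max profiles, and
  the reported score maximises the test-set mean over the confidence
  grid. Natural log is the default base — the base rescales all scores
  uniformly and cancels nowhere, so it is fixed per analysis. Terms in
  disjoint DAG components share only a virtual root of zero content.
  When conditional probabilities are not supplied with the DAG they are
  estimated from an annotation corpus as the Clark-Radivojac frequency
  ratio count(v) / count(parents of v) after ancestor closure.

Truth and prediction sets are scored exactly as given by default.
CAFA-style ancestor propagation (close truth sets upward; propagate
prediction confidences to ancestors by maximum) is available via
`inverted_kfold(propagate = TRUE)` but off by default, because the
closed-form identities of the metrics — and like-for-like comparison with
methods that emit leaf terms only — are easier to reason about on raw
sets.

**Term filtering.** Before evaluation, GO terms are restricted to an
intermediate specificity band: terms annotating between `min_count` and
`max_count` proteins of the target network. The reference band is
(50, 500) for networks with thousands of annotated proteins and (50, 300)
for the smaller yeast-scale networks; for the 300-node synthetic study
below we scale it to (10, 150).

**Inverted cross-validation.** Ordinary k-fold CV trains on $k-1$ folds.
The inverted design trains on *one* fold and scores the other $k-1$, so
larger k means scarcer training labels — the regime cross-species
transfer is for. Five independent shuffles is the default (`n_runs`);
fold sizes are always within one protein of $A/k$. `grid_search()`
implements the companion tuning protocol: a 50/50 split into tuning and
validation halves, standard 5-fold CV on the tuning half only, and
configurations ranked by mean accuracy.

# The synthetic benchmark

Real BioGRID-scale inputs are external downloads; the `synth` generator
creates a paired-species benchmark that exercises every module without
any network access.

* **Topology.** The model network grows by duplication-divergence (a new
  node copies a random anchor's edges with retention 0.5 and always keeps
  at least one), giving the hub-dominated degree distribution DSD is
  designed to dampen. The target network copies a connected
  `n_orthologs`-node subgraph (breadth-first from a random seed), rewires
  each copied edge with probability `rewire_prob`, and grows fresh nodes
  by the same process.
* **Hits.** Planted ortholog pairs receive mutual hit rows whose
  identities and coverages are drawn from Beta distributions separated
  from the decoys'; `n_landmarks` of the pairs draw above the stringent
  (90, 85) preset and the rest between the relaxed (75, 50) and stringent
  presets, emulating that only a minority of true orthologs are stringent
  reciprocal best hits. Decoy bitscores sit strictly below ortholog
  bitscores and decoy pairs are never sampled in both directions, so the
  planted bijection is recoverable exactly — which pins down the expected
  output of landmark selection.
* **Labels.** Each GO term is a "functional module": a graph
  neighbourhood ball (5-15% of the network) around a seed node,
  instantiated in *both* networks with the target seed being the ortholog
  copy of the model seed where one exists. Members carry each of their
  ball's terms with probability `label_signal` (0.8), ortholog partners
  additionally inherit model labels with probability `conservation`
  (0.7), and 5% random noise labels are sprinkled on top. The DAG is
  layered with level-constant conditional probabilities decreasing with
  depth.

Defaults (`rewire_prob = 0.3`, `conservation = 0.7`) are chosen so that
the two vote sources carry comparable, complementary signal, which is the
regime reported on real close-species pairs — cross-species interactomes
share well under a fifth of their interactions, and functional
conservation between orthologs is substantial but far from perfect. With
near-isomorphic networks and near-perfect conservation the cross source
alone dominates and combining sources could only dilute it; that is a
property of an unrealistic generator, not of the method.

What the generator deliberately does **not** emulate: databased
interactome ascertainment bias (real BioGRID edges concentrate around
well-studied proteins), genetic-vs-physical edge semantics, sequence
evolution (hit tables are sampled, not aligned), multi-domain proteins
with one-to-many homology, and the heavy-tailed term-size distribution of
real GO. Passing the synthetic study therefore demonstrates that the
implementation is correct and that the method behaves as designed when
its assumptions hold — not that it will match any particular accuracy on
real data.

# Problem sizes and runtime choices

The packaged tests and the reproduction script run everything at desk
scale, chosen as the smallest sizes at which each property is
non-trivial: metric and equivariance checks on random graphs of 10-50
nodes; Monte-Carlo walk validation with $10^5$ walks per start node on a
10-node graph; landmark recovery on 70-node proteomes with 50 planted
orthologs and 30% decoy rate; and the headline study on 300-node paired
networks with 150 orthologs, 20 stringent landmark pairs, ~20 filtered
terms per namespace, and 10-fold inverted CV (one shuffle per seed, five
seeds). On these sizes the full cycle — embeddings by dense solves and
eigendecompositions, co-embedding, voting, and CV — completes in minutes
on one CPU. For real interactomes ($10^4$ nodes) the dense
eigendecomposition and linear solves are the bottleneck (hours, done once
per species pair and cached by content hash); the fast approximate-DSD
literature is the escape hatch the interface leaves room for but does not
implement.

# Known limitations

* Dense matrix algebra throughout: memory is $O(|V|^2)$; networks beyond
  a few tens of thousands of nodes need the approximate methods noted
  above.
* Landmark quality is the method's load-bearing assumption. For species
  pairs too distant for stringent reciprocal best hits, the relaxed
  preset trades landmark noise against landmark count, and beyond some
  distance no threshold setting yields a usable anchor set.
* Confidences are normalised vote masses, not calibrated probabilities;
  they order labels well but should not be read as posterior
  probabilities.
* Genetic and physical interactions are treated identically (an edge-type
  filter is available in the BioGRID reader for sensitivity analyses).
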