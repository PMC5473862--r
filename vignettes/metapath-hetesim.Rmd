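---
title: "Metapath HeteSim scores for lncRNA-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapath HeteSim scores for lncRNA-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetesimlpi)
```

## The problem

Long non-coding RNAs (lncRNAs) act largely by binding proteins, but
experimentally confirmed lncRNA-protein interactions cover only a small
fraction of the transcriptome. `hetesimlpi` prioritizes candidate
interactions from network context alone. It takes three weighted layers —
lncRNA-lncRNA co-expression similarity, lncRNA-protein association
evidence, and protein-protein interaction confidence — assembles them into
one heterogeneous network with two node types, `L` (lncRNA) and `P`
(protein), and asks, for every (lncRNA, protein) pair, how strongly the
network topology ties the two together.

The key idea is that *how* a walk gets from an lncRNA to a protein
matters. The path type `L-L-P` ("a similar lncRNA binds this protein")
and the path type `L-P-P` ("this lncRNA binds a partner of this protein")
carry different evidence, and longer path types carry weaker but still
informative signal. Each path type is therefore scored separately and the
per-path scores become the features of a classifier.

## Building the network

Edge lists are read from 3-column TSV files (`read_edge_list()`). When
several co-expression datasets report a correlation for the same gene
pair, `combine_coexpression()` merges them with a noisy-or rule,

$$C = 1 - \prod_{d} (1 - C_d), \qquad C_d > 0,$$

dropping non-positive correlations first (a negative correlation is not
evidence of association here; a pair supported by several datasets scores
higher than any single dataset alone).

`build_hetero_network()` applies a sparsification cutoff: edges with
weight at or below the cutoff are removed. Typical cutoffs are 0.3
(dense), 0.5, and 0.9 (sparse, high-confidence). Two choices are
deliberate defaults, both overridable in `network_config()`:

* **Binarization.** Retained edges are set to weight 1, so all walks run
  on 0/1 adjacency. The scoring theory below is defined for adjacency
  matrices; keeping weights (`binarize = FALSE`) is supported and simply
  feeds weighted rows into the same normalization.
* **Stable node universe.** Every identifier seen in any edge list keeps
  its index slot even if the cutoff isolates it, so feature matrices have
  identical dimensions across cutoffs and isolated nodes score 0 rather
  than disappearing.

Within-type layers are stored symmetrically with a zero diagonal —
self-similarity would add vacuous `L-L` or `P-P` hops — and every ordered
relation is stored together with its transpose.

## HeteSim along a metapath

A *metapath* is a sequence of node types, e.g. `LLPP`. For one edge
between types the *transition probability matrix* row-normalizes the
adjacency:

$$T_{LP}(i,j) = \frac{I_{LP}(i,j)}{\sum_k I_{LP}(i,k)},$$

and along a metapath $\mathcal{P} = (P_1 \cdots P_{n+1})$ the *reachable
probability matrix* is the ordered product
$R_\mathcal{P} = T_{P_1P_2} \cdots T_{P_nP_{n+1}}$: walk distributions
under the path's type constraint. A node with no edges in a relation
keeps an all-zero transition row — the 0/0 case is resolved as "no walk
mass", the only convention that keeps all scores in $[0,1]$.

HeteSim scores a pair by splitting the path at its midpoint, walking from
both endpoints toward it, and taking the cosine of the two arrival
distributions:

$$\mathrm{HeteSim}(l,p \mid \mathcal{P}) =
\frac{R_{\mathcal{P}_L}(l,:) \; R_{\mathcal{P}_R^{-1}}(p,:)^T}
     {\lVert R_{\mathcal{P}_L}(l,:)\rVert_2 \;
      \lVert R_{\mathcal{P}_R^{-1}}(p,:)\rVert_2},$$

where $\mathcal{P}_R^{-1}$ is the reversed right half. An even edge count
has one midpoint; an odd edge count is split at both candidate midpoints
and the two scores averaged with equal weight. A zero-norm row (no route
to the midpoint) scores 0 against everything. The measure is symmetric
($\mathrm{HeteSim}(l,p\mid\mathcal{P}) =
\mathrm{HeteSim}(p,l\mid\mathcal{P}^{-1})$), self-maximal, and bounded in
$[0,1]$ because all vectors are nonnegative.

The bundled three-type example network (`toy_network()`, types `L`, `T`,
`P`) makes this concrete:

```{r toy}
net <- toy_network()
transition_matrix(net, "L", "T")
round(hetesim_pairwise(net, parse_metapath("LTP", c("L", "T", "P"))), 4)
```

Note the contrast between walk *counts* and HeteSim: `l2` has a single
`T` neighbor shared with `p1`, and scores a perfect 1, while hub nodes
with many spread-out edges score lower — the cosine rewards concentrated,
mutual connectivity, not volume.

## From scores to a classifier

With only `L` and `P` types, there are exactly $2^{k-2}$ metapaths of $k$
nodes from an lncRNA to a protein, hence $2 + 4 + 8 = 14$ paths with 3-5
nodes (`enumerate_metapaths()`, `canonical_metapaths()`). Enumeration
orders paths by node count then lexicographically; the package ships a
manifest fixing the conventional id order 1-14 so feature columns are
reproducible.

`build_feature_table()` damps each path's score by $\beta^{k-2}$ — a
3-node path contributes at most $\beta$, a 4-node path $\beta^2$, a
5-node path $\beta^3$ — encoding that longer paths are semantically
weaker. Published sensitivity analyses and our own synthetic runs agree
that downstream accuracy is remarkably flat in $\beta$; the default 0.2
is taken from the better-performing region of that grid. $\beta$ enters
the features multiplicatively per column, so with standardized features
its main role is relative weighting across path lengths, which is why the
flatness is unsurprising.

The classifier is a support vector machine (`e1071::svm`) on the 14
damped scores. The published method specifies an SVM but neither kernel
nor regularization; the package defaults to an RBF kernel with cost 1 —
14 bounded, correlated features are well inside that kernel's comfort
zone — and exposes both in `classifier_config()`. Features are
standardized with statistics fitted on the training rows only;
zero-variance columns (e.g. a path absent from a sparse network) pass
through unscaled instead of producing NaNs. Ranking and ROC analysis use
the signed decision value, not calibrated probabilities; only the order
matters for the metrics reported here.

Training pairs (`sample_training_pairs()`) follow the asymmetric-cutoff
recipe: positives are edges of the sparse high-confidence network (0.9
cutoff), negatives are sampled from pairs with *no* edge in the dense
network (0.3 cutoff) — absence from even weak evidence is the most
conservative available notion of non-interaction. Classes are balanced by
construction, a mandatory gold-standard set can be forced into the
positives, and every draw is seeded.

## Evaluation

`loocv()` holds out each labeled pair in turn. Leakage is controlled by
deleting the held-out pair's own association edge from the network before
recomputing that pair's features; training pairs keep their full-network
features, and the classifier is retrained in every round. (Deleting the
held-out *nodes*, a literal reading of "remove all connected lncRNAs and
proteins", would make the pair unscorable; an optional `strict` mode
additionally removes the pair's other incident association edges.)
`independent_test()` fits once on a training set and evaluates a disjoint
test set whose positive edges are all removed before test features are
computed; any train/test overlap is an error, not a warning.

Confusion metrics follow the standard definitions (SEN, SPE, ACC, PRE,
MCC, F1) at a configurable decision threshold (default 0 — the published
protocol does not state its operating point). Zero-denominator cases
return 0 with a warning. The ROC curve steps over all distinct score
thresholds, tied scores sharing a step, and the AUC is computed as the
Mann-Whitney statistic with the half-tie convention; the test suite
verifies it equals the trapezoidal area under the returned curve to
1e-10.

## The synthetic generator

Real co-expression and interaction networks require large external
downloads, so the package tests itself on seeded block-structured
networks (`synthetic_spec()`, `generate_network()`): lncRNAs and proteins
are assigned to functional blocks; association edges appear with
probability 0.6 within a block and 0.05 across; within-type similarities
are 1 inside a block and 0 outside, perturbed by half-normal noise of
scale 0.1 and truncated to [0, 1], so the usual cutoffs separate planted
from spurious similarity. Similarities are generated directly on the
[0, 1] scale rather than via simulated expression profiles and Pearson
correlation — simpler, and sufficient to exercise cutoff behavior.
Ground truth is block co-membership. Defaults are 60 lncRNAs, 40
proteins, 4 blocks, seed 7: large enough that a full 14-path
leave-one-out run over 200 pairs completes in well under a minute on one
CPU, small enough to keep the whole test battery fast.

What the generator does *not* emulate: scale-free degree structure, hub
proteins, tissue-specific expression blocks, correlated evidence channels
(STRING scores and co-expression are independent here), or label noise in
the gold standard. Passing recovery tests on these networks demonstrates
that the scoring and evaluation machinery is correct and that planted
topological signal is recoverable end to end — not that any particular
accuracy will transfer to real interactomes.

## Numerical choices, in one place

* Zero-degree rows stay zero in transition matrices; zero-norm rows score
  0 in cosines.
* Odd-path splits are averaged with equal weights.
* Dense base-R matrices throughout: the intended regime (hundreds to a
  few thousand nodes) never makes the matrix chain the bottleneck, and
  the implementation is required by its tests to match a brute-force
  walk-enumeration oracle to 1e-10, which it does with or without the
  per-network transition-matrix cache.
* Ranking ties break by protein identifier, ascending, so ranked lists
  are fully deterministic.
* All sampling and training goes through explicit integer seeds via
  `withr::with_seed`; the caller's RNG state is never touched.

## Problem sizes used in the test battery

Oracle-equivalence checks run on random networks up to 8 nodes per type
across all 14 paths; symmetry and range properties on 100 seeded random
networks; the recovery run uses the default 60 x 40 network with 100
positive and 100 negative ground-truth pairs (leave-one-out, retraining
each round) plus a label-permutation null and a 50/50 independent split;
ROC equivalence uses 1000 random score vectors. These sizes are the
package's chosen desk-scale battery: small enough to run routinely,
large enough that every code path — odd and even splits, dead ends,
ties, degenerate rounds — is exercised.

## Limitations

* Scores are relative within a network; cutoff choice changes them, and
  cross-network score comparison is meaningless without re-training.
* The negative-sampling definition (non-edges of the dense network) can
  label true-but-unobserved interactions as negatives; reported
  specificity is correspondingly conservative.
* Only one relation per type pair is supported (no multi-channel edges),
  and relations are undirected.
* Leave-one-out with per-round retraining is quadratic-ish in the labeled
  set; thousands of pairs call for the independent-test protocol instead.
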