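# hetesimlpi

Predicting lncRNA–protein interactions from heterogeneous network
topology with metapath-constrained HeteSim scores.

Long non-coding RNAs work largely by binding proteins, yet confirmed
lncRNA–protein interactions are scarce. `hetesimlpi` ranks candidate
interactions using only network context: it assembles an lncRNA–lncRNA
co-expression similarity layer, an lncRNA–protein association layer and a
protein–protein interaction layer into one two-type heterogeneous
network, scores every (lncRNA, protein) pair along each metapath
(type-constrained walk pattern such as `L-L-P` or `L-P-P-P`), and
combines the per-path scores with an SVM.

## The score

For a relation with adjacency `I`, the transition matrix row-normalizes
it, `T(i,j) = I(i,j) / Σ_k I(i,k)`, and a metapath
`P = (P_1 … P_{n+1})` has reachable probability matrix
`R_P = T_{P1P2} ⋯ T_{PnPn+1}`. HeteSim splits the path at its midpoint,
walks from both endpoints toward it, and takes the cosine of the two
arrival distributions:

```
HeteSim(l, p | P) = R_PL(l,:) · R_PR⁻¹(p,:)ᵀ / (‖R_PL(l,:)‖₂ ‖R_PR⁻¹(p,:)‖₂)
```

(odd-length paths are split at both candidate midpoints and averaged).
With types `{L, P}` there are exactly fourteen 3–5-node paths from an
lncRNA to a protein; each path's score, damped by `β^(nodes−2)` to
discount longer walks, is one feature of the classifier. Evaluation
covers leave-one-out cross-validation with per-pair edge removal (so a
pair never sees its own edge in its features), independent tests,
SEN/SPE/ACC/PRE/MCC/F1 and ROC/AUC.

## Worked example

The package bundles the small three-type network used to illustrate the
score by hand (3 lncRNAs, 4 intermediate nodes, 2 proteins):

```r
library(hetesimlpi)
net <- toy_network()
round(hetesim_pairwise(net, parse_metapath("LTP", c("L", "T", "P"))), 4)
#>        p1     p2
#> l1 0.0000 0.4082
#> l2 1.0000 0.5774
#> l3 0.5774 0.6667
```

`l2` touches a single intermediate node that `p1` also touches, so its
walk distributions coincide and the pair scores a perfect 1; `l1` shares
nothing with `p1` and scores 0. The cosine rewards concentrated mutual
connectivity, not edge counts.

The full pipeline on a seeded synthetic network with planted
block-interaction structure (60 lncRNAs, 40 proteins, 4 blocks):

```r
sim <- generate_network(synthetic_spec())
lab <- subsample_labeled(sim$truth, 100, 100, seed = 2)
res <- loocv(sim$network, lab, canonical_metapaths(), classifier_config(seed = 3))
sprintf("LOOCV AUC = %.3f  ACC = %.3f  MCC = %.3f",
        res$metrics$auc, res$metrics$ACC, res$metrics$MCC)
#> "LOOCV AUC = 1.000  ACC = 1.000  MCC = 1.000"
```

The planted signal is fully recovered: every held-out pair is ranked on
the correct side. (Permuting the labels drops the AUC to ≈ 0.5; the test
suite checks both.) Ranking candidate partners for one lncRNA:

```r
ft  <- build_feature_table(sim$network, lab, canonical_metapaths(), 0.2)
clf <- train_classifier(ft, lab, classifier_config(seed = 3))
head(rank_candidate_proteins(sim$network, clf, "l001"), 3)
#>   protein    score rank
#> 1    p037 1.095476    1
#> 2    p021 1.093065    2
#> 3    p025 1.086845    3
```

All three top-ranked proteins belong to `l001`'s block.

A thin command-line front end (`inst/cli/hetesimlpi.R`) wraps the same
functions: `simulate`, `score`, `train`, `predict`, `loocv` on TSV edge
lists. See `vignettes/metapath-hetesim.Rmd` for the model, its
assumptions and the numerical conventions.

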