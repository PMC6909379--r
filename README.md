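# idlda

Ranking candidate lncRNA–disease associations by similarity-ensemble
resource diffusion on a bipartite network.

## The problem

Long non-coding RNAs (lncRNAs) are implicated in many human diseases, but
experimentally verifying individual lncRNA–disease associations is slow and
expensive. Given a catalogue of verified associations — a bipartite graph
with diseases on one side and lncRNAs on the other, encoded as a binary
adjacency matrix `A` (`N_d × N_l`, diseases in rows) — the task is to rank
every *unverified* pair by how likely it is to be a real association, so
that experimental effort can be focused on the top of the list. The guiding
assumption is the standard one in this field: phenotypically similar
diseases tend to involve functionally similar lncRNAs, and vice versa.

This package is written for computational biologists who have (or can
simulate) such an association table, plus optionally a table of MeSH
Category-C tree numbers for the diseases.

## The model

Two similarity ensembles are built from the data:

* **Disease side.** Each MeSH-annotated disease defines a DAG: its
  tree-number coordinates plus all ancestors. Node `t` of disease `d`'s DAG
  contributes `C_d(t) = Δ^k` (decay `Δ = 0.5` by default, `k` = hop
  distance to the disease's own nodes), and the semantic similarity of two
  diseases is the contribution mass on their shared nodes divided by the
  sum of their total masses:
  `SS_ij = Σ_{t∈V(i)∩V(j)} (C_i(t) + C_j(t)) / (C(d_i) + C(d_j))`.
  A Gaussian interaction-profile kernel over the rows of `A`,
  `KD_ij = exp(−γ_d ‖IP(d_i) − IP(d_j)‖²)` with `γ_d` scaled by the mean
  squared profile norm, fills in for diseases without MeSH coverage:
  `DS_ij = (SS_ij + KD_ij)/2` where `SS_ij ≠ 0`, else `KD_ij`.
* **lncRNA side.** Functional similarity `FS_ij` is the best-match average
  of `SS` between the two lncRNAs' associated disease sets, and the
  analogous kernel `KL` over the columns of `A` gives
  `LS_ij = (FS_ij + KL_ij)/2` where `FS_ij ≠ 0`, else `KL_ij`.

The adjacency is then smoothed into two ensemble association matrices,
`DA = DS·A` and `LA = A·LS`, and scores come from a two-pass
resource-allocation diffusion: for seed disease `u`, resources seeded by
row `u` of `LA`/`DA` flow lncRNAs → diseases (splitting each lncRNA's
column proportionally; mixing weight `α` between the `LA`- and `DA`-guided
flows) and back diseases → lncRNAs (splitting each disease's row; weight
`β`). The result is a relevance matrix `R` whose row `u` ranks all lncRNAs
for disease `u`; because a new disease still has nonzero `DA` entries
through its semantic similarity to known diseases, the model can score
diseases (and, via the kernel, lncRNAs) with no known associations at all.

Defaults are `α = 0.3`, `β = 0.5`, `Δ = 0.5`, `γ′_d = γ′_l = 1`.

## Worked example

```r
library(idlda)

spec   <- synthetic_spec(seed = 42)   # 20x20, two planted blocks
net    <- make_network(spec)
forest <- make_forest(spec)
net
#> Bipartite association network
#>   diseases: 20   lncRNAs: 20   associations: 161   density: 0.4025

fit <- idlda(net, forest, alpha = 0.3, beta = 0.5)
head(predict(fit, disease = "disease001"), 5)
#>      disease    lncrna    score rank known
#> 1 disease001 lncrna009 3.891904    1     0
#> 2 disease001 lncrna001 3.561321    2     0
#> 3 disease001 lncrna011 3.540453    3     0
#> 4 disease001 lncrna004 2.784832    4     0
#> 5 disease001 lncrna010 2.665491    5     0

loocv(net, forest)
#> loocv: 161 positives, 1889 negatives, AUROC=0.8323

enrichment(fit, net, x = 40)
#> fold enrichment (bin size 40, 10 bins, 161/400 verified)
#>   top bins: 2.30 2.24 2.05 1.43 0.99
```

The prediction table lists, for one disease, the candidate (not yet
verified) lncRNAs in descending relevance order. The leave-one-out AUROC
of 0.83 says that a held-out true association outranks a random
non-association 83% of the time, every similarity matrix being recomputed
without the held-out edge. The fold-enrichment scores show verified
associations concentrated ~2.3× above chance in the top rank bins.

A command-line interface wrapping the same functions lives at
`inst/cli/idlda.R`:

```sh
Rscript inst/cli/idlda.R simulate --out-dir data --seed 7
Rscript inst/cli/idlda.R loocv --associations data/associations.tsv \
    --mesh data/mesh.tsv --out-dir results
```

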