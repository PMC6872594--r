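# hubfisher

Hub-gene identification for labelled tumor expression data: Fisher-score
feature ranking, over-representation filtering, Maximal Clique Centrality
(MCC) hub scoring on a protein-interaction network, and Kaplan–Meier /
log-rank survival evaluation of the resulting hub panel — with seeded
synthetic-data generators that provide planted ground truth for every
stage.

## Who this is for

Analysts working with genes × samples expression matrices (microarray or
similar log2-scale data) carrying tumor/normal labels, who want a
transparent, fully reproducible route from a raw matrix to a short list of
network-central candidate genes, and a way to validate each step of that
route against known truth before trusting it on real cohorts.

## The method

**Fisher score.** Gene *l* with classes *k* of sizes *n<sub>k</sub>*, class
means μ<sub>k</sub><sup>l</sup>, class standard deviations
σ<sub>k</sub><sup>l</sup> and grand mean μ<sup>l</sup> is scored

> f(l) = Σ<sub>k</sub> n<sub>k</sub>(μ<sub>k</sub><sup>l</sup> − μ<sup>l</sup>)² / Σ<sub>k</sub> n<sub>k</sub>(σ<sub>k</sub><sup>l</sup>)²

— between-class scatter over within-class scatter, computed per gene, so
the top-k feature subset (default k = 1000) consists of individually
discriminative genes. ReliefF, random-forest permutation importance and a
lasso ranking are available as drop-in comparison selectors.

**MCC.** On the interaction subgraph induced by the feature genes that are
over-represented in at least one supplied gene set (hypergeometric p <
0.05 **and** overlap count > 10), each node is scored

> MCC(v) = Σ<sub>C ∈ S(v)</sub> (|C| − 1)!

over the maximal cliques C containing v; the top ten nodes are the hub
panel. **Survival.** Each hub median-splits a cohort into high/low
expression groups compared by the log-rank test, with the O/E hazard-ratio
estimator flagging whether high expression is the adverse direction.

Supporting modules: probe-to-symbol collapsing and multi-dataset
integration, PCA batch-effect detection with per-gene linear-model removal,
and a GSEA core (signal-to-noise ranking, weighted KS running sum,
gene-set permutation null with NES/FDR).

## Worked example

Everything below is synthetic, with planted truth, so the output can be
checked against what was planted:

```r
library(hubfisher)

cfg <- synthetic_config(n_genes = 300, n_informative = 30,
                        n_tumor = 100, n_normal = 100, n_modules = 0, seed = 1)
sim <- simulate_expression(cfg)
sets <- list(PLANTED = sim$truth$informative_genes,
             DECOY = sim$expression$gene[101:160])
ppi <- simulate_ppi(nodes = sim$truth$informative_genes,
                    hub_cliques = 3, clique_size = 5, background_p = 0.03,
                    seed = 1)
cohort <- simulate_survival(sim$expression, sim$sample_info,
                            ppi$truth$planted_hub, cfg)

res <- run_pipeline(sim$expression, sim$sample_info, sets, ppi$graph,
                    cohort = cohort, k = 50, hub_k = 10, seed = 1)
res
```

```
[input] genes=300 samples=200
[rank] method=fisher ranked=300 feature_set=50
[ora] sets_tested=2 significant=1 enriched_genes=30
[hubs] nodes=30 edges=35 hubs=10
[survival] hubs_tested=10 significant=1
Hub-gene identification pipeline
  selector: fisher | feature set: 50 genes | enriched: 30 | hubs: 10
  hubs: g00001, g00005, g00011, g00002, g00012, g00003, g00004, g00006, g00007, g00008
  survival: 1/10 hubs with log-rank p < 0.05
```

The per-stage lines report how many genes survive each step; the invariant
`hubs ⊆ enriched genes ⊆ feature set` is asserted at run time. `tidy(res)`
returns the hub table:

```
    rank gene     mcc degree      p_value hazard_ratio direction
 1     1 g00001    75     13 0.0000000114        3.87  high-worse
 2     2 g00005    26      5 0.865               1.04  high-worse
 3     3 g00011    26      5 0.792               0.938 low-worse
 ...
```

Reading it: `g00001` — the planted hub — tops the MCC ranking (score 75
versus ≤ 26 for every other node), and because the cohort's hazard was tied
to its expression, its high-expression group shows a 3.9-fold excess hazard
with log-rank p ≈ 1e-8, flagged `high-worse`. The other hubs' p values are
null, as they should be: no hazard was planted on them.

A thin command-line wrapper with `simulate`, `collapse`, `integrate`,
`batch-detect`, `batch-correct`, `rank`, `ora`, `gsea`, `hubs`, `survival`,
`run` and `compare` subcommands is installed at `inst/cli/hubfisher`; all
its I/O is TSV/GMT.

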