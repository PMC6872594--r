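---
title: "Identifying tumor hub genes with the Fisher score and Maximal Clique Centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tumor hub genes with the Fisher score and Maximal Clique Centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubfisher)
```

## The problem and the method

Bulk tumor expression studies routinely face far more genes than samples: a
microarray panel measures tens of thousands of probes on at most a few
hundred tumor/normal pairs. hubfisher implements a filter-then-network
strategy for nominating *hub genes* — genes whose proteins sit at the centre
of a dense interaction neighbourhood among the class-discriminative genes —
and for checking whether those hubs carry prognostic signal.

The pipeline has five stages.

1. **Feature ranking with the Fisher score.** For gene $l$ measured on
   classes $k = 1,\dots,C$ with $n_k$ samples, class means $\mu_k^l$, class
   standard deviations $\sigma_k^l$ and grand mean $\mu^l$,
   $$f(l) = \frac{\sum_k n_k (\mu_k^l - \mu^l)^2}{\sum_k n_k (\sigma_k^l)^2}.$$
   This is the coordinate-wise decomposition of the global trace ratio of
   between-class to within-class scatter: each gene is scored independently,
   so the selected subset consists of individual genes rather than linear
   combinations, and the score is invariant to affine rescaling of a gene.
   The top $k$ genes (default 1000, the conventional panel size for tumor
   feature subsets) form the feature set.
2. **Over-representation filtering.** The feature set is tested against a
   user-supplied gene-set collection (GMT) with the upper-tail
   hypergeometric test over the measured universe, Benjamini–Hochberg FDR
   across sets, and the joint significance rule *p < 0.05 and overlap
   count > 10*. Genes belonging to at least one significant set form the
   enriched gene list; if nothing is significant the pipeline stops with an
   error rather than silently passing every gene through.
3. **Hub scoring with Maximal Clique Centrality (MCC).** On the interaction
   subgraph induced by the enriched genes,
   $$\mathrm{MCC}(v) = \sum_{C \in S(v)} (|C| - 1)!$$
   where $S(v)$ is the set of maximal cliques of size $\ge 2$ containing
   $v$; isolated nodes score 0. MCC rewards membership in large dense
   cliques much more than raw degree does, which is why it discriminates
   protein-complex hubs well. The top ten nodes (the conventional hub-panel
   size) are the hub genes.
4. **Survival evaluation.** Each hub dichotomizes the cohort at its median
   expression (ties go to the low group); the high and low groups are
   compared with the Kaplan–Meier product-limit estimator and the two-group
   log-rank test, with the observed/expected hazard-ratio estimator
   determining whether high expression is the adverse direction.
5. **Selector comparison.** ReliefF, random-forest permutation importance
   and an L1-penalized (lasso) ranking are drop-in alternatives to the
   Fisher score, and `compare_methods()` tabulates the hub-list overlaps
   across arms (the tabular form of a Venn diagram).

## Assumptions

* Expression values are on a roughly Gaussian (log2) scale and already
  normalized; the package performs no probe-level preprocessing.
* Classes are defined per sample (tumor/normal) with at least two samples
  per class; the Fisher denominator uses the sample standard deviation
  (ddof = 1) — the formula leaves the estimator unspecified, so this is a
  documented choice.
* Batch effects are additive and gene-specific, which is exactly the
  structure a per-gene linear model with sum-to-zero batch indicators can
  remove. Empirical-Bayes shrinkage (ComBat-style) is deliberately out of
  scope.
* Censoring is independent of the event process (the generator uses
  administrative censoring, the simplest mechanism with that property).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 1000 | feature-subset size; the conventional size for tumor panels |
| `hub_k` | 10 | hub-panel size |
| `ora_p`, `ora_min_count` | 0.05, 10 | the joint enrichment filter (p strictly below, count strictly above) |
| `min_confidence` | 0.4 | edge-confidence cutoff for interaction exports; the common medium-confidence convention, configurable |
| GSEA `n_perm`, `min_size`, `max_size` | 1000, 10, 500 | gene-set-permutation null with the usual set-size window |
| `relieff_m`, `relieff_neighbors` | 100, 1 | iterations and neighbours; the single-neighbour update is the reference form, `n_neighbors > 1` averages over k hits/misses |
| lasso `alpha` | required | L1 penalty; no default is pretended to be canonical — the ranking is a comparison arm and `alpha` is study-specific |
| `n_trees` | 500 | forest size for the permutation-importance arm |

## What the synthetic generators emulate

`simulate_expression()` draws gene-wise independent Gaussian log2 values
around per-gene baselines ($\mathcal{N}(7, 1)$), then layers three planted
structures with known truth:

* **informative genes** get a class-mean shift `effect_size` in tumor
  samples (default 0.75 log2 units = 1.5 within-class standard deviations
  at the default `base_sd` 0.5 — the regime in which a variance-ratio
  filter should recover essentially all planted genes);
* **correlated modules** share a latent standard-normal factor scaled so
  the pairwise within-block correlation is `module_rho` (default 0.7, a
  typical co-expression-module strength); by default module blocks are
  disjoint from the informative genes, with `overlap_modules = TRUE`
  available for correlated-duplicate experiments;
* **batches** add one Gaussian offset per gene-by-batch cell
  (`batch_shift_sd`, default 1) — precisely the structure the correction
  stage can remove exactly.

`simulate_ppi()` plants a hub inside `hub_cliques` otherwise-disjoint
cliques of `clique_size` nodes, giving the closed-form score
`hub_cliques * (clique_size - 1)!` when `background_p = 0`, and adds
independent background edges otherwise. `simulate_survival()` draws
exponential event times with hazard
$h_0 \exp(\beta z)$, $z$ the standardized expression of a chosen gene
(defaults $\beta = 0.7$ per SD, $h_0 = 0.1$), and censors administratively
at the cutoff whose expected censored fraction is `censor_rate`
(default 0.3).

What the generators do **not** emulate: heavy-tailed or intensity-dependent
microarray noise, probe-level artefacts, correlated (informative)
censoring, and interaction networks with realistic degree distributions
beyond the planted-clique-plus-noise structure. Passing the validation
suite therefore demonstrates algorithmic correctness and calibration under
the stated model, not robustness to every property of real cohorts.

## Numerical choices

* **Ties.** Every ordering in the package is deterministic: rankings break
  score ties lexicographically by gene id; hub ordering falls back from MCC
  to degree to gene id; the GSEA ranking metric breaks ties
  lexicographically; the median split sends values equal to the median to
  the low group.
* **Degenerate genes.** A gene constant everywhere has Fisher score 0
  (0/0); a gene with zero within-class variance but distinct class means
  scores `Inf` and ranks above all finite scores, so perfect separators are
  never dropped by NaN handling. The GSEA signal-to-noise denominator is
  floored at 1e-8 with a warning when both class standard deviations are
  zero.
* **Lasso.** Cyclic coordinate descent on internally standardized genes
  (mean 0, variance 1 with denominator $n$), convergence when the largest
  coefficient change in a sweep falls below 1e-8, at most 1e5 sweeps,
  explicit error on non-convergence. The response is the 0/1 class label
  under squared loss; a logistic variant is out of scope.
* **MCC arithmetic.** Factorial sums are computed in double precision,
  which is exact for integers up to $2^{53}$ — cliques of up to 19 members.
  Interaction networks whose maximal cliques exceed that are outside the
  intended regime and would need big-integer arithmetic.
* **Batch correction.** Sum-to-zero batch encoding so the intercept is the
  per-gene grand mean; only the fitted batch component is subtracted, then
  each gene is re-centred so its grand mean is preserved exactly. The
  operation is a projection (idempotent), and with `preserve_labels = TRUE`
  (the default) class indicators are in the design so within-batch
  tumor/normal contrasts are untouched. The default is the safer choice
  when classes are partially confounded with batch; `preserve_labels =
  FALSE` reproduces the unprotected fit.

## Design decisions that were genuinely open

* **Collapse before correction.** Probe-to-symbol collapsing (drop probes
  with zero or multiple symbols, average multiple probes per symbol) runs
  before batch correction in `run_pipeline()`; the reverse order would
  correct probe-level rows that are later averaged anyway, and fixing one
  order keeps runs comparable. The CLI help documents the fixed order.
* **ORA universe.** The hypergeometric universe is the full collapsed gene
  list of the analysed matrix, not the feature subset — the subset is the
  query, and testing it against a universe it defines would be circular.
* **Enrichment statistic.** A transparent raw hypergeometric tail is used
  (not the EASE-adjusted variant some annotation services report), because
  it is exactly enumerable and therefore testable.
* **GSEA null.** Gene-set permutation (random same-size gene sets), not
  phenotype permutation; NES divides ES by the mean absolute null ES of
  matching sign, and the FDR q uses the standard pooled-NES procedure.
* **Hazard-ratio estimator.** The observed/expected ratio
  $(O_1/E_1)/(O_2/E_2)$ rather than a fitted proportional-hazards model —
  it needs no iteration, inverts exactly under group swap, and is the
  quantity the log-rank table already contains.
* **Median split only.** An "optimal cutoff" scan is intentionally not
  implemented: scanning cutoffs inflates type-I error unless corrected, and
  the median split is the analysis whose calibration this package
  demonstrates.
* **Unhoused formalism.** Decision-system notation sometimes attached to
  neighbourhood-based feature selection (a universe with a neighbourhood
  radius $\delta$) plays no computational role in the per-gene score and
  has no counterpart here.

## Validation problem sizes

The test suite validates each component against independent oracles at
sizes chosen so exhaustive enumeration stays exact: maximal-clique
enumeration and MCC against a full $2^n$ subset scan on 200 random graphs
with up to 12 nodes; hypergeometric p values against complete draw
enumeration for universes up to 12; the GSEA running sum against a
step-by-step walk on 10-gene lists; log-rank calibration on 1000 null
cohorts of n = 100 and power on 200 cohorts of n = 364 (a typical liver
cohort size) at $\beta = 0.7$; batch-separation decrease across 100 seeded
two-batch matrices; and the full pipeline on a 300-gene, 50-sample bundle
with a planted hub. `scripts/acceptance.R` re-runs the same checks from a
single seed and writes the resulting rates and errors as JSON.

## Known limitations

* Only the additive linear-model batch correction is provided; strong
  nonlinear or variance-inflating batch effects are out of scope.
* The lasso arm uses squared loss on the 0/1 label; coefficients are not
  odds ratios.
* MCC is computed exactly via complete maximal-clique enumeration, which is
  exponential in the worst case; it is intended for enrichment-restricted
  subnetworks (hundreds of nodes), not genome-scale graphs.
* The survival module implements two-group comparisons only — no Cox
  regression, covariate adjustment, or restricted-time analyses.

## A worked miniature

```{r example, message = FALSE}
cfg <- synthetic_config(n_genes = 300, n_informative = 30,
                        n_tumor = 25, n_normal = 25, n_modules = 0, seed = 1)
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
tidy(res)
res$hubs[1] == ppi$truth$planted_hub
```
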