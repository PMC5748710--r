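---
title: "Methods: MIS-based gene-set association and class ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIS-based gene-set association and class ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misrank)
```

## The model

misrank quantifies how strongly each member of a disease-gene class
interacts with a query gene set on a confidence-weighted PPI network, and
aggregates those per-gene signals into a class-level ranking. The approach
is guilt-by-association in its most literal form: a gene's evidence is its
single strongest interaction with the query set, not a diffusion or
shortest-path statistic. That makes the score interpretable (it is an edge
you can look up) and robust to the long tail of low-confidence edges, at
the cost of ignoring multi-edge convergence: a gene with ten medium-score
links to the query scores lower than one with a single strong link.

For gene $g$ and query set $Q$ on a network with symmetric integer edge
scores $S(\cdot,\cdot)$:

$$\mathrm{MIS}(g) = \max\{\, S(g, g') : g' \in Q,\ g' \neq g \,\},$$

with $\mathrm{MIS}(g) = 0$ if no edge connects $g$ to $Q$. Raw MIS values
are incomparable across genes — a promiscuous hub reaches high scores
against *any* set — so each gene is calibrated against random sets
$D_1,\dots,D_n$ of size $|Q|$ drawn uniformly from the node universe:

$$\Lambda(g) = \#\{\, i : \mathrm{MIS}_i(g) > \mathrm{MIS}(g) \,\},
\qquad p(g) = \Lambda(g)/n .$$

Per class, the empirical distribution of $p$-values is summarised by the
proportion–threshold (PT) curve $t \mapsto \#\{p < t\}/m$ and its area
under the curve, which the package computes in closed form:
$\mathrm{AUC} = \operatorname{mean}(1 - p)$. Classes are ranked by AUC.

## Conventions and their consequences

**Strict exceedance, no +1 correction.** $\Lambda$ counts random sets
whose MIS is *strictly higher* than the observed one, and $p = \Lambda/n$
exactly. Consequently $p = 0$ is attainable and ties count in the gene's
favour: relative to the conventional $(\Lambda+1)/(n+1)$ estimator this is
anti-conservative whenever the null MIS distribution has atoms. Two
situations create atoms. First, discrete scores: two candidate sets often
share the gene's single top neighbour, tying at its score. Second, the
degenerate atom at zero: a gene with *no* neighbours at all has observed
MIS $= 0$ and every $\mathrm{MIS}_i = 0$, hence $\Lambda = 0$ and $p = 0$ —
an isolated gene looks maximally significant, not maximally null. Genes
should therefore be filtered to the network (the readers do this), and
null AUCs sit slightly above 0.5 (quantified below) rather than at it. We
keep the strict rule because it is the estimator the method is defined
with; the bias is a property of the method, documented rather than
patched.

**Self-exclusion.** $g$ is removed from $Q$ (and from any $D_i$) before
taking the maximum, so a gene belonging to both the query set and a
disease class cannot match itself. On loop-free networks this only matters
for set membership, but the convention is applied uniformly.

**One shared null.** The $n$ random sets are drawn once per run (seeded)
and reused for every gene of every class, so all p-values are comparable
against the same null draw and a run is exactly reproducible from
`(inputs, seed)`. The null draws sets from *all* network nodes, query
members included — the least assumptive universe; excluding the query
would shift every null MIS slightly downward.

**Exact AUC.** The PT curve is a step function, and its exact integral
over $[0,1]$ is $\operatorname{mean}(1-p)$ (each gene contributes the
interval $(p_i, 1]$). The package uses this closed form everywhere; a
trapezoid variant on a regular grid (`pt_auc_grid()`, step $h$, error
$\le h/2$) exists for plotting and cross-checks. The default threshold
grid is $\{0, 1/n, \dots, 1\}$ — the only points where the curve can step,
since p-values live on that grid. With the strict `<` in the proportion, a
gene at $p = 1$ contributes zero area.

**Determinism.** Ranking ties (equal AUC) break lexicographically by
class name; records are independent of gene iteration order; repeated runs
of `run_study()` with one configuration produce byte-identical tables.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_permutations` | 1000 | null sets; p-value resolution is $1/n$ |
| `min_score`, `max_score` | 150, 999 | accepted score range of the input network (STRING combined scores); bounds are validation, not a transformation |
| random-set size | $|Q|$ after filtering | matches the null to the query set's size |
| `report_cutoff` | 0.05 | presentation filter for the significant-gene table; never used inside scoring |
| `seed` | — | drives the single random-set draw |

1000 permutations give p-value resolution 0.001, matching the precision at
which published per-gene tables in this literature are reported. The test
and benchmark studies in this package use 50–200 permutations: resolution
0.005–0.02 is ample for class-level AUCs averaged over tens of genes.

## What the synthetic generator emulates

`generate_study()` builds an Erdős–Rényi network with independent integer
edge scores, assigns disjoint (by default) query and class gene blocks,
and plants the association signal directly in the mechanism the statistic
measures: each class gene receives, with probability `strength`, one edge
to a random query member with a uniform score in a high band. `strength`
is the ground truth the pipeline should recover.

Defaults, chosen once as desk-scale analogues of a genome-scale STRING
study:

* **`n_proteins = 200`, `edge_probability = 0.1`** — mean degree ≈ 20.
  A score-thresholded human STRING network is dense (mean degree in the
  hundreds over ~19k proteins); preserving its literal density at 200
  nodes (mean degree ≈ 2) would fragment the graph and make the isolated-
  gene atom dominate. We preserve "well-connected", not the density value.
* **`query_size = 20`** — 10% of the universe. Small enough that a random
  set rarely contains a given gene's top neighbour, large enough that the
  tie atom stays small (next paragraph).
* **planted scores uniform on [950, 999]** — the top STRING confidence
  band, matching the MIS range reported for strongly associated genes.
* **uniform score sampler on [150, 999]** — minimises score ties, the
  cleanest setting for calibrating a strict-exceedance p-value; a
  low-score-heavy geometric option (`score_sampler("skewed")`) stresses
  tie handling.

Under these defaults the tie bias is predictable. With inclusion
probability $\pi = |Q|/N$ and degree $d$, the chance that the query draw
and a null draw tie (same top neighbour, or both empty) is approximately
$\frac{\pi}{2-\pi}\left(1-(1-\pi)^{2d}\right) + (1-\pi)^{2d} \approx 0.07$
at $\pi = 0.1$, $d = 20$, giving
$E[\mathrm{AUC}_{\text{null}}] \approx 0.5 + 0.07/2 \approx 0.53$ — which
is what the all-null calibration studies in the acceptance suite observe
(grand mean ≈ 0.53–0.54, inside the 0.45–0.55 band).

What the generator does **not** emulate: scale-free degree structure, edge
dependence (triadic closure), STRING's evidence channels or its empirical
score distribution, and overlap between query and class sets. Passing the
planted-recovery benchmarks therefore shows the pipeline recovers signal
expressed as strong direct edges on a homogeneous background; it does not
certify behaviour under hub-dominated degree heterogeneity, where
MIS-based calibration must lean on the permutation null much harder.

## Problem sizes used by the shipped studies

The acceptance suite runs: exact brute-force agreement on 100 random
networks of ≤ 50 nodes; AUC identities on 1000 random p-vectors; null
calibration on 10 studies of 200 nodes × 20 classes × 30 genes at 200
permutations; planted recovery on 50 replicates of 5 classes (strengths
0–1) at 200 permutations. These sizes give stable stochastic checks
(standard error of the null grand mean AUC ≈ 0.004) while keeping the
whole suite around a minute on one core.

## Published-data checks

The per-gene tables printed for the four top-ranked classes of the
motivating obesity study ship in
`inst/extdata/reported_gene_tables.tsv` (censored `<0.001` entries decode
to exactly 0 on a 1000-permutation strict-exceedance grid). From these the
package recomputes the significant-gene counts per class (15, 38, 11, 4).
The published top-class AUC (0.9621 for the nutritional class) was
computed over all 18 class genes, of which only the 15 significant ones
are printed; the three unprinted p-values are bounded by the 0.05
reporting cutoff, so `partial_auc_interval()` brackets the attainable
full-class AUC sharply (0.8268–0.9852) and the check asserts the published
value falls inside. A full recomputation needs the complete supplementary
per-gene table and the STRING v10 network; the scripted genome-scale
experiment (`inst/scripts/reproduce_string_study.R`) covers that case for
users with the downloads.

## Known limitations

* MIS uses one edge only; convergent medium-confidence neighbourhoods are
  invisible to it.
* The uniform-node null ignores degree: hub disease genes get flatter null
  MIS distributions than peripheral ones. Degree-preserving nulls are out
  of scope by design.
* $p = 0$ means "0 of $n$ exceedances", not "infinitely significant";
  resolution is $1/n$.
* No multiple-testing correction across genes or classes is applied
  anywhere; AUCs are descriptive ranks, not tested hypotheses, and no
  confidence intervals are attached to them.
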