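---
title: "Centrality-weighted pathway enrichment: model, null distribution and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-weighted pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcent)
```

# The model

## Nodes as the unit of analysis

A pathway is a directed graph whose vertices are *nodes* — proteins,
complexes, protein families, compounds and microRNAs — each holding a
(possibly empty) set of member genes. This representation has three
consequences that a flat gene-set view misses:

* a multi-gene complex or family is differentially *affected* as soon as
  any one member gene is differential;
* a gene residing in several nodes flips all of them;
* compound and microRNA nodes carry no measurable genes, are never
  differential, but still contribute to the topology and therefore to
  every centrality value.

`map_genes_to_nodes()` implements exactly this: node $v$ is affected iff
its member-gene set intersects the differential list. Pathway genes that
are absent from the measured background stay in the topology and are
simply never differential. Gene identifiers are opaque, case-sensitive
strings; identifier normalisation (symbol/accession conversion) is out of
scope and must happen upstream.

## The pathway score

Given per-node weights $w_i$ and affected-status indicators
$d_i \in \{0, 1\}$, the pathway score is

$$ s = \sum_{i=1}^{n} w_i d_i . $$

With $w_i = 1$ (the `equal.weight` condition) $s$ is the affected-node
count, which for single-gene nodes makes the test approximately the
classical hypergeometric ORA (binomial vs hypergeometric sampling is the
only difference). Weighting by centrality lets a few well-placed nodes
dominate the score, which is the point: a pathway can be significant
because key positions are hit, or fail to be despite many hits in
peripheral positions.

## Centralities and their conventions

Built-ins: `in.degree` / `out.degree` (direct upstream / downstream
neighbours), `betweenness`, and the largest-reach pair `in.reach` /
`out.reach`, defined as the largest *finite* shortest-path length into or
out of a node — a measure of how deep downstream (in) or far upstream
(out) a node sits in the signal flow. Equal weight completes the set, and
`register_weight_function()` accepts any user measure (closeness,
eigenvector, PageRank, ... can be added this way; they are deliberately
not built in because the characterisation experiments do not use them).

Two conventions are underdetermined by the definitions and are fixed here
explicitly (and recorded in every output header):

* **Betweenness respects edge direction and is unnormalized**, endpoints
  excluded, pairs with no connecting path contributing zero. Pathways are
  directed objects, so discarding direction would conflate upstream and
  downstream flow; normalisation rescales all weights jointly and cancels
  in ranks but not in scores, and the unnormalized form is the common
  graph-library default.
* **Unreachable pairs are excluded from largest reach**: the maximum is
  taken over finite distances only, and a node with no reachable
  counterpart gets 0. This keeps weights finite on the disconnected
  graphs that sparse random structures routinely produce, and ranks
  isolated nodes lowest, which matches the information-flow reading.

## The positivity adjustment

Centralities are frequently exactly zero, and a zero-weight affected node
would not move the score. Every weight is therefore shifted:
$w_i' = w_i + \alpha$ with $\alpha$ = 1/100 of the minimum non-zero raw
weight — small enough to leave the weighting essentially untouched, large
enough that every affected node registers. When *all* raw weights are
zero (betweenness on a very sparse graph), $\alpha$ falls back to 1,
degrading gracefully to the equal-weight condition rather than failing.
Scoring and the null simulation always use the adjusted vector; under
equal weight the uniform shift moves observed and null scores identically,
so p-values are unaffected there.

# The null distribution

## Bernoulli gene perturbation

The null asks: how large would $s$ be if differential status were sprayed
at random over the measured genes at the observed rate
$p_{\text{diff}} = n_{\text{diff}} / n_{\text{bg}}$? Each repetition draws
an independent Bernoulli($p_{\text{diff}}$) status *per distinct pathway
gene* — not per node — then maps the drawn gene set to nodes through the
same composition map. Nodes sharing genes therefore stay correlated under
the null exactly as in the observed mapping; drawing per node would break
that dependence and misstate the tail. Topology and weights are never
perturbed.

The p-value is the inclusive exceedance fraction
$p = \#\{s_{\text{sim}} \ge s\} / \#\{\text{sim}\}$, implemented
literally: no pseudo-count is added, so the smallest resolvable non-zero
p is $1/\text{reps}$ and a reported 0 means "below $1/\text{reps}$".
BH-FDR downstream tolerates zeros. The default is 1000 repetitions per
pathway, the number used throughout the characterisation experiments;
raise it when FDR decisions sit near the resolution limit.

Monte-Carlo comparisons use exact floating `>=`. This is safe because
observed and simulated scores are sums over the same weight vector; the
test suite nevertheless probes the exact tail at off-lattice thresholds
to stay independent of last-ulp effects.

## Exact small-n tail

For a pathway of $n$ independent single-gene nodes the score distribution
is computable exactly by enumerating all $2^n$ status outcomes
(`theoretical_tail()`, capped at $n \le 25$; the iterative subset-sum
doubling costs $O(2^n)$ memory). With equal weights it collapses to the
binomial upper tail, which the tests verify in closed form. Its role is
to anchor the Monte-Carlo machinery: the suite checks that empirical
p-values from $10^5$ draws agree with the enumeration within three
Monte-Carlo standard errors on random small pathways.

## Reporting

`run_enrichment()` emits one row per (pathway, measure): score, p-value,
BH-FDR, node counts, and the min / median / 75th-percentile / max of the
*raw* centralities of the affected nodes — a four-number sketch of where
the hits sit in the centrality spectrum. Quantiles interpolate linearly
between order statistics (type 7); the convention is stated in the output
metadata since other conventions exist. FDR is computed within each
measure by default: each centrality is a separate family of hypotheses,
and mixing measures would let a well-populated measure dilute another's
correction (a pooled mode exists behind `fdr_per_measure = FALSE`).
Rows are ordered by (measure, p, pathway id) and ties are broken
deterministically.

# The simulation harness

## What the generators emulate

The random-network study asks how pathway significance depends on
structure and measure when the gene-level evidence is held fixed. Its
conditions are the generator defaults: networks of $n = 200$ single-gene
nodes, 40 differential nodes drawn uniformly without replacement, a
background of 10,000 genes with 1,000 differential
($p_{\text{diff}} = 0.1$), 1000 networks per condition and 1000 null
draws per network. Under ORA this configuration is constant and highly
significant (Fisher's one-sided $p = 1.36 \times 10^{-5}$; at threshold
0.01 the minimal significant overlap is 31 genes) — any loss of
significance under centrality weighting is therefore attributable to
topology alone.

* **ER**: every unordered pair is connected independently with
  probability $1/n$; each realised connection receives exactly one
  uniformly chosen direction. Expected edge count $(n-1)/2$; degrees are
  binomial.
* **BA**: growth with preferential attachment — each arriving node
  attaches to an existing node with probability proportional to current
  degree (first attachment uniform), then each edge is oriented
  uniformly. Degrees are heavy-tailed: a small minority of hubs holds
  most connections.

The attachment count per arriving node is $m = 1$, the canonical minimal
preferential-attachment process. It keeps the BA edge count ($n - 1$) on
the same order as ER's expected $(n-1)/2$ and produces the hub structure
the study reasons about; $m$ is exposed as `ba_m` for
sensitivity analysis, and the BA proportions should be read with wider
error bars than ER's since density shifts them systematically.

Within one simulated network all measures are evaluated against the same
differential draw and the same null perturbation draws; each measure's
marginal p-value is unchanged by the sharing, and per-network RNG streams
are derived from the root seed and the network index, so results are
independent of evaluation order.

## What they do not emulate

Simulated nodes carry exactly one unique gene each, so the generators do
not exercise multi-gene complexes, shared genes, or non-gene nodes — the
mapping semantics are tested separately on hand-built catalogues. Real
differential calls are also correlated (co-regulation, batch effects)
where the Bernoulli null assumes independence, and real catalogues have
modular, curated structure rather than ER/BA statistics. Passing the
simulation checks therefore validates the scoring and null machinery, not
the biological calibration of p-values on any particular catalogue.

## The key-node experiment

On a single undirected BA network with degree weights, differential sets
of size $k = 1, \dots, k_{\max}$ are formed from the highest-degree nodes
down, or from the lowest-degree nodes up (ties broken by node id), and
each is tested against the same null. The ORA column depends only on $k$
and crosses 0.01 at $k = 31$ regardless of topology; the high-degree-first
curve crosses far earlier and the low-degree-first curve far later, which
is the method's core claim in miniature: *which* nodes are hit matters
more than how many. Because a single network realisation is noisy, the
test suite aggregates the crossing points over 25 seeded networks and
compares medians.

# Numerical and reproducibility choices

* All randomness flows from one root seed; per-pathway and per-network
  streams are derived by hashing the root with the pathway / network
  label, so adding or reordering pathways never changes another
  pathway's p-value. The CLI draws and prints a seed when none is given.
* Degenerate inputs: an edgeless graph is valid (all centralities 0,
  rescued by the $\alpha$ fallback); a pathway with no member genes
  cannot respond to any gene list and is reported at $p = 1$ with a
  `no_genes` flag and a warning; an empty differential list yields score
  0 and $p = 1$ everywhere; parallel edges are collapsed on input and
  self-loops rejected.
* Scores are double precision throughout; the exact-tail enumeration
  clamps cumulative probabilities into $[0, 1]$ to guard against float
  accumulation.
* Routine test runs use reduced simulation sizes (200 networks × 500
  null draws for the study proportions, $10^5$ draws for the exactness
  checks, 25 seeds for the key-node medians) — large enough that the
  checked tolerances exceed three Monte-Carlo standard errors, small
  enough to keep the suite fast; `scripts/acceptance.R` runs the full
  1000 × 1000 configuration.

# Limitations

* Only the binary (ORA-style) front end is implemented: a continuous
  gene-level statistic would require a node-level aggregation rule and an
  expression-permutation null, which this package does not provide.
* Catalogue ingestion is the three-file TSV format only; converting
  vendor XML formats and mapping identifiers is upstream work.
* The Bernoulli null conditions on the observed differential *rate*, not
  on the observed count; for single-gene pathways this is the binomial
  approximation to the hypergeometric, slightly conservative for
  pathways that are large relative to the background.
* Betweenness and largest reach are recomputed per pathway per run; for
  catalogues of thousands of large pathways, caching weight vectors
  across measures would be the first optimisation.
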