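---
title: "Ranking formula targets by network efficiency decrease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking formula targets by network efficiency decrease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

A multi-herb formula is a mixture of hundreds of compounds hitting
hundreds of protein targets across overlapping pathways. Single-target
reasoning cannot say which of those targets carry the therapeutic load.
`herbnet` treats the question as one of network robustness: build the
bipartite target–pathway relation produced by pathway enrichment of the
formula's predicted targets, project it to a one-mode
targets–pathways–targets (TPT) graph, and ask how much the graph's global
efficiency depends on each target.

## The perturbation model

The model rests on one biological assumption: **every member target of a
pathway contributes an equal share of that pathway's activity.** When a
target is "set off" (assumed undruggable by the formula), a pathway with
$N_j$ members loses one share:

$$PE_j = \frac{N_j - 1}{N_j},$$

while pathways not containing the target keep efficacy 1. An edge of the
TPT graph exists because its two endpoints share pathways; the edge's
efficacy is the product over its affected pathways,

$$EE = \prod_{k=1}^{t} \frac{N_k - 1}{N_k}, \qquad
  L = \frac{1}{EE},$$

so a weakened edge becomes *longer*. Unaffected edges keep length 1.
Global integrity is measured by network efficiency, the sum of reciprocal
shortest-path lengths over unordered node pairs,

$$NE = \sum_{m < n \in G} \frac{1}{d_{mn}},$$

with unreachable pairs contributing 0, and the score of a target is the
efficiency it takes with it:

$$NED_i = NE_0 - NE_i \ge 0 .$$

Knockouts only lengthen edges, so all shortest paths are non-decreasing
and NED is non-negative by construction; the test suite asserts this on
seeded random ensembles.

Two conventions deserve emphasis because the defining formulas are often
written ambiguously:

- **Unordered pairs.** Summing ordered pairs ($m \ne n$) would exactly
  double every value. On the worked example below the unordered sum gives
  $NE_0 = 83/6 = 13.8\overline{3}$, which matches the published worked
  value of 13.83, while the ordered sum would give 27.67. The worked
  example is treated as normative.
- **The knocked node is retained.** Only edge lengths change; the knocked
  target's own incident pairs still count. (The worked example's published
  perturbed distance matrix keeps all rows and columns of the knocked
  target populated, which forces this reading.)

## The worked example

```{r}
map <- sample_network()
g <- tpt_project(map)
unlist(tpt_stats(g))
network_efficiency(g)      # 83/6
k <- knockout(g, map, "C")
k$edge_states
ned_rank(g, map)
```

Target C sits in four of the six pathways; knocking it out drops the two
size-3 pathways to $2/3$ (displayed 67 %) and the two size-2 pathways
containing C to $1/2$ (50 %). The B–C edge carries both size-3 pathways,
so its efficacy is $4/9$ and its length $9/4 = 2.25$.

**A documented discrepancy.** The publication this example originates
from prints, for this knockout, $NE = 8.60$ and $NED = 5.23$. Running any
correct shortest-path algorithm over that publication's *own printed
length matrix* yields $NE = 8.4761$ and $NED = 5.3572$, as above. The printed
matrix (which this package reproduces entry for entry) is taken as
normative; the implementation is deliberately not adjusted to emit 8.60,
and we do not speculate on the source of the 0.12 gap.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `top_fraction` | 0.10 | share of ranked targets called "main"; the selection takes `ceiling(fraction * n)` entries, so 279 targets yield 28 |
| `alpha` | 0.05 | FDR threshold for pathway retention in `enrich()` |
| pathway indegree cut | 10 (strict `>`) | a pathway is "main" when more than 10 main targets feed it in the TPD graph |
| disease indegree cut | 20 (strict `>`) | a disease class is prominent when more than 20 pathways feed it |
| Veber bounds | ≤ 10 bonds, ≤ 140 Å² | inclusive on both boundaries |

Ties in the NED ranking break by ascending target id, making the full
ordering deterministic. Per-target knockouts are independent, so they may
be evaluated in any order; results are always merged in rank order.

## Enrichment: a transparent substitution

Formula pipelines typically obtain the target–pathway relation from an
enrichment web service whose internal annotation and universe are not
recoverable offline. `enrich()` therefore implements the standard
transparent equivalent: a one-sided hypergeometric upper tail
$P(X \ge k)$ per pathway, Benjamini–Hochberg adjustment across the
pathways with non-zero overlap (pathways with $k = 0$ have $p = 1$ and
are not reported), and retention at $q < \alpha$. The default universe is
the set of all targets in the annotation table, overridable. Pathway
membership is intersected with the universe before testing. A
pre-enriched table can always bypass this stage and enter the pipeline
directly.

## Validation against the literature

A useful importance score should correlate with how often a target is
co-mentioned with the formula in the literature. `validate_scores()` runs
Spearman's test for each of NED, degree and betweenness against full-text
and abstract co-occurrence counts. Counts are heavily tied (many zeros),
so $\rho$ is computed as the Pearson correlation of mid-ranks and the
two-tailed p-value from the $t$ approximation with $n - 2$ degrees of
freedom — a documented choice, since tie handling is rarely stated in
applied work. An exact permutation p-value is available behind
`exact = TRUE` for $n \le 10$ (full enumeration; practical only at small
$n$). Constant inputs yield a flagged degenerate result rather than an
error. Degree is reported as the raw incident-edge count and betweenness
unnormalized (Brandes): the comparison is rank-based, so normalization
cannot change it.

## Synthetic data: what it emulates and what it does not

- `sample_network()` returns the seven-target fixture above.
- `random_bipartite()` draws each (target, pathway) membership
  independently with a fixed probability. Pathways falling below
  `min_pathway_size` (default 2 — singleton pathways are invisible to the
  projection and would put $N_j = 1$ outside the perturbation model's
  domain) are re-drawn by default, or dropped on request. Identical
  arguments and seed reproduce the map bit for bit.
- `synthetic_cooccurrence()` draws counts from a Poisson log-linear model
  $\text{count}_i \sim \text{Pois}(\exp(\beta_0 + \beta z_i))$ with $z$
  the standardized score — the simplest monotone count model. The default
  baseline $\beta_0 = 1$ (mean $\approx 2.7$ hits per target) reflects
  that most genes are co-mentioned with a given formula in only a handful
  of papers.

The generator emulates the *structure* of an enriched annotation, not its
biology: real pathway memberships are strongly nested and correlated
(shared complexes, pathway hierarchies), whereas these are independent
Bernoulli draws; real co-occurrence counts mix true signal with citation
fashion, database lag and synonymy, none of which is modelled. Passing
tests therefore demonstrate the correctness and calibration of the
algorithms, not that NED will rank any particular formula's targets well.

## The simulation study behind the test suite

The acceptance tests run, at sizes chosen to represent a realistic
formula while keeping the suite fast:

- NED non-negativity over 100 seeded random maps of up to 30 targets, and
  agreement of the weighted efficiency with an independent
  Floyd–Warshall oracle to $10^{-9}$ on 50 graphs of up to 12 nodes;
- type-I calibration of the validation: with counts independent of the
  scores ($\beta = 0$, $n = 279$ targets from a simulated 155-pathway
  annotation at membership density 0.03), the Spearman test rejects at
  the 5 % level in 5 % ± 2 % of 1000 seeded replicates, and with
  $\beta = 2$ it rejects at $p < 0.001$ in at least 95 % of 100
  replicates;
- Veber screening on a seeded 10,000-compound table against a
  brute-force recount, with exact-boundary compounds planted.

## Numerical choices and degenerate inputs

- Edge efficacies and lengths are formed from exact integer products
  (numerator $\prod (N_k - 1)$, denominator $\prod N_k$), so each stored
  double is the correctly rounded value of the underlying rational;
  displayed percentages round to the nearest integer ($2/3 \to$ 67 %).
- Shortest paths use Dijkstra (via igraph) — all lengths are $\ge 1$ —
  and the oracle in the tests is an independent Floyd–Warshall.
- An empty map projects to an empty graph; a pathway with a single member
  contributes no edges but keeps its target as an isolated node, whose
  NED is exactly 0; unreachable pairs contribute 0 to NE.
- Duplicate membership pairs collapse silently; duplicate compounds merge
  their herb provenance (the standard chemical databases overlap).
- The pipeline writes no timestamps, so identical configs reproduce
  identical bytes.

## Limitations

- The equal-share contribution assumption is hard-coded; there is no
  per-target weighting hook.
- Single-target knockouts only; no simultaneous multi-target perturbation.
- Baseline edges are unweighted regardless of how many pathways they
  share; all weighting is perturbation-specific.
- Enrichment results depend on the annotation table supplied; the package
  neither fetches nor versions pathway databases.
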