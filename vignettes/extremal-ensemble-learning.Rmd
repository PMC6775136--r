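---
title: "Extremal ensemble learning for modularity maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extremal ensemble learning for modularity maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reneel)
```

## The problem

Community detection by modularity maximization asks for the node partition
$P = \{c_1, \dots, c_r\}$ of an undirected network that maximizes

$$
Q = \sum_i \left[ \frac{m_i}{m} -
  \left( \frac{2 m_i + e_i}{2m} \right)^2 \right],
$$

where $m_i$ and $e_i$ are the weight of links internal and external to
community $c_i$ and $m$ is the total link weight. The first term is the
fraction of weight inside communities; the second is its expectation under a
strength-preserving random null model. Maximizing $Q$ exactly is NP-hard, so
practical algorithms are stochastic heuristics: different runs return
different partitions, and any returned $Q$ is a lower bound on the true
maximum $Q_\max$.

`reneel()` implements an *extremal ensemble learning* scheme on top of such a
heuristic. Instead of simply keeping the best of many runs, it makes an
ensemble of runs cooperate: the ensemble repeatedly identifies what its
members already agree on, re-optimizes only the remaining degrees of freedom,
and updates itself with extremal acceptance criteria until it reaches
consensus.

## The scheme

1. **Initial ensemble.** The base algorithm is run `k_max` times on the
   network $G$, giving an ensemble of at most `k_max` distinct partitions,
   kept sorted by $Q$.
2. **Core groups.** A *core group* is a maximal node set whose members share
   a community in *every* ensemble partition — a block of the meet of the
   partitions. Nodes co-assigned everywhere are "easy"; the open question is
   only how core groups combine.
3. **Reduction.** Each core group collapses to a single node of a weighted
   reduced network $G'$: inter-group link weights are summed and the weight
   internal to a group becomes a self-loop. With the self-loop convention
   used throughout this package (a self-loop of weight $w$ adds $w$ to $m$
   and $2w$ to its node's strength), any partition of $G'$ has exactly the
   same modularity as its expansion back onto $G$ — the reduction loses no
   quality information at the core-group resolution.
4. **Candidate generation.** The base algorithm is run `k_prime` times on
   $G'$ and the best reduced partition, expanded to $G$, becomes the
   candidate.
5. **Extremal update.** If the candidate is already in the ensemble, the
   worst member is deleted. Otherwise, if its $Q$ strictly exceeds the worst
   member's, it is inserted (replacing the worst member when the ensemble is
   at capacity, growing the ensemble otherwise). Otherwise the worst member
   is deleted. Equality with the worst member counts as *not better*: the
   acceptance rule is strict, and we deliberately compare $Q$ values exactly
   (no epsilon), with every $Q$ produced by one shared accumulation routine —
   an epsilon here would silently change when the loop terminates.
6. **Termination.** Steps 2–5 repeat until one partition remains. Acceptance
   requires strictly beating the worst member and the ensemble is bounded,
   so the loop always halts; the survivor is the consensus partition.

Two structural consequences are worth stating because the tests assert them.
Core groups are *agglomerative*: every accepted candidate is a union of
current core groups, so later groupings only coarsen earlier ones and the
reduced network shrinks monotonically. And the ensemble's extremes are
*monotone*: the worst and best $Q$ in the ensemble never decrease.

## The base algorithm

The built-in base algorithm is randomized greedy agglomeration. From
singleton communities it samples `sample_size` communities (default 2)
uniformly among those that still have neighbours, scans all merges between a
sampled community and a neighbouring community, and applies the merge with
the largest modularity gain

$$
\Delta Q = 2 \left[ \frac{w_{ab}}{2m} - \frac{s_a s_b}{(2m)^2} \right],
$$

recording $Q$ at every level and returning the best level. Merges are
restricted to community neighbourhoods, which keeps the expected cost near
$O(m \log n)$ and means disconnected components are never joined (joining
them can only lower $Q$). Ties in $\Delta Q$ go to the lowest community-id
pair and equal recorded $Q$ values to the earliest level, so a run is fully
determined by its seed. The base is pluggable: any `function(graph)`
returning a partition can stand in, for the original network and the reduced
network independently.

A single randomized greedy run is deliberately cheap and noticeably
suboptimal — on the planted-partition fixture below it stays within roughly
ten percent of the planted partition's $Q$ but rarely lands on the exact
optimum. That gap
is the reason ensemble schemes exist, and the acceptance tests check the
resulting ordering: consensus $\geq$ best-of-100 $\geq$ single run.

## Parameters

* `k_max` (default 100) — ensemble capacity. Larger ensembles define finer
  initial core groups and explore longer before consensus; iteration count
  grows roughly linearly with `k_max`.
* `k_prime` (default 20) — reduced-network partitions per iteration. Larger
  values give better candidates per iteration at proportional cost.
* `sample_size` (default 2) — randomized greedy sample size; 2 is the
  classic choice and keeps single runs cheap and diverse.
* `seed` — every random choice in a run (initial ensemble, per-iteration
  candidate generation) derives from it; fixed seed means bit-identical
  output, including across the command-line interface.

The defaults are the standard study conditions used throughout the package's
tests and are appropriate for networks up to a few tens of thousands of
nodes on one core.

## Co-clustering diagnostics

`co_cluster_matrix()` summarizes an ensemble by $s_{ij}$, the fraction of
member partitions that co-assign nodes $i$ and $j$; off-diagonal entries
equal to 1 mark core groups. To visualize block structure the node order is
seriated by minimizing

$$
H = \sum_{i<j} s_{ij} \, d_{ij}^{\alpha},
$$

where $d_{ij}$ is the circular distance between display positions (periodic
boundary conditions) and $\alpha = 3$ by default. `anneal_order()` minimizes
$H$ by simulated annealing over random pair swaps with Metropolis acceptance
$\min(1, e^{-\Delta H/T})$. Design choices, since the cooling schedule is
genuinely open: the chain starts from the identity order at a temperature
high enough to randomize it (10 times the standard deviation of $\Delta H$
over 100 random proposals), cools geometrically by 0.98 per stage of $n^2$
proposals, stops after 3 stages without an accepted cost-changing move
(zero-cost swaps keep mixing but do not reset the stall counter), and
returns the best order ever seen — so the result never costs more than the
starting order. $H$ is invariant under rotations and reflections of the
circle, so "the" optimal order is an equivalence class; tests compare costs,
not label sequences. A `groups` argument restricts swaps to within-group
pairs for hierarchy-constrained displays.

## Synthetic fixtures and what they do (and do not) show

The package tests itself without any external data using two generators.

* `planted_partition(blocks, block_size, p_in, p_out)` — independent
  within-block edges with probability `p_in` and cross-block edges with
  `p_out`. The standard fixture is 4 blocks of 25 nodes with `p_in = 0.3`,
  `p_out = 0.01`: strong but sparse assortative structure whose planted
  partition is usually (not always) the modularity optimum.
* `ring_of_cliques(K, c)` — $K$ cliques of size $c$ joined in a ring by
  single links; every quantity has a closed form ($m = K(\binom{c}{2}+1)$,
  each clique has $m_i = \binom{c}{2}$, $e_i = 2$), making it the analytic
  anchor for the quality function.

These fixtures exercise the scheme's mechanics — meet/reduce/expand
identities, extremal updating, consensus ordering versus the naive
comparator — under clean block structure. They do not emulate heavy-tailed
degrees, overlapping or hierarchical communities, or the resolution-limit
regime of very large sparse graphs, so green tests here say the machinery is
correct, not that consensus $Q$ on an arbitrary real network is near
$Q_\max$. The classic published benchmark networks are external downloads
(`scripts/fetch_benchmarks.R` documents per-network provenance); the
corresponding acceptance check runs only when they are present.

## Numerical choices and degenerate inputs

* All cached and compared $Q$ values come from one accumulation routine
  (community sums in sorted community order), so strict comparisons in the
  update rule are exact; reduction/expansion equality is asserted to
  $10^{-12}$ at every iteration.
* Parallel input edges merge (sum in weighted input, collapse to weight 1
  in unweighted input, with a message); zero or negative weights are
  rejected; `m = 0` graphs have no defined modularity and are rejected.
* Empty communities are never carried; membership vectors are canonicalized
  by first appearance, which is also the equality test for the duplicate
  branch of the extremal update.
* `k_max = 1` (or an initial ensemble that deduplicates to one member)
  terminates before any iteration: consensus pre-exists.
* Disconnected graphs are accepted silently; isolated nodes stay singleton
  communities.
* Problem sizes in the test-suite study conditions: property checks use
  random graphs of 6–30 nodes against brute-force oracles (all set
  partitions up to $n = 8$, all circular orders up to $n = 6$); full-run
  checks use the 100-node planted fixture and the 40-node ring at
  `k_max = 100`, `k_prime = 20`.

## Known limitations

* Plain modularity inherits the resolution limit; resolution parameters and
  modularity-density variants are out of scope here.
* The seriation uses free pair swaps only; the three-stage
  hierarchy-constrained protocol used for multi-stage core-group displays is
  available only through the `groups` hook, one stage at a time.
* The randomized greedy base is the only built-in; stronger bases (e.g.
  spectral bisection with refinement) can be supplied through the `base`
  argument but are not shipped.
* Directed and bipartite networks, and GML/GraphML ingestion, are not
  supported.
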