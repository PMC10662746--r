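---
title: "Methods: the zero-agnostic copy number transformation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the zero-agnostic copy number transformation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcnt)
```

## The model

A copy number profile is a vector $p \in \{0,\dots,B\}^m$ of copies per
genomic bin. The classical CNT model evolves profiles by interval events
$c_{s,t,b}$ with $b \in \{+1,-1\}$ that add $b$ to every *non-zero* entry in
bins $s..t$: once a locus is lost it stays lost. This package implements the
zero-agnostic relaxation (ZCNT), where events add $b$ to *every* entry in
the interval, zeros included, and intermediate values may go negative. The
relaxation is not biologically faithful — genomes cannot re-amplify deleted
material — but it makes the distance a closed-form metric and the ancestral
reconstruction problems tractable, and the package quantifies after the fact
how often reconstructed ancestors actually violate the CNT rules
(`cnt_violation_stats`).

### Delta profiles

The delta map $\Delta$ replaces a profile by its adjacent-locus differences,
padding both chromosome ends with the diploid baseline (default 2, a
configuration parameter):
$\Delta(p)_1 = p_1 - 2$, $\Delta(p)_i = p_i - p_{i-1}$,
$\Delta(p)_{m+1} = 2 - p_m$. Each per-chromosome segment sums to zero (the
*balancing condition*), $\Delta$ is a bijection onto such vectors
(cumulative sums invert it), and a ZCNT event moves exactly two delta
coordinates in opposite directions. Consequently:

* the ZCNT distance is $d(p,p') = \tfrac12\lVert\Delta(p)-\Delta(p')\rVert_1$,
  always a non-negative integer, and a metric;
* event order never matters (delta events commute);
* a minimum-length event sequence realizing an edge can be read off by
  pairing the positive and negative unit charges of
  $\Delta(\text{child})-\Delta(\text{parent})$ left to right
  (`canonical_event_decomposition`); amplifications are scheduled before
  deletions, so that intermediate profiles stay as high as possible.

Chromosomes are handled as independent delta segments with baseline padding
at both ends; distances and objectives sum over segments. An alternative —
one concatenated vector across chromosomes — differs only at the
inter-chromosome junctions, where it would allow a single event to span two
chromosomes; the per-chromosome choice matches the biology of
intrachromosomal CNAs.

### ZCNT versus CNT distances

ZCNT relaxes the CNT *model*, but the ZCNT distance does **not** uniformly
lower-bound the CNT distance. A single CNT event whose interval spans an
interior zero changes each maximal non-zero run separately — something no
single ZCNT interval event does. For example
$\sigma((1,0,1)\to(0,0,0)) = 1$ (one deletion, the middle zero skipped)
while $d = 2$:

```{r}
bfs_min_events(c(1, 0, 1), c(0, 0, 0), "CNT")
zcnt_distance(c(1, 0, 1), c(0, 0, 0))
```

On zero-free intervals every CNT event *is* a ZCNT event, so the two
distances track each other closely away from heavily deleted genomes;
`cnt_zcnt_comparison` computes the per-pair relative differences
$|d_{CNT}/d_{ZCNT}-1|$ (pairs with $d_{ZCNT}=0$ or an infeasible CNT
transformation are excluded and counted). CNT distances come from an
exhaustive BFS oracle that is deliberately guarded to toy scale
($m \le 6$, entries $\le 5$, at most 12 events); at realistic scale CNT
distances must be supplied externally.

## Small parsimony

Given a tree with cells at the leaves, the ZCNT small parsimony problem asks
for balanced integer delta labelings of the internal vertices minimizing the
summed per-edge L1 distance (the event count is half of that; both units are
always reported). Four solvers are provided:

* **Unbalanced relaxation** (`unbalanced_small_parsimony`), exact when the
  balancing condition is dropped. Coordinates decouple into independent L1
  problems on the tree, solved by interval message passing: each vertex's
  message is the interval of minimizers of its (convex, piecewise-linear,
  slope-clipped) subtree cost; overlapping child intervals intersect, and
  disjoint ones contribute the gap length to the cost. Tie-breaking in the
  top-down pass is deterministic: the root takes the interval value nearest
  zero (the diploid delta) and every child the value nearest its parent —
  this minimizes spurious non-diploid ancestral states without affecting
  optimality. Polytomies are resolved deterministically first; resolution
  can only lower the optimum, never raise it.
* **LP relaxation** (`lp_relaxation_small_parsimony`), dropping integrality
  instead: absolute values are split into non-negative slack pairs and the
  balancing rows kept. The fractional optimum sits between the unbalanced
  optimum and the integer optimum.
* **Exact ILP** (`exact_small_parsimony_ilp`), integrality on the vertex
  labels only. Both mathematical programs are formulated in R and solved by
  HiGHS through SciPy's `milp` (the `python` on `PATH`; override with
  `options(zcnt.python = ...)`). Ancestral labels are boxed to the
  per-coordinate leaf range widened by a slack (default: the largest
  absolute discrepancy of the unbalanced solution, at least 1); if any label
  sits on the box boundary at the optimum the box is widened (doubled plus
  one) and the instance re-solved, so the box never binds the reported
  optimum. LP/ILP scores are compared at $10^{-6}$; the ILP labeling is
  rounded and re-scored as a consistency check.
* **2-approximation** (`two_approx_small_parsimony`): run the unbalanced
  solver, then *repair* each vertex by subtracting its per-chromosome
  discrepancy from the final (right-telomere) delta coordinate. The edge
  cost increase is at most $|disc(u)-disc(v)| \le \lVert\ell(u)-\ell(v)
  \rVert_1$, so the repaired (feasible) cost is at most twice the unbalanced
  optimum, which itself lower-bounds the true optimum. Repairing the
  telomere coordinate corresponds to extending events to the chromosome end
  and leaves interior breakpoints untouched; any fixed coordinate would give
  the factor 2, but interior choices would scatter extra breakpoints through
  the genome.

The discrepancy sum also gives a general lower bound: any labeling agreeing
with the leaves costs at least $\sum_u |disc(\ell(u))|$.

## The median problem

For a star tree the problem reduces to finding one profile minimizing the
total distance to $n$ inputs. `zcnt_median` fills, per chromosome, a table
$A[j,k]$ = minimal partial L1 cost of a length-$j$ delta prefix with entry
sum $k$, with the next entry ranging over $\{-B,\dots,B\}$ ($B$ = the
maximum input copy number, widened to cover the leaf delta range so the
boundary-coordinate entries, which can exceed $B$ when $B<2$, stay
reachable). The boundary is $A[0,0]=0$ and $A[0,k\ne 0]=\infty$: the empty
prefix has discrepancy zero, the only reading under which the recurrence's
prefix semantics is consistent (verified against exhaustive search in the
tests). The answer is $A[L,0]$, the balanced completion; ties among next
entries break toward the value nearest zero, preferring near-diploid
medians. For $n=2$ the optimum equals the pairwise distance and an input
profile attains it.

## Large parsimony search

`zcnt_phylo` chains: pairwise ZCNT distances → neighbor joining → NNI hill
climbing → final balanced labeling. Scoring *during* the search uses the
unbalanced relaxation — orders of magnitude faster than the ILP, and the
ranking of candidate topologies with and without the balancing condition is
nearly the same in practice — while the *final* reported labeling is always
balanced (2-approximation by default, ILP on request). The search schedule
is deliberately simple and fully determined by `search_config`:
best-improvement NNI until no improving move, then `max_rounds` (default
50) rounds of a random NNI walk of length
$\lceil \text{perturbation\_strength} \cdot n \rceil$ (default strength
0.2) followed by re-climbing, keeping the best tree seen; a single seed
(default 0) makes the whole search reproducible. First-improvement moves,
SPR/TBR neighborhoods, and candidate ensembles are intentionally out of
scope. With `root_at_diploid` a pseudo-leaf named `"diploid"` carrying the
all-diploid profile is attached before the search, pinning the root state
as large parsimony demands; evaluation functions drop it automatically.

## The simulator

`simulate_evolution` is the ground-truth generator behind all simulated
tests: a random pair-joining binary topology, an all-diploid root, and per
edge a Poisson number of interval events (uniform chromosome, uniform — or
optionally geometric-length, focal — intervals, amplification with
probability 0.5 by default, 3 events per edge by default) applied under
**CNT** semantics, so simulated histories never violate the CNT model and
both models can be evaluated on the same data; ZCNT semantics is a flag. An
optional copy cap rejects (skips) events that would exceed it; rejections
are recorded in the event log. The simulator emulates interval gains and
losses only: no whole-genome doubling, no chromothripsis, no breakpoint
reuse bias, and no measurement noise (profiles are observed exactly).
Passing tests therefore demonstrate correctness of the algorithms under the
stated generative model, not robustness to segmentation error or complex
rearrangements in real data.

## Problem sizes and numerical choices

The test suite exercises: exhaustive profile grids at $m=3$, entries
$0..3$ (4096 ordered pairs against the BFS oracle); metric and delta-map
properties at $m=50$; 50 simulated small-parsimony instances with 10 cells,
30 bins and Poisson(3) events per edge for the relaxation sandwich and the
factor-2 ratio against the ILP; exhaustive balanced-state-space oracles on
all rooted topologies with up to 4 leaves at $m=3$, entries $\le 2$; and
search runs with 8–20 cells and 100–200 bins at one event per edge. These
sizes were chosen so each property is checked at the largest scale at which
its independent oracle is exhaustive or the check is exact.

Floating point enters only through the LP/ILP backend (tolerance $10^{-6}$);
all other arithmetic is exact integer work. Degenerate inputs are defined
behavior: identical profiles give distance 0; a single profile is its own
median; an all-diploid matrix yields a zero-score star-like fit; unbalanced
delta segments are rejected by the inverse map with a balancing-violation
error.

## Known limitations

* Exact CNT quantities are available only through the toy-scale BFS oracle.
* The ILP scales to moderate instances (tens of cells, hundreds of bins);
  beyond that the 2-approximation is the intended tool.
* The NNI-only search can be trapped by local optima; perturbation rounds
  mitigate but do not eliminate this.
* Clonal discordance is defined here as single-character Hartigan parsimony
  (its minimum over trees with clone-clades is $k-1$); other definitions
  would change absolute values.
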