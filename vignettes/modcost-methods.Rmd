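---
title: "Methods: evolving modular networks under connection costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving modular networks under connection costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcost)
```

## The question the package addresses

Biological networks — gene regulation, metabolism, nervous systems — are
strikingly modular: they decompose into clusters of nodes densely
connected internally and sparsely connected to the rest.  One candidate
explanation is that modularity is a byproduct of direct selection to
reduce the *cost of connections* (wiring length, maintenance, signal
delay), rather than of indirect selection for evolvability.  `modcost`
implements a computational test of that hypothesis: populations of
layered Boolean-task networks evolve either under selection on task
performance alone (PA) or on performance plus a connection-cost
objective (P&CC), and the resulting networks are compared for
modularity, functional decomposition, and speed of re-adaptation.

## Network model

A genome encodes a feed-forward network: nodes are arranged in layers
and connections link consecutive layers only.  Node output is

$$y_j = \tanh\!\Big(\lambda \big(\textstyle\sum_{i \in I} w_{ij} y_i - b_j\big)\Big),$$

with integer weights $w_{ij} \in \{-2,-1,1,2\}$ (0 encodes "no
connection"), integer thresholds $b_j \in \{-2,\dots,2\}$, and slope
$\lambda = 20$, which makes each node close to a hard threshold unit
with outputs in $[-1,1]$.  A continuous output is read as a Boolean
answer by thresholding at zero, with 0 itself counting as *true*.  The
sign convention ($-b$) follows the reading of $b$ as the input level at
which the node's output crosses from negative to positive; it is
configurable (`bias_sign`), as is an input encoding of $\{0,1\}$ instead
of the default $\pm 1$.

Thresholds are stored for every node, inputs included.  Input
thresholds never affect evaluation, but keeping them in the encoding
makes the genome's parameter count match the conventional accounting of
the search space (for the retina architecture: $8\cdot8 + 8\cdot4 +
4\cdot2 + 2\cdot1 = 106$ weight slots plus $23$ node thresholds $= 129$
parameters, each taking one of five values, i.e. $5^{129} \approx
10^{90}$ genomes) and gives the per-node threshold-mutation rate its
natural meaning.

Architectures are task-fixed: 8-8-4-2-1 for the retina tasks,
10-8-5 for the five-XOR task, 8-8-4-4-2 for the hierarchical-XOR task.
Nodes are never added or removed by mutation; nodes without any
connection are retained in the genome but excluded from displayed
networks and from all modularity calculations.

## Tasks

**Retina (default).**  All $2^8 = 256$ patterns on an eight-pixel
retina are shown; the left and right four-pixel halves each may contain
an "object".  The network answers whether objects are present on both
sides (L-AND-R) or on either side (L-OR-R).  Performance is the
fraction of correctly classified patterns.  The packaged object sets
keep the task's defining structure — eight of the sixteen possible
half-patterns count as objects per side, with slightly different sets
for the two sides: a
half-pattern is an object if at least three pixels are ON, or exactly
two are ON including that half's outer pixel.  The sets are a config
option (YAML `objects:` key), and every combinatorial check in the test
suite depends only on the 8/16 property, not on the particular
patterns.

**Non-modular retina.**  The answer is whether at least four of the
eight pixels are ON — every input matters, so no left/right
decomposition exists.  The phrase "any four pixels on" is ambiguous
between *at least* and *exactly* four; the package defaults to *at
least* and offers `exactly_4` as an alternative.

**XOR suites.**  `five_xor`: ten inputs, five outputs, output $k$ the
XOR of input pair $(2k-1, 2k)$ (consecutive pairing matches the
left-to-right coordinate layout).  `hierarchical_xor`: eight inputs,
two outputs, each output the XOR of the XORs of its half's input
pairs.  XOR is true iff its arguments differ, under the $\pm1$
encoding.

Inputs sit at $y=0$ with unit-spaced $x$ (retina: $-3.5 \dots 3.5$,
output at $(4, 0)$; five-XOR: $-4.5\dots4.5$, outputs at
$x\in\{-4,-2,0,2,4\}$, $y=2$; hierarchical XOR: $-3.5\dots3.5$, outputs
at $x\in\{-2,2\}$, $y=4$).

## Connection costs

The default cost is the summed squared Euclidean length of all
connections *after hidden nodes have been placed optimally*: inputs and
outputs are fixed, hidden nodes are free in both coordinates, and the
quadratic objective is minimized exactly by solving the graph-Laplacian
linear system in which each free node sits at the mean of its
neighbours.  Connected components that contain no fixed node have no
determinate position; their nodes are placed at the centroid of the
fixed coordinates, contributing zero length (they are functionally
isolated, and the choice removes the singularity of the system).  A
second cost, the number of connections, ignores geometry entirely; a
connection counts once regardless of weight magnitude.

## Selection: NSGA-II with stochastic Pareto dominance

Evolution is an elitist $(\mu + \lambda)$ NSGA-II with $\lambda = \mu$,
binary-tournament parent selection, and mutation only (no crossover).
Because selection on performance is stronger than on cost, the cost
objective is consulted *probabilistically*: in each pairwise dominance
test a fresh $r \sim U[0,1]$ is drawn; if $r > p$ (default $p = 0.25$)
only performance is compared, otherwise standard two-objective Pareto
dominance applies.  Drawing $r$ per comparison (rather than once per
sort) follows the definition of the dominance relation; the possible
rank intransitivity within one sort is accepted — the peeling procedure
is well defined regardless, and mutual dominance is impossible because
any domination implies no worse performance.  The merge step is the
standard elitist one (survivors are the best $\mu$ of parents plus
offspring by rank, then crowding distance).

Treatments: `PA` (performance only), `PCC_length` (default cost),
`PCC_count` (connection count), and the control `PRO`, in which each
new individual receives a fresh uniform random number as its second
objective.

## Mutation

Four independent events, applied in a fixed order for reproducibility
(they are not mutually exclusive): a 20% chance of adding one
connection (uniform over absent consecutive-layer slots; the new weight
is uniform over the four legal values, a package choice); a 20% chance of removing one uniformly chosen
connection; a $1/24$ chance per node of a $\pm1$ threshold step; and a
$2.0/n$ chance per connection ($n$ = current connection count) of a
$\pm1$ weight step.  Steps that would leave the legal range are
ignored; integer weight steps skip 0 because 0 means "no connection",
so $-1 + 1 \to +1$ and $+1 - 1 \to -1$, keeping the four-value alphabet
closed.  A real-valued variant replaces the $\pm1$ steps with Gaussian
perturbations ($\sigma = 0.5$, a package default)
clamped to $[-2, 2]$.

## Modularity

Networks are directed, so the package's Q uses the directed form

$$Q = \sum_{ij}\Big(\frac{A_{ij}}{m} - \frac{k^{out}_i k^{in}_j}{m^2}\Big)\,\delta(c_i, c_j),$$

with an undirected (symmetrized) option.  `maximize_modularity()` is a
deterministic heuristic — greedy agglomeration, Kernighan–Lin-style
single-node moves, whole-community merges, and recursive bisection,
iterated to a fixed point from three initializations — whose
approximation quality is bounded in the tests by exact Bell-number
enumeration on small graphs (it attains the exact optimum on ≥ 95% of
200 random ≤ 10-node graphs).  Functional modularity uses the best
*two*-module split (exhaustive over 2-colourings up to 20 nodes,
spectral + refinement above): a network is functionally modular when
that split puts the left subproblem's displayed inputs in one module
and the right's in the other.  A hidden node is a *perfect
sub-solution* node when its thresholded output equals a subproblem's
answer on every pattern; a node answering the exact complement
everywhere also counts by default, since a downstream negative weight
recovers the answer (`polarity = "strict"` disables this).

## MOLE: mapping the performance landscape

Multi-Objective Landscape Exploration searches for the best achievable
performance at every combination of cost and modularity.  It is
NSGA-II with two deterministically applied objectives — performance,
and distance in axis-normalized (cost, Q) space to the nearest
already-discovered individual.  Every evaluated individual enters an
archive thinned to a 100×100 grid keeping the best-performance
representative per cell (unbounded archives would make the
nearest-neighbour queries quadratic; archive mechanics, population
size, generations and distance normalization are package choices).  Novelty is measured against the archive as it stood
before the current offspring were inserted, so an individual that lands
in unexplored territory scores high in the selection round in which it
was discovered.  Maps from several runs merge by per-cell maximum.

The distance normalization is a consequential choice.  Normalizing each
axis by the archive's current extent — the obvious default — turns out
to be self-defeating: early archives span a tiny Q range, so Q noise is
amplified relative to genuine moves along the cost axis and novelty
loses its directional meaning (the archive then never grows beyond the
dense-network region).  `run_mole()` therefore normalizes against fixed
natural scales: the Q axis by 1 (its theoretical extent) and the cost
axis by the cost of the fully connected architecture, the largest value
a genome can attain.  `novelty_distance()` itself keeps the
extent-relative default for standalone use.

## Statistics

Summaries are medians with 95% percentile-bootstrap confidence
intervals (5000 resamples); trajectory plots may be smoothed with a
centered running median (window 200, truncated at the edges).
Between-treatment comparisons use the Mann–Whitney rank-sum test and,
for categorical flags, Fisher's exact test — all delegated to base R
(`wilcox.test`, `fisher.test`).

## Study conditions and the scaled presets

The full study conditions are 50 trials per treatment, population 1000,
25 000 generations — tens of CPU-hours per treatment.  Those are the
package defaults (`evolution_config()`), and all mechanisms are
identical at any scale.  For routine verification the package ships
scaled presets, chosen once as the smallest sizes at which the
qualitative contrasts are well expressed:

* **Direction checks** (test suite): population 200, 5000
  generations, 10 trials per treatment on L-AND-R.  At this scale P&CC
  populations reliably reach the sparse, modular regime
  (cost ≈ 20–30, Q ≈ 0.55) while PA remains dense (Q ≈ 0.2), so
  rank-sum contrasts are decisive with 10 trials.
* **Evolvability transfer**: because perfect PA networks are rare at
  desk scale (at full scale the original protocol needed 320+ trials to
  collect 50), the scaled transfer uses an adaptation criterion of
  performance ≥ 0.95 in both source and target, population 200,
  horizon 600 generations, with the per-trial best networks of the
  direction-check batches as seeds.  The full-scale protocol (1000
  clones, perfect performance, 5000-generation censoring horizon) is
  the function's default.
* **MOLE**: population 100, ~1200 generations.  A desk-scale MOLE
  archive explores the neighbourhood of the random-genome region; it
  exhibits the inverse cost–Q relation among its best-performing cells
  but does not reach the sparse region where perfect low-cost networks
  live — that requires tens of sequential connection removals along the
  cost axis, a diffusion budget only full-scale runs have (see
  *Known limitations*).
* **Random-genome survey**: 10⁴ uniform genomes.

The generators emulate the study's synthetic conditions exactly (all
256 patterns, the stated coordinates, rates and probabilities); what
they do *not* emulate is anything beyond those conditions — no noise in
inputs, no lifetime learning, no node birth/death — so passing tests
speak to the evolutionary mechanism, not to robustness of real
biological data.

## Numerical choices and degenerate cases

* Placement solves a strictly convex quadratic whenever every free
  component touches a fixed node; the solution is unique and checked
  against a generic numerical optimizer (agreement ≤ 10⁻⁶) and by
  ±ε perturbation (local optimality).
* Q is undefined on edgeless graphs (an error); batch drivers record
  `NA` for such final networks (they do not occur in practice).
* Modularity tie-breaks are by lowest index everywhere, making every
  partition-valued result reproducible without randomness.
* The compiled generation loop consumes R's RNG stream, so a single
  `set.seed()` (or the config's seed) reproduces a trial bit-for-bit;
  per-trial seeds are spawned from the master seed by a fixed draw.
* The `tanh` evaluation uses a saturation fast path (|argument| > 19
  returns ±1), which is bit-identical to `tanh` in double precision.
* Empirically the add/remove/threshold mutation frequencies are
  recovered at 0.20 / 0.20 / (1/24) per call/node over 10⁵ calls in
  the acceptance checks.

## Known limitations

* The heuristic Q maximizer is exact only in the ranges the oracle
  tests cover; on larger graphs it is a lower bound on the true
  optimum, the same caveat that applies to any practical modularity
  optimizer.
* MOLE is a sampling device: per-cell values are lower bounds on the
  best achievable performance, and desk-scale runs fill the plane far
  more sparsely than full-scale multi-run maps.  In particular, desk-scale
  archives stay near the dense random-network region and contain no
  perfect-performance cells; exploring the full cost axis is a
  topology-diffusion process whose budget grows with the number of
  connections that must be shed.
* The retina object sets are one concrete realization of the
  8-of-16-per-side structure; results that depend only
  on the 8/16 structure are unaffected, but exact per-pattern
  performances of specific hand-built genomes could differ.
* Real-valued weight evolution is provided as a robustness variant;
  its Gaussian step size is a package choice.
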