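---
title: "Ollivier-Ricci curvature from node-level omics data: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ollivier-Ricci curvature from node-level omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccinet)
```

## The model

`riccinet` computes an edge-level robustness statistic on a simple,
undirected, connected interaction network whose nodes carry nonnegative
measurements (gene expression, protein abundance, any node-level omics
value). The ingredients, per sample:

1. **Mass-action kernel.** Node weights $w_i$ induce random-walk
   transition probabilities $p_{ij} = w_j / \sum_{k \sim i} w_k$ for
   neighbors $j \sim i$ and 0 otherwise. Rows sum to one by construction.
2. **Neighbor measures.** Each node spreads the same normalization as a
   probability measure over its neighborhood,
   $\mu_i(k) = w_k / \sum_{j \sim i} w_j$. With idleness $\alpha > 0$ the
   node keeps mass $\alpha$ on itself and scales the rest by
   $1 - \alpha$; the default $\alpha = 0$ is the plain mass-action
   measure.
3. **Ground metric.** In *weighted* mode each edge gets length
   $1/\tilde w_{ij}$ with $\tilde w_{ij} = (p_{ij} + p_{ji})/2$ — strong
   two-way traffic makes an edge short — and $d(i,j)$ is the
   shortest-path distance under these lengths. In *hop* mode all lengths
   are one. In both modes the direct edge is *not* assumed shortest; the
   metric is the true shortest-path distance in the full graph.
4. **Curvature.** $\kappa(i,j) = 1 - W_1(\mu_i, \mu_j)/d(i,j)$, where
   $W_1$ is the Wasserstein-1 distance under the same metric, solved
   exactly as a transportation linear program (simplex method). The
   optimal value of that program is unique, so the result is
   deterministic even though the optimal transport plan need not be.

Curvature is at most 1, positive where adjacent neighborhoods overlap
(triangles, cliques — redundant routes, robustness), negative on
bridge-like edges whose removal disconnects flow (fragility). On the
complete graph $K_n$ with uniform weights every edge has
$\kappa = (n-2)/(n-1)$; a path interior edge has $\kappa = 0$; the bridge
of a barbell (two leafy hubs joined by one edge) has $\kappa = -2/3$.
These closed forms anchor the test suite.

A cohort is processed column by column: sample $s$'s curvature depends
only on sample $s$'s weights. Differential ("delta") curvature between
two samples or groups is the edge-wise difference of (group-mean)
curvatures.

## Parameters that matter

* **`mode`** (`"weighted"`, the default, or `"hop"`): the ground metric.
  Weighted mode folds the measurements into the geometry itself and is
  the default; hop mode is the classical unit-length variant, useful for
  comparability with topology-only curvature analyses. On a regular graph
  with uniform weights the two coincide (all transformed lengths are
  equal, and curvature is invariant to a global rescaling of the metric).
* **`alpha`** (idleness, in $[0,1)$, default 0): self-mass of each
  neighbor measure. The definition above places no mass on the node
  itself, so 0 is the faithful default; the parameter is exposed because
  lazy-walk variants are common in the curvature literature.
* **`pseudocount`** (nonnegative, default 0): added to every node weight
  before normalization. The formulas divide by neighborhood weight sums,
  which a legitimate all-zero neighborhood makes undefined. The package
  refuses such inputs by default and names the offending node rather than
  imputing silently; a positive pseudocount is the explicit opt-in. The
  same device resolves edges with zero two-way transition probability in
  weighted mode.
* **Strictness flags** (`symmetrize`, `largest_component`): the curvature
  computation requires a symmetric adjacency and a connected graph, so
  violations are errors by default; each flag relaxes one check with a
  warning. Adjacency magnitudes are never used as edge weights — any
  strictly positive off-diagonal entry is an edge, and the geometry comes
  entirely from the node measurements.

Node weights enter only through ratios, so curvature is invariant under
global rescaling of a sample's measurements (checked as a property test);
normalization of the input matrix across samples is the user's modelling
decision, not something the statistic imposes.

## Numerical choices

* $W_1$ is computed as the exact transportation LP over the positive-mass
  supports of the two measures, with single-support cases short-circuited
  in closed form. No entropic or approximate solver is used anywhere.
* Kernel rows and measures are validated to sum to one within $10^{-12}$;
  solver-vs-oracle agreement is asserted at $10^{-8}$.
* An independent brute-force oracle (`brute_force_w1`) re-derives the
  optimum by exhaustive search over the vertices of the transportation
  polytope, generated by greedy-deletion pick orders with a
  partial-order reduction (consecutive commuting picks are forced into
  lexicographic order), branch-and-bound pruning, and a greedy feasible
  plan as the initial incumbent. For equal-size uniform-mass supports it
  additionally cross-checks against a permutation search, since an
  optimal coupling may then be taken to be a permutation. The oracle is
  exponential by nature and guards its support size (default 6 per
  measure, overridable); it exists to verify the LP route, never to
  replace it.
* Ties in optimal transport plans are harmless: only the optimal value
  enters $\kappa$.
* Canonical edge identity is the lexicographically sorted label pair, and
  output rows are sorted by it, so results are stable under permutations
  of the input rows/columns (checked as a property test).

## The synthetic-data generator

`make_fixture()` produces the toy motifs used throughout (triangle, path,
star, barbell, complete graph) and Erdős–Rényi `random_connected(n, p)`
graphs redrawn until connected, with uniform weights (the toy-network
convention of unit node weights), i.i.d. log-normal weights
(positive, right-skewed — a crude stand-in for normalized expression), or
user-supplied vectors. The perturbation option reproduces the
single-gene overexpression scenario: all samples share one baseline draw
and exactly one (node, sample) entry is multiplied by a fold change
(10-fold in the canonical example).

What the generator does **not** emulate: correlation structure between
genes, sample-to-sample covariance, realistic interactome degree
distributions, batch effects, or measurement noise models. Passing tests
therefore demonstrate correctness of the computation and its invariances,
not biological validity of conclusions drawn from any particular dataset.

Problem sizes in the tests and the acceptance script are deliberately
modest — 200 random graphs of 4–8 nodes for the solver-vs-oracle sweep
(small enough for the exponential oracle to be exact), and a 50-sample
cohort on a 100-node network with mean degree about 5 (typical of a
focused pathway subnetwork) for the end-to-end run. Curvature on graphs
of this size is fully determined by the same code paths that larger
inputs exercise.

## Design decisions taken where the definition is open

* **One weight, two roles.** The kernel and the neighbor measure use the
  same node weights with the same normalization; the two are deliberately
  not decoupled.
* **Group deltas.** Delta curvature between groups uses the edge-wise
  arithmetic mean per group. Medians or paired designs are reasonable
  alternatives; only the mean is provided, and no p-values or FDR are
  attached — deltas are reported raw.
* **Node-level aggregation.** `node_curvature()` sums incident edge
  curvatures as a convenience (a discrete scalar-curvature analogue); it
  is a reporting device layered on the edge-level definition.
* **Error policy.** Per-sample failures abort the cohort by default
  (`on_error = "skip"` drops the sample with a warning naming it), so a
  silent hole in a curvature matrix cannot masquerade as a result.

## Known limitations

* Undirected networks only; directedness has no meaning in the edge
  length transform used here.
* The transportation LP is solved per edge; cohorts of tens of thousands
  of edges and samples will want parallelization, which is not built in.
* Zero-weight neighborhoods require an explicit pseudocount decision from
  the user; there is no automatic imputation.
* Delta curvature is descriptive. Attaching inference (permutation tests,
  FDR) is downstream of this package's scope.
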