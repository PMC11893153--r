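# riccinet

Edge-level robustness analysis of biological interaction networks from
node-level omics data, via Ollivier-Ricci curvature (ORC).

## The problem

Most network statistics used in bioinformatics — degree, centrality,
modularity — describe nodes or whole graphs. But many biological questions
live on the *edges*: is this interaction backed by redundant alternative
routes (robust), or is it a bottleneck whose failure fragments information
flow (fragile)? Omics assays (RNA-seq, proteomics, ...) measure node-level
quantities, while classical curvature computations expect edge weights.
`riccinet` bridges the two: it takes a nonnegative feature-by-sample matrix
and a binary symmetric adjacency matrix over the same features, maps each
sample's measurements onto the nodes, and returns an Ollivier-Ricci
curvature value for every edge and sample.

## The statistic

For one sample, node weights \(w_i\) define a mass-action random walk on
the (simple, undirected, connected) network:

    p_ij = w_j / Σ_{k~i} w_k      for j ~ i,  0 otherwise

Each node spreads a probability measure over its neighbors the same way
(μ_i(k) = w_k / Σ_{j~i} w_j). Edge lengths are derived from the kernel,

    w̃_ij = (p_ij + p_ji)/2,   length(i,j) = 1/w̃_ij

and the ground distance d(i,j) is the shortest-path distance under those
lengths ("weighted" mode; "hop" mode uses unit lengths). The curvature of
an edge is

    κ(i,j) = 1 − W₁(μ_i, μ_j) / d(i,j)

where W₁ is the Wasserstein-1 (earth mover's) distance, solved exactly as
a transportation linear program. κ ≤ 1 always; κ > 0 marks robust edges
(overlapping neighborhoods, triangles), κ < 0 fragile bridges. Differences
of κ between samples or groups ("delta curvature") localize how a
perturbation — e.g. a 10-fold overexpression of one gene — propagates
through the network, including to edges not incident to the perturbed
gene.

## Worked example

A "barbell" network — hubs G1 and G2 joined by a bridge, with pendant
leaves G3, G4 on G1 and G5, G6 on G2 — under uniform baseline weights,
with gene G3 overexpressed 10-fold in the second sample:

```r
library(riccinet)
fx  <- make_fixture("barbell", n_samples = 2,
                    perturb = list(node = "G3", fold = 10, sample = 2))
fit <- orc(fx$features, fx$adjacency, mode = "hop")
fit
#> Ollivier-Ricci curvature: 5 edges x 2 samples
#> mode: hop, alpha = 0, pseudocount = 0
#> kappa range: [-1.167, 0]; 0% of edge-sample values positive
#>    edge      S1      S2
#> 1 G1|G2 -0.6667 -1.1667
#> 2 G1|G3  0.0000  0.0000
#> 3 G1|G4  0.0000  0.0000
#> 4 G2|G5  0.0000  0.0000
#> 5 G2|G6  0.0000  0.0000

delta_curvature(fit, "S1", "S2")
#> Delta curvature (b - a): a = {S1}, b = {S2}
#> 1 of 5 edges changed; |delta| max 0.5
#>  node_u node_v delta_kappa
#>      G1     G2        -0.5
#>      G1     G3         0.0
#>      G1     G4         0.0
#>      G2     G5         0.0
#>      G2     G6         0.0
```

Reading the numbers: in the baseline sample the bridge G1–G2 has
κ = −2/3, the hallmark of a fragile bottleneck, while the leaf edges sit
at κ = 0. Overexpressing G3 pulls G1's neighbor measure toward G3 and
drops the bridge to κ = −7/6: the only edge that moves (Δκ = −0.5) is the
bridge, which G3 does not even touch — a cascading, non-local robustness
change.

The same workflow is available from the shell:

```sh
riccinet fixtures --topology barbell --n-samples 2 \
    --perturb-node G3 --perturb-fold 10 --perturb-sample 2 --outdir data/
riccinet compute --features data/features.csv --adjacency data/adjacency.csv \
    --mode hop --out data/curvature.csv
riccinet diff --curvature data/curvature.csv --a S1 --b S2 --out data/delta.csv
```

(the launcher script is installed at `exec/riccinet` inside the package;
`Rscript -e 'riccinet::cli_main(...)'` is equivalent.)

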