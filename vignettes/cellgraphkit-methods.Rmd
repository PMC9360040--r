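---
title: "cellgraphkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellgraphkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellgraphkit)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter and their defaults,
the numerical choices, and the places where the design was genuinely open
and we had to commit to one reading.

## Chunked storage and streaming

A count matrix (cells × features) is stored as a grid of dense,
individually compressed chunks (default 2000 × 2000) in a plain directory,
with cell attributes at the store root (shared across assays) and feature
attributes under each assay group; one assay is the default recipient of
operations. Chunk size trades loading cycles against peak memory: larger
chunks stream faster, smaller chunks bound memory harder. Every downstream
operation consumes the matrix through `streamBlocks()` / `iterChunks()`,
whose contract — contiguous, disjoint, ordered row blocks whose
concatenation reproduces the matrix exactly — is what makes all streamed
statistics independent of the block size (the suite checks identity for
blocks of 1, 7 and n). Chunks stay dense throughout; there is no
sparse/dense interconversion anywhere in the pipeline.

## Normalisation and feature selection

Library-size normalisation scales each cell to a common total
`y = S·x/Σx` (default `S = 1000`), optionally followed by `ln(1+y)`.
Natural logarithms are used throughout the package. TF-IDF for peak
matrices is `y = (x/n_Fc)·ln(1 + N_C/n_Cf)`, with the per-cell accessible
count `n_Fc`, the per-peak cell count `n_Cf` and the total cell count `N_C`
always computed over the *full* matrix, never per chunk.

Highly variable genes: per-gene means and variances of the normalised
values are log-transformed; genes are split into equal-*count* bins on log
mean (equal-width bins can be empty, which would starve the trend fit);
one anchor gene per bin feeds a lowess trend (span 0.4, 3 robustness
iterations) whose interpolated prediction is subtracted from each gene's
log variance. The anchor is the *lowest-variance* gene per bin by default:
picking the bin's floor in the binned variable itself would be circular, so
the floor of the response is the reading we adopt; the literal
lowest-*mean* reading remains available via `bin_anchor = "lowest_mean"`.
Mitochondrial (`MT-`), ribosomal (`RPS/RPL/MRPS/MRPL`) and a short
cell-cycle gene list are disqualified before selection (configurable);
these families track library composition and batch far more than cell
state. Ties in corrected variance resolve in stable feature order. Peak
selection ranks prevalence scores — column sums of the TF-IDF matrix.

## Dimension reduction

PCA standard-scales features (scaler fitted on the *training* cells only,
SDs below 1e-8 clipped to 1) and then needs only second moments, so it
streams: up to 1000 selected features the covariance is accumulated
exactly and eigendecomposed; for wider matrices a seeded randomized
subspace iteration (4 block power iterations on the streamed Gram matrix,
10 oversampled directions, Rayleigh–Ritz rotation) gives the leading
subspace with one pass per iteration. The exact path makes the streamed
result literally equal to full-batch PCA (the suite checks principal
angles < 1e-3 on 500 × 50 data streamed in blocks of 7; the achieved
angles are at numerical precision); the randomized path is deterministic
given its seed. Loadings carry a fixed sign convention (largest-magnitude
entry positive) so runs are reproducible. LSI is the same machinery
without centering, applied to the TF-IDF stream — the scATAC analogue of
PCA. Cells outside the training mask are transformed with the trained
scaler and loadings, never refit.

## The neighbourhood graph

The reduced coordinates are indexed for k-nearest-neighbour search under
the Euclidean metric. Two backends satisfy one contract: `exact`
(brute-force blockwise search; the oracle, recall 1 by construction on
distinct points) and `hnsw` (RcppHNSW, graph degree 48, construction beam
200, query beam 100). Each cell queries k+1 neighbours; whether the cell
returns as its own nearest neighbour is recorded *before* self-removal and
summarised as the recall value; on an approximate self-miss the last
neighbour is dropped and the miss counts against recall. The index can be
persisted and reloaded, which is what makes reference mapping cheap.

Distances become weights by the UMAP smoothing scheme with local
connectivity 1: `w_i = exp(−max(0, d_i − ρ)/σ)` with ρ the nearest
distance, σ bisected (64 iterations, bracket tolerance 1e-8) so that
`Σ w_i = log2(k)`. The nearest neighbour always gets weight 1. Two
degeneracies are clamped: when all k distances are equal the budget is
unreachable and all weights are 1; weights underflowing 0 are floored at
1e-12 to respect the (0,1] contract. Directed k-lists are stored; graph
algorithms consume the fuzzy-union symmetrization
`w∪ = w1 + w2 − w1·w2`, which connects two cells if either lists the
other.

The initial embedding for 2D/3D engines comes from k-means on the reduced
coordinates (default `c = min(100, n/10)` centroids — enough resolution to
seed layout without overfitting; the choice is configurable), a second PCA
of the c × d centroid matrix down to 2–3 dimensions, and assignment of
each cell to its centroid's projection, so co-clustered cells start at
identical coordinates.

## Clustering

Leiden is delegated to igraph's implementation (modularity objective); our
contract is determinism under a fixed seed, a resolution parameter
(default 1.0), and relabelling by decreasing cluster size.

Paris hierarchical clustering is implemented from scratch. Cluster
distance follows the node-pair sampling model,
`d(a,b) = p(a)p(b)/p(a,b)` with `p(a) = w(a)/2w_tot` and
`p(a,b) = w(a,b)/w_tot`: pairs sharing more edge mass than their sizes
predict merge first. The distance is reducible, so the
nearest-neighbour-chain algorithm — walk to the nearest neighbour until a
reciprocal pair appears, merge, resume — produces the same hierarchy as
exhaustive greedy agglomeration (the suite verifies equality on all
labeled connected graphs with up to 5 nodes and on seeded random graphs of
6–8 nodes; exhaustive labeled enumeration beyond that is combinatorially
out of reach). Reducibility also guarantees that sorting the merges by
height keeps children before parents, which is what makes the stored
dendrogram valid. Disconnected graphs yield one dendrogram per component,
joined under a synthetic root at height +∞ (exports replace ∞ by twice the
largest finite height). Cutting removes the k−1 highest merges via
union-find, so cuts are nested by construction. We run Paris on the
symmetrized smoothed weights — the same graph Leiden sees.

## Topology-assisted downsampling

Two per-node scores summarise local topology on the binarised graph: the
n-step neighbourhood degree NND (summed degree over the ≤ n-step
neighbourhood; default `n_steps = 2`, configurable) and neighbourhood
connectedness NC, the sum over a node's neighbours of the
shared-nearest-neighbour Jaccard similarity `|N(v)∩N(u)|/|N(v)∪N(u)|`.
Raw neighbour sets are used in the Jaccard (so a triangle scores 1/3 per
pair); this is the standard SNN form and the one consistent with "strongly
interconnected neighbourhoods score high". Both are density/redundancy
proxies: clusters whose medians are high are safe to sample thinly.

Only the *direction* of the rate adjustment is prescribed by the method's
description, so the functional form is our design and is deliberately
simple: cluster medians of NND and NC are rescaled across clusters to
[1, 2] and the rate is `clip(base/(s(nnd)·s(nc)), min, max)` — monotone
decreasing in both scores, equal to `base` when topology is flat, and at
most a factor 4 below it. `base_rate` doubles as the maximum sampling rate
(default 0.01); every non-empty cluster is allotted at least one cell.
Seeds are the medoids of a per-cluster k-means sub-clustering into
`n_to_sample` groups.

Seeds get a uniform prize (default 10); edges cost
`E_p = E_cm·E_bw^(−E_w)` (defaults 1 and 10), so well-supported edges are
cheap and the bandwidth sharpens the contrast; `E_bw ≤ 1` is rejected
because it cannot discriminate. An unrooted prize-collecting Steiner tree
then connects the seeds, one tree per graph component. The solver builds
the metric closure over seeds by shortest paths, takes its MST, expands
the paths, re-MSTs the expansion, and finally runs an exact
prize-collecting dynamic program on that tree, which can still drop seeds
whose connection costs more than their prize. On tree-shaped graphs this
is provably exact (with prizes on seeds only, the optimum lies inside the
seeds' Steiner tree); on general graphs it is a heuristic that the suite
holds to within a factor 2 of an exhaustive-search oracle on small graphs
(and equality on trees). A component that contains a single seed can never
grow a tree and would leave that cell isolated in the sketch, so any
multi-cell component with exactly one seed receives a second landmark (the
cell farthest from the first in reduced space) — on well-separated data,
where each population forms its own component, this is what keeps the
non-zero-degree fraction of the sketch at 100%.

## Reference mapping

Mapping is reference-anchored: the target is interpreted in the
reference's space, never the other way round. Cells (reference and target)
are rescaled so their sums over the *reference's* HVGs equal a common
total (default 1000) — this cancels composition shifts such as one batch
capturing more ribosomal mass, under the usual assumption that batch
effects are orthogonal to the heterogeneity captured by the HVGs. Cells
with a zero HVG sum cannot be rescaled and are excluded by id, never
zero-filled.

CORAL aligns second moments: both matrices are z-scored per feature (each
with its own statistics), covariances are shrunk by adding 1 to the
diagonal, and the target is whitened with its own covariance and
recoloured with the reference's, `A = Cov(S)^{1/2}·Cov(T)^{−1/2}`. The
variant with both exponents at +1/2 circulates in descriptions of the
method but does not whiten — under it `cov(A·T) ≠ cov(S)` — so the
whiten–recolour form is the default and the +1/2 variant is kept behind
`literal = TRUE` for comparison. Matrix roots use symmetric
eigendecomposition with eigenvalues floored at 1e-8. Corrected targets are
projected with the reference's loadings (`apply_scaler = FALSE`, since
CORAL output already lives in the scaled space); without CORAL the target
is z-scored with the *reference's* scaler. Either way the reference's PCA
and index are never refit.

Mapped edges get weights `W = 1/(ln(D+1)+1)` (1 exactly at distance 0,
strictly decreasing); the unified graph spikes each target into the
reference graph with exactly `top_m` edges (default 3) at constant weight
(default 1), leaving the reference sub-block untouched; mapping scores
aggregate incoming weight per reference cell normalised by the target
count (`M_r = Σ W_rt / N_T`, optionally `ln(1000·M + 1)`); label transfer
assigns the class holding ≥ 50% of a target's edge weight when it is the
unique maximum, else NA. The threshold applies over all k mapped
neighbours (not only the spiked `top_m`) — using the full neighbourhood is
the more conservative reading. For unified embeddings, target cells are
initialised at the mean of their `top_m` reference neighbours' initial
coordinates and the engine runs for 100 iterations.

## Evaluation statistics

Marker scores rank each feature's normalised values across cells (average
ranks on ties — so a constant feature scores uniformly), average the ranks
within clusters and normalise by the sum over clusters, giving scores in
[0, 1] that sum to 1 per feature. Ranking across cells is the only reading
under which a per-cluster mean rank and that normalisation are coherent; a
per-cell ranking alternative exists but produces cluster scores with no
common scale. The remaining metrics are direct: average centroid distance
in an embedding; log2 cluster enrichment of a selection (−∞ flagged when a
cluster is missed); percentage of selected cells with an edge to another
selected cell; mean KNN overlap between graph and embedding
neighbourhoods; and per-cluster Spearman correlation between
log2-transformed cluster-similarity matrices (pseudo-count 1, since
disconnected cluster pairs legitimately share zero edge weight; rank
correlation requires at least 3 clusters).

## Embedding engines

2D/3D layout engines are pluggable behind one contract: the engine
receives the symmetrized graph and the initial embedding unchanged (this
module never recomputes neighbours), `n_iter = 0` returns the
initialisation untouched, and a fixed seed reproduces coordinates. The
default engine is igraph's weighted Fruchterman–Reingold layout; `umap`
uses uwot when installed; a graph t-SNE engine is not available in this
build and requesting it raises a capability error rather than silently
substituting.

## The synthetic-data generators

The generators exist so every module is testable without downloads, and
their defaults are the package's study conditions. Clustered scRNA-seq:
gamma-distributed per-gene baselines, disjoint per-cluster DE programs
(`de_fraction = 0.1` of genes up-regulated `fold = 4`), log-normal library
factors (σ = 0.3), negative-binomial counts parameterised by mean and
dispersion (`var = μ + 0.5μ²`), multinomial cluster sizes so a 1%
population is genuinely rare. Trajectory data interpolate gene programs
linearly between stage anchors along a uniform pseudotime; a tenth of the
genes are constructed log-linear in pseudotime (on a raised baseline, so
the trend survives count noise) for correlation checks. scATAC emulation
binarises clustered counts over an inflated feature panel. The generators
emulate cluster separation, library-size variation, overdispersion, rarity
and continua; they do not emulate ambient RNA, doublets, batch-specific
nonlinear distortions, zero-inflation beyond the NB, or realistic gene–gene
correlation structure — so green tests certify algorithmic behaviour under
the stated models, not performance on any real tissue.

Benchmark problem sizes used by the packaged evaluations: connectivity of
the downsampler is measured on 5,000-cell clustered (8 populations, one at
1%) and 3,500-cell trajectory simulations, ten runs each, with 2,500 HVGs,
25 PCA dimensions, k = 21, Leiden clustering and a 1% maximum sampling
rate; CORAL recovery uses a 6,000-cell three-population simulation split
into reference and target halves with a log-normal (σ = 1) per-gene
distortion; oracle comparisons run on exhaustively enumerated ≤ 5-node
graphs plus seeded random 6–8-node graphs.

## Known limitations

Paris runs in-memory over the symmetrized edge list in pure R; it is
comfortable at tens of thousands of cells but is the first candidate for
compiled code at atlas scale. The exact KNN backend is quadratic — it is
the oracle and the default at desk scale, with HNSW available for large n.
The PCST solver is a constructive heuristic, not an approximation-ratio
algorithm on general graphs; its tree-DP pruning stage is exact only on
the tree it is given. CORAL corrects second moments under a linear model
and will not remove nonlinear batch structure. Multi-assay stores share
one cell table, so assays must agree on the cell set.
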