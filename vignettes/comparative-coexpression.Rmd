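---
title: "Comparative co-expression network analysis with comparex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative co-expression network analysis with comparex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comparex)
```

## The problem

Divergence in gene regulation, rather than in protein-coding sequence, is a
major driver of species differentiation in plants. One way to study it
without requiring comparable samples across species is to infer a
co-expression network per species from large expression compendia and then
ask, through sequence-predicted orthologs, which parts of the network are
conserved: individual gene–gene links, the statistical overlap of whole
network neighbourhoods, global properties such as scale-free organization
and gene centrality, and small regulatory motifs. `comparex` implements this
comparative pipeline end to end, together with a synthetic multi-species
generator with planted ground truth so that every stage can be validated
quantitatively.

## Network inference

For each gene pair the package computes normalized mutual information with a
B-spline estimator: sample values are rank-transformed, mapped onto a
uniform knot vector with `n_bins` basis functions of order `spline_order`
(default 3), and each sample contributes soft membership weights (summing
to 1) to the bins. Plugin entropies $H(X)$, $H(Y)$, $H(X,Y)$ are computed
from the weighted joint histogram, the marginals being the margins of that
same joint, so that

$$\mathrm{MI}(X,Y) \;=\; \frac{H(X)+H(Y)-H(X,Y)}{\min\{H(X),H(Y)\}} \in [0,1]$$

holds by construction ($H(X,Y) \ge \max\{H(X),H(Y)\}$ for any joint).
Rank transformation makes the score invariant to monotone transformations
and robust to outliers. Genes with zero variance have zero marginal entropy
and score 0 against everything; they are kept in the matrix so the gene
universe stays aligned across thresholds.

Two numerical facts are worth knowing. First, with `spline_order = 1` the
estimator reduces *exactly* to hard-binned histogram MI (the test suite
asserts agreement to 1e-12 against an independent implementation). Second,
with soft binning (order > 1) the self-comparison of a gene with an
identical copy does not reach 1: each sample's weight is spread over
adjacent bins, which adds joint entropy that the marginals do not carry, so
self-MI equals $H_{\text{bins}}/(H_{\text{bins}}+\bar h)$ where $\bar h$ is
the mean per-sample weight entropy (about 0.53 at 100 samples, 10 bins,
order 3). The bound MI ≤ 1 is what the normalization guarantees; only hard
binning attains it.

The bin count defaults to square-root scaling in the number of samples,
clamped to $[4, 16]$. (Quadratic scaling is not meaningful — several
thousand samples would imply tens of millions of bins — and the cited
estimator literature recommends root-scale bin counts.)

The context likelihood of relatedness (CLR) background correction turns the
MI matrix into edge-specific Z-scores: for gene $i$ with off-diagonal row
mean $\mu_i$ and standard deviation $\sigma_i$,
$z_i(j) = \max\{0, (\mathrm{MI}_{ij}-\mu_i)/\sigma_i\}$ and
$\mathrm{CLR}_{ij} = \sqrt{z_i(j)^2 + z_j(i)^2}$; $\sigma_i = 0$ gives
$z_i \equiv 0$. Thresholding the CLR matrix (edge iff CLR ≥ t, ties kept)
yields the co-expression network; the regulation view directs every edge
incident to an annotated transcription factor as TF → gene and keeps TF–TF
edges reciprocal in both directions, because one-way TF→TF directionality
is not inferred from co-expression.

## The synthetic generator and its scale-down design

`scenario_spec()` + `simulate_study()` produce per-species expression
matrices, an OrthoMCL-style ortholog map with BLAST bit-scores, TF lists,
GO annotations and a planted ground truth. The expression model is a
latent-factor model: each module has a per-sample factor
$z_m \sim N(0,1)$; a member gene's value is $\ell \cdot z_m + N(0,
\sigma_{\text{noise}})$ with loadings $\ell \sim U(0.5, 1.5)$; background
genes follow the same model with a private factor. Conserved ortholog pairs
occupy the *same* module in both species (so their network neighbourhoods
map onto each other), diverged pairs occupy different modules, unrelated
genes have no ortholog. A duplicated gene receives one conserved (`_a`) and
one diverged (`_b`) copy, and a fair coin decides which copy gets the
higher bit-score, making sequence similarity uninformative about regulatory
conservation by construction.

The default study conditions are 300 genes × 100 samples per species,
4 modules of 65–85 genes, class fractions 0.85 / 0.10 / 0.05
(conserved / diverged / unrelated), duplication rate 0.10, TF fraction
0.10, noise SD 0.5. The module geometry follows from an explicit scale-down
power analysis rather than from the appearance of real networks: the
divergence test is the *lower* hypergeometric tail of the neighbourhood
overlap $x$ under $\mathrm{Hyp}(N, k, n)$, and even a perfect zero overlap
has $p \approx e^{-nk/N}$. Detecting planted divergence at FDR 0.05 in a
300-gene universe therefore requires the null overlap expectation
$nk/N \gtrsim 10$, i.e. neighbourhoods of ~60–80 genes. Compendium-scale
data reach that operating point with much smaller *relative* neighbourhoods
(at $N \approx 2\times 10^4$ and 10% network density, $nk/N$ is in the
hundreds); a faithful desk-scale analogue must preserve the operating point,
not the relative sizes. The same analysis explains an observation reported
for the real networks: genes with small neighbourhoods cannot show
significant divergence even when their neighbourhoods share nothing.

Module sizes are drawn from the configured range with probability
$\propto s^{-2.5}$: co-expression cluster sizes in real networks are
heavy-tailed, and over a narrow range (such as the default 65–85) the law
is effectively uniform. With a wide range this produces many small, tight
modules and few large diffuse ones, which is what makes the degree
distribution of the high-threshold network heavy-tailed (a module of size
$s$ contributes $s$ nodes of degree ≈ $s-1$, so the node-degree mass
follows $s \cdot s^{-2.5} = s^{-1.5}$).

What the generator deliberately does not emulate: probe-level microarray
artefacts, cross-hybridization between paralogs, heterogeneous experiment
(batch) structure, and correlated modules. Passing the recovery tests
therefore shows the statistical machinery is correct at its operating
point, not that real compendia meet the model's assumptions.

## Degree-distribution fitting

`fit_degree_distribution()` fits the degrees of connected nodes to a
discrete power law (MLE for the exponent via a Hurwitz-zeta normalizer,
$x_{\min}$ chosen by a Kolmogorov–Smirnov scan) and to a Poisson law with
$\lambda$ equal to the mean degree. Classification compares total
log-likelihood on the common support $x \ge \max\{1, x_{\min}\}$, both
models renormalized to that support, with a margin of 2 log-units; smaller
differences, or degenerate degree samples, are `indeterminate`. On
synthetic module data with heavy-tailed module sizes the classification
flips from `random` at permissive thresholds (where noise edges dominate
and degrees concentrate around their mean) to `scale_free` in the stringent
regime — the state-switch behaviour seen in real co-expression networks.

## Motifs

Motif classes are typed directed graphs over TF/gene nodes under the
regulation-network link semantics (TF–TF reciprocal, TF→gene, genes emit
nothing), reduced to canonical representatives by minimizing the adjacency
bit-string over type-preserving permutations. Exhaustive enumeration gives
6 connected classes of size 3 — including the pattern of two connected TFs
regulating the same gene (the "feed-forward loop" in the loose sense used
for reciprocal TF–TF links) — and 24 classes of size 4, including the
bi-fan. Published counts for this motif vocabulary sometimes state 22
four-node classes; our canonical-form census, cross-checked class-by-class
with igraph's VF2 isomorphism on colored graphs, finds 24 (1 class with one
TF, 6 with two, 11 with three, 6 with four), and no natural exclusion rule
reproduces 22, so 24 is what the package asserts.

Counting is by connected *induced* subgraphs (ESU enumeration,
oracle-checked against exhaustive subset enumeration), so class counts sum
to the number of connected induced subgraphs of that size. Enrichment
Z-scores compare observed counts on a GO term's induced subnetwork against
the same gene set in degree-preserving randomized networks: the TF→gene
stratum is rewired by bipartite double-edge swaps (preserving out- and
in-degrees exactly), the TF–TF stratum as an undirected graph, 10×|E| swap
attempts each, no self-loops or multi-edges; degree preservation is
asserted on every draw.

## Cross-species comparison

Comparing species S1 to S2, eligibility requires a gene to be connected in
S1 with at least one ortholog connected in S2. A link A–B is conserved if
*any* ortholog of A links to *any* ortholog of B in S2. The neighbourhood
test maps the neighbours of the ortholog A′ back to S1 (de-duplicated) and
computes both hypergeometric tails of the overlap; `N` is the full S1 gene
universe (configurable), `n` the neighbourhood size of A, `k` the mapped
neighbour count, `x` the overlap. Benjamini–Hochberg FDR is applied
separately to the conserved-tail and diverged-tail families of a directed
comparison — two one-sided families must not be pooled. Gene categories
(Conserved, Conserved-and-Diverged, Diverged, None) follow from the
significant tests per gene; multi-ortholog summaries add Uniquely conserved
with precedence over the mixed categories; reciprocal classification keeps
a call only when the most significant ortholog relation is mutual, with a
fully deterministic tie-break (p, then overlap x, then bit-score, then
lexicographic id; missing bit-scores rank last, never "best").

Two conventions deserve a note. Link-conservation fractions are `NA` when
no eligible links exist. The neighbourhood conservation *fraction*
(`neighbourhood_conservation_fraction()`) is instead reported as 0 when no
gene remains eligible: at thresholds beyond the score range no gene has a
conserved neighbourhood, and reporting 0 keeps threshold sweeps
interpretable where the eligible set vanishes; `n_eligible` is always
reported alongside so the degenerate case is visible.

Null models follow the study design: name-shuffled networks (topology
intact, labels permuted) for link conservation, and randomized gene or term
lists with the +1-corrected empirical p-value $(r+1)/(n_{\text{rand}}+1)$
for all top-fraction conservation statistics (centralities, subnetwork
statistics, motifs). Top-fraction membership takes exactly
$\lceil f \cdot n \rceil$ items, ranked by value with ties broken by id, so
reruns are deterministic.

## Problem sizes and reproducibility

The test suite and the acceptance script run on the generator's default
study conditions (300 genes × 100 samples per species for the recovery
analyses; 400 genes for the degree-distribution sweep; 200 genes for the
MI-bound target), sizes at which the full pipeline — two MI matrices, CLR,
networks at several thresholds, all neighbourhood tests and 100 null
randomizations — completes in well under two minutes. All randomness flows
through explicit seeds: scenario outputs are pure functions of the spec
(including its seed), and every randomized procedure takes a seed argument
and restores the caller's RNG state. `run_pipeline()` records seeds,
parameters and file checksums in its manifest, and rerunning a
configuration reproduces byte-identical outputs.

## Known limitations

* Desk-scale universes compress the CLR score range (a gene's background
  contains a large elevated block when modules are a sizable fraction of
  the genome), so the meaningful threshold range is roughly 0.5–8 on
  synthetic data versus 1–30 on compendium-scale data.
* Divergence calls need large neighbourhoods (see the power analysis
  above); this matches the behaviour reported for real networks but means
  small planted modules cannot exercise the diverged branch.
* The generator's conserved pairs share module identity exactly; partial
  neighbourhood conservation arises only through loading noise and edge
  dropout, not through genuinely overlapping module structure.
* GO annotations in the generator are one term per module plus a background
  term; term-to-term correlation structure of real ontologies is not
  modelled.
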