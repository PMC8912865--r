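---
title: "Methods: regulator-centric coexpression networks with coexreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulator-centric coexpression networks with coexreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexreg)
```

`coexreg` analyses gene expression (TPM) tables around designated regulator
transcripts — in the motivating fungal setting, the cellulase activator XYR1
and the carbon-catabolite repressor CRE1. This vignette documents the models
and procedures, the parameters that matter, the synthetic-data generator used
for validation, and the numerical and design choices made where the
methodology left room.

## The coexpression model

### Input and filtering

The input is a genes × samples matrix of TPM values with per-sample condition
labels (e.g. cellulose vs glucose, three or more replicates each). Two
filters precede network construction:

* **Low expression** (`filter_low_expression()`): a gene is removed only
  when, in *every* condition, the fraction of samples with TPM exactly 0
  exceeds `max_zero_fraction` (default 0.5, i.e. "most replicates"). The
  per-condition rule deliberately retains condition-specific transcripts — a
  cellulase expressed only on cellulose survives. A global variant (all
  samples as one condition) is available by passing `samples = NULL`.
  "Null" is read as exactly 0 because TPM tables carry no missing-value
  sentinel. Values are used as raw TPM; correlations are invariant to
  per-gene affine rescalings, so a log transform mainly changes the relative
  influence of high-expression samples and is left to the user upstream.
* **Constant genes** (`drop_constant_genes()`): zero-variance profiles have
  undefined Pearson correlation and must be removed; the function warns and
  records what it dropped.

Both filters preserve gene order and are idempotent.

### From correlation to modules

1. **Correlation.** Pairwise Pearson `r_ij` over samples
   (`pearson_matrix()`, ≥ 3 samples required).
2. **Signed adjacency.** `a_ij = ((1 + r_ij) / 2)^β`
   (`signed_adjacency()`). The signed map keeps anti-correlated pairs apart
   (r = −1 → a = 0) instead of conflating them with positively correlated
   ones, which matters when an activator and a repressor live in the same
   network.
3. **Soft power β.** `pick_soft_power()` scans an ascending candidate grid
   (default 1–50, wide enough for strongly saturated networks) and picks the
   smallest β whose **scale-free fit index** reaches `r2_target` (default
   0.8). The fit index (`scale_free_fit()`) bins connectivities
   `k_i = Σ_{j≠i} a_ij` into `n_bins = 10` equal-width bins and regresses
   `log10` (fraction of nodes per bin) on `log10` (mean k per bin) over
   non-empty bins; the index is `R² · (−sign(slope))`, so only a *decreasing*
   degree distribution scores well. A network whose connectivities are all
   equal is flagged degenerate with index 0. When no candidate reaches the
   target the scan is still returned and the pipeline falls back to the
   best-fitting power with a message — small dense simulations legitimately
   never look scale-free, and silently picking the maximum power would hide
   that.
4. **Topological overlap.** `TOM_ij = (L_ij + a_ij) /
   (min(k_i, k_j) + 1 − a_ij)` with `L_ij = Σ_{u≠i,j} a_iu a_uj`
   (`topological_overlap()`), computed by matrix product with the diagonal
   zeroed so that self-terms never leak into `L` or `k`. Entries are clamped
   to [0, 1] and the matrix is symmetrized against floating-point drift in
   the crossproduct; a triple-loop brute-force oracle in the test suite
   pins the implementation to the formula within 1e−10.
5. **Clustering.** Average-linkage hierarchical clustering of the
   dissimilarity `1 − TOM` (`cluster_dendrogram()`, `stats::hclust`), which
   is deterministic for a fixed input ordering.

### Adaptive module cutting

`cut_modules()` implements a gap-based adaptive cut rather than a fixed
cut height. The intuition: in an average-linkage tree over `1 − TOM`,
within-module merges form a low continuum, and the merges that join distinct
modules (or attach unclustered background genes) sit clearly higher, leaving
a visible gap in the sorted merge-height distribution.

The algorithm sorts all merge heights, searches the window between a lower
quantile and the `cut_height_quantile` quantile (default 0.99) for the five
widest gaps, and evaluates a cut at each gap's midpoint. Candidates are
ranked by (1) the number of clusters of at least `min_module_size` leaves
the cut retains, (2) the number of genes those clusters cover, then (3) the
gap width. The first criterion rejects cuts so high that modules merge; the
second rejects cuts so low that modules fragment into pieces that still pass
the size threshold. Clusters below `min_module_size` are left unassigned
(module 0), and retained modules are renumbered 1, 2, … by decreasing size
(ties by smallest member gene id, for determinism).

`deep_split` (0–3, default 2) sets the lower bound of the gap-search window
at the 0.75 / 0.625 / 0.5 / 0.375 quantile of merge heights: larger values
look deeper into the tree and therefore allow finer modules. If no positive
gap exists in the window (e.g. all heights equal) the cut falls back to the
`cut_height_quantile` height. `min_module_size` defaults to 30, the
conventional floor below which a coexpression module is hard to interpret
or enrich.

This is a deliberate departure from the reference dynamic tree-cut
implementations: the variant here is a single adaptive cut with a candidate
search rather than a recursive branch analysis. It is validated by
planted-module recovery (adjusted Rand index against a known truth), not by
label-for-label equality with any particular implementation; the method name
is recorded in the pipeline manifest (`"widest-gap adaptive cut"`).

### Regulator groups

`regulator_group()` returns the module containing a named regulator. Two
failure modes are kept distinct: a regulator id absent from the analysis
because filtering removed it (error class `coexreg_filtered_regulator`,
detected when a pre-filter `universe` is supplied) versus an id never seen
(`coexreg_unknown_gene`). A regulator landing in the unassigned set returns
module 0 with a warning rather than an error, since that is a legitimate —
if disappointing — outcome.

## The HRR network

The highest-reciprocal-rank network (`build_hrr_network()`) is built
directly from the correlation matrix. Each gene ranks all others by
decreasing `r` (ties by gene id); the HRR rank of a pair is
`max(rank_i(j), rank_j(i))` — an edge is only as good as its *weaker*
direction, which prevents a single promiscuous hub from accumulating edges
to genes that do not reciprocate. An edge is kept iff `r_ij ≥ r_threshold`
(default 0.8) **and** HRR rank ≤ `max_rank` (default 30). Edges carry a
band weight of 1/5 (ranks 1–10), 1/15 (11–20) or 1/30 (21–30) — the three
bands are read as disjoint rank intervals, the only reading consistent with
three distinct codes. The threshold applies to positive `r` by default,
since HRR edges represent *coexpressed* neighborhoods; `absolute = TRUE`
switches to `|r|` for users who want anti-correlated edges too.

Structural guarantees asserted in tests: no self-loops, symmetric
construction, band weights take only the three coded values, and the edge
count never exceeds `n · max_rank / 2`.

## Topology around the regulators

* **Hubs** (`degree_and_hubs()`): all nodes tied at the `top_k` highest
  distinct degree values. Hubs are conventionally sought within a module
  subnetwork (`module_subnetwork()`), because a module's hub need not be a
  global hub; pass the global network for global hubs.
* **First neighbors** (`first_neighbors()`): the distance-1 shell of a
  focal transcript, joined with module labels, functional categories and DE
  status, plus the count of distinct modules the neighborhood spans.
* **Geodesics** (`geodesics()`): breadth-first search gives the shortest
  path ("the minimal number of edges"), and the number of distinct shortest
  paths is accumulated with the standard predecessor-sum recurrence
  (`count(v) = Σ count(u)` over neighbors `u` one level closer to the
  source). Counting by recurrence scales linearly in edges; the exhaustive
  path-enumeration oracle exists only in tests. Unreachable and absent
  targets are reported explicitly (`reachable = FALSE` with a reason), never
  as sentinel numbers.
* **Transitive transcripts** (`transitive_transcripts()`): for pairs at
  distance exactly 2, the middle nodes — the candidates for indirect
  regulation between a TF and a CAZyme. For other distances the result is
  empty and carries the observed distance.
* **Regulator × target matrices** (`regulator_target_geodesics()`): long
  tables of distance and geodesic count per (regulator, CAZyme) pair,
  rendered by `plot_geodesic_heatmap()`. We interpret the two reported
  quantities as (a) geodesic length and (b) number of distinct geodesics;
  this interpretation is recorded in the pipeline manifest because the
  heatmap convention is not self-describing.

Shortest paths treat edges as unweighted; the band weights are
visualization and export attributes only.

## Functional characterization

`go_enrichment()` performs classic one-sided Fisher overrepresentation per
GO term: with `N` background genes, `K` annotated, module size `n` and `k`
annotated module members, `p = P(X ≥ k)` for hypergeometric `X` — computed
via `stats::phyper(k − 1, K, N − K, n, lower.tail = FALSE)` and verified in
tests against an explicit binomial-coefficient summation to 1e−12. Choices:

* Annotations are taken exactly as supplied — no GO-graph propagation and no
  elim/weight-style decorrelation. Flat gene→term tables keep the test
  honest and the behavior predictable; an ontology-aware pass is future
  work.
* The default background is **all filtered transcripts** (the gene universe
  that could have entered a module), configurable via `background_genes`.
* The significance flag uses the raw `p < alpha` (default 0.05) to match the
  common raw-threshold convention; Benjamini–Hochberg correction is
  available behind `adjust = TRUE` and then flags on the adjusted value.

`category_tally()` counts module genes per CAZyme family, TF class,
transporter class, KO pathway class or DE status; `cazyme_class` aggregates
families into GH/GT/CE/PL/AA/CBM by prefix. `de_overlap()` reports
up/down/none counts for a gene set. KO and DE assignments are always
consumed from user-supplied tables, never fetched from live databases, so
results cannot drift with database versions.

## The synthetic-data generator

`simulate_coexpression()` plants `n_modules` modules of `genes_per_module`
genes: each module has a latent eigenprofile drawn i.i.d. standard normal
per sample (optionally offset in the first condition via `condition_effect`,
so condition-specific "DE" modules can be planted); member gene `g` is
`loading_g · eigenprofile + N(0, noise_sd)` with loadings uniform in
`loading_range` (default [0.5, 1]). Background genes are i.i.d. Gaussian
noise. Every gene is then shifted to minimum 0 and rescaled to a TPM-like
mean — a positive affine map, so all correlations, and hence every
downstream quantity, are unchanged by it. Regulators are planted as ordinary
members of designated modules. `simulate_annotations()` adds GO-like terms
annotated to a chosen fraction of each module plus a background rate,
random category labels, and per-module DE status. Generation is
deterministic given the design (including its seed).

What the generator emulates: the shape of a replicated two-condition TPM
study (the motivating design is 3 replicates × 2 carbon sources, ~11,000
transcripts after filtering), block-structured coexpression, regulators
embedded in modules, and enrichment signal of known strength. What it does
**not** emulate: count noise and library-size effects, correlated background
structure, hub-and-spoke topology within modules, overlapping modules, or
realistic GO term hierarchies. Passing the recovery tests therefore shows
the machinery is correct on well-posed inputs; it does not certify
performance on real transcriptomes, where module boundaries are far fuzzier.

Default design and validation scale: 5 modules × 100 genes plus 100
background genes over 20 samples at `noise_sd = 0.3`. Module recovery is
asserted at ≥ 20 samples only — with 6 samples (the real study's size)
pairwise correlations are too noisy for a recovery guarantee, and the
package supports but does not promise that regime. At these sizes the full
test suite runs in well under a minute and the end-to-end acceptance script
in about half a minute. Matrices are dense, so memory grows as `n²` genes;
around 10–15k genes (a filtered fungal transcriptome) the correlation, the
adjacency and TOM each occupy roughly 1–2 GB and the TOM product dominates
runtime.

## Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1] and diagonals set to exactly 1;
  adjacency and TOM entries are clamped to [0, 1] (assertions in tests).
* Ties everywhere break by gene id (neighbor ranking, module renumbering),
  making every output deterministic for a fixed input.
* `hclust` average linkage is deterministic; a single-gene input returns a
  degenerate one-leaf tree and a single (or unassigned) module rather than
  an error.
* A `min_module_size` larger than the gene count yields all-unassigned with
  a warning. A uniform-degree adjacency yields a degenerate scale-free fit
  flag, not a spurious index.
* The pipeline manifest (`run_pipeline()`) records package version,
  parameters, the seed, the cut-method name, the geodesic interpretation
  note, and an MD5 checksum per output file, with output names stored as
  basenames so that manifests from identical configs are byte-identical
  regardless of where the run directory lives.

## Known limitations

* No module eigengenes, module–trait correlation or preservation
  statistics — out of scope for the regulator-centric questions addressed
  here.
* No weighted shortest paths or centralities beyond degree.
* Enrichment treats GO terms independently; hierarchically related terms
  will co-report.
* The adaptive cut assumes modules separate from the background by a height
  gap; data with a smooth merge-height continuum (very high noise, or
  strongly nested modules) will under-split toward fewer, larger modules.
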