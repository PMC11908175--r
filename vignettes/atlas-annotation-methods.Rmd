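---
title: "Methods: annotating a lineage-traced fly brain snRNA-seq atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating a lineage-traced fly brain snRNA-seq atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2atlas)
```

# The problem

Adult *Drosophila* central-brain atlases built from single-nucleus RNA-seq
arrive as a clustered cells-by-genes count matrix. When type-II (T2)
neuroblast progeny carry permanent lineage-tracing transgenes (FLP
recombinase plus GFP/RFP reporters flipped on by a T2-specific driver),
the same matrix also encodes each nucleus's developmental origin: any
detected transgene read marks a T2-derived cell, and triple-negative cells
are attributed to type-I (T1) lineages. `t2atlas` implements the
downstream annotation layers that turn such a matrix into biology: lineage
assignment, QC, cluster markers, fast-neurotransmitter and neuropeptide
classification, transcription-factor (TF) combinatorial codes, sex-biased
clusters, and three procedures for mapping clusters onto known neuron
types. Cluster labels are consumed as input — graph clustering and data
integration are upstream concerns and deliberately out of scope.

# Model and procedures

## Normalisation

Counts are depth-normalised per cell and log-transformed,
$\ell_{ij} = \log(1 + s\,c_{ij}/d_i)$ with scale factor $s = 10^4$ and
depth $d_i = \sum_j c_{ij}$, the standard convention for UMI data. The
`scaled` layer is the per-gene z-score of $\ell$ across cells; the
"scaled average expression" used for heatmaps and enhancer-gene scoring is
instead the per-gene z-score *across clusters* of the cluster means of
$\ell$. All z-scores use the sample standard deviation ($n-1$), matching
`scale()`; genes with zero variance map to 0 rather than NaN. Cells with
zero depth get an all-zero row and a warning instead of an error, because
they are legitimately produced by aggressive gene subsetting.

## QC

Cells are retained when their detected-gene count lies in
`[min_genes, max_genes]` = [200, 2500] (inclusive — the thresholds are
phrased as "fewer than 200" and "more than 2500", so the bounds
themselves pass) and their mitochondrial read fraction is at most 5%.
A cell failing several criteria is tallied once, under the first failure
(low genes, high genes, mito), so the report partitions the input. With
no annotated mitochondrial genes the mito criterion is skipped, warned
about, and recorded in the report rather than silently passing.

## Lineage assignment

T2 positivity is "at least `min_counts` reads of any transgene", with
`min_counts = 1`: the sparsity of snRNA-seq makes any detected transgene
read strong evidence, and no published threshold exists to adopt. The
partition is exhaustive and binary — there is no "ambiguous" class —
because downstream bookkeeping (T1 count + T2 count = total) depends on
it. The threshold is exposed for sensitivity analyses.

## Marker detection

`find_all_markers()` is a one-vs-rest two-sided Wilcoxon rank-sum on the
log-normalised layer, the default test of the major single-cell toolkits,
implemented here as a vectorised tie-corrected normal approximation with
continuity correction (exactly `wilcox.test(exact = FALSE, correct =
TRUE)`; the test suite asserts agreement to 1e-10). One-vs-rest tests
share their ranking across clusters, so ranks are computed once per gene.
Genes are prefiltered before testing — detection fraction below
`min_pct = 0.1` in both groups, or |log2 fold-change| below 0.25 —
and Benjamini–Hochberg adjustment runs per cluster over the tested set,
mirroring the behaviour users of `FindAllMarkers`-style tables expect.
The fold-change is `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) +
1))`, stated explicitly so results can be cross-checked. Clusters with
fewer than three cells cannot support a rank test and are skipped with a
warning.

## Neurotransmitter classification

A cell is positive for one of the seven fast-transmitter pathway genes
(`VGlut`, `VAChT`, `Gad1`, `Tbh`, `ple`, `SerT`, `Tdc2`) when its
expression exceeds a threshold of 2. Two conventions circulate for which
layer that threshold applies to — z-scaled expression or log-normalised
expression — and they are not equivalent: a gene expressed in a large
fraction of cells has a large mean and SD, so its z-scores saturate lower.
The package defaults to the scaled layer and exposes `layer =
"lognorm"`; the discrepancy is surfaced as a parameter rather than
silently resolved, and the per-cell ground-truth tests run on the
log-normalised layer where recovery is sharper. Cells are partitioned
into single-class, multi-class (≥ 2) and negative; the three fractions
sum to one exactly, and reported percentages are rounded half-up to one
decimal.

## Cluster-defining neuropeptides

"Enriched in a limited number of clusters" is operationalised as: a
significant positive marker (adjusted p < 0.05) in at least 1 and at most
`max_clusters = 4` clusters. No published rule fixes the ceiling; 4 is
the smallest value that accommodates the known many-to-many cases (one
neuropeptide defining several clusters, one cluster carrying several
neuropeptides) and it is configurable and recorded in the output
attributes. TF–neuropeptide correlation defaults to Pearson on the
log-normalised layer, with Spearman available; no correlation method is
published for this analysis, and single-cell coefficients on sparse
counts are descriptive either way — the documentation says so.

## TF combinatorial codes

Per DNA-binding-domain class (zinc finger, helix-turn-helix, homeodomain,
basic domain, unidentified DNA-binding domain, high-mobility group), the
clusters × TFs matrix gets a 1 wherever the TF is a significant positive
marker of the cluster, 0 otherwise; TFs that mark no cluster are dropped.
A cluster's code is *unique* when no other cluster has an identical row —
all members of a duplicated code are non-unique, not $n-1$ of them, the
only reading under which unique-cluster counts and percentages stay
mutually consistent. Two all-zero rows are mutual duplicates. Percentages
are rounded half-up to one decimal (base `round()` is round-half-even,
which would turn 34.15 into 34.1 rather than the conventionally printed
34.2).

Jaccard similarity between cluster codes treats rows as TF sets:
$J = |A \cap B| / |A \cup B|$, with $J \equiv 0$ when both sets are empty
so codeless clusters never dominate the ordering. "Sorted from most to
least similar" is not a complete algorithm specification; the package
uses the leaf order of average-linkage hierarchical clustering on
$1 - J$, processing rows in lexicographic label order so ties break
deterministically, with a greedy nearest-neighbour chain as the
configurable alternative.

## Sex bias

Cells from mixed-sex samples are excluded outright — their sex of origin
is unknowable from the labels. Testing each cluster's female count
against the *global* female fraction of the remaining cells is exactly
the input normalisation required: under the null a cluster samples the
sexed input pool proportionally, whatever the female/male sample sizes.
The test is a two-sided exact binomial per cluster, BH-adjusted, with an
effect-size floor of |log2 odds ratio| ≥ 1 (observed odds carry a 0.5
continuity correction so empty cells don't produce infinities). Both
thresholds are configurable and attached to the report: no published
threshold for "disproportionate" exists, so auditability matters more
than any particular default.

Pseudobulk differential expression sums counts per sample (per sample ×
cluster in the per-cluster scope), converts to log2 CPM, and rank-sum
tests female against male units. A design with a single sample per sex —
including the three-sample female/male/mixed design the generator
defaults to — cannot support a replicate-level test, so the function
falls back to a per-cell rank-sum, warns, and records the fallback in
the output provenance. Note that even two units per side cannot reach
p < 0.05 under a rank-sum test; that is a property of the design, and
the provenance lets readers see which path produced a table.

## Cluster-to-neuron-type mapping

Three procedures, reflecting three kinds of external evidence:

* **Bulk correlation** — Pearson (or Spearman) between each cluster's
  mean log expression and each bulk-profiled cell type's `log1p`
  expression over the shared gene set; each cluster is assigned its
  arg-max cell type, ties broken lexicographically and flagged. Whether
  published versions of this comparison used raw, log or scaled bulk
  values is unstated; log is the default here, and the full coefficient
  matrix is returned so the assignment rule is auditable. The gene set
  defaults to the full intersection, with a highly-variable-gene option.
* **Enhancer genes** — a cluster qualifies for a split-Gal4 driver when
  *every* enhancer gene of the driver has positive scaled average
  expression (> 0, i.e. above the cross-cluster mean, read literally).
  Multiple clusters per driver and drivers per cluster are expected and
  preserved.
* **Marker logic** — boolean predicates such as `toy+ run-`, evaluated
  on detection fractions: positive genes need ≥ 50% of cluster cells
  detected, negative genes ≤ 10%. The fractions are unpublished
  choices, configurable and logged.

# The synthetic-data generator

No machine-readable matrix accompanies the study this design emulates, so
validation rests on a generator with complete ground truth. It draws
negative-binomial counts (mean–dispersion parameterisation, log-normal
library-size factors with σ = 0.3 — a standard overdispersed model for
UMI data) on top of cluster-level means that encode every planted
structure: per-cluster markers raised by `marker_log2fc`; TF genes high
exactly where the planted binary code has a 1; `repo` in glial clusters;
the seven transmitter genes per an assignment whose class frequencies
follow the reported composition of adult central-brain neurons
(cholinergic most abundant at 21%, then glutamatergic 12%, GABAergic 9%,
rare monoaminergic classes, ~12% multi-transmitter, ~40% negative); 49
neuropeptide genes of which 13 are cluster-restricted; `yp1/yp2/yp3`
elevated in female cells and `roX1/roX2` in male cells; transgene counts
only in T2 cells, with per-cell per-transgene Bernoulli dropout (a true
T2 cell can therefore appear triple-negative, modelling imperfect
capture — the true detection sensitivity is unpublished, so the default
rate of 0.9 is a placeholder, not an estimate); and mitochondrial genes
tuned to a per-cell fraction drawn from `mito_fraction_range`. The
default `t2_fraction` of 0.1 matches the ~10% transgene-positive share of
the unsorted experiment. The default sample design is one female, one
male and one mixed sample; cells in the mixed sample carry the observed
label `"mixed"` while their true sex lives only in the ground truth,
mirroring how mixed samples must be excluded from sex analyses.

What the generator does **not** emulate: ambient RNA, doublets,
batch/chemistry effects, read-level structure, and the long-tailed
cluster-size distribution of real atlases (clusters are equal-sized).
Passing the recovery tests therefore demonstrates that the
implementations are correct on data satisfying their assumptions — not
that the thresholds are optimal on real brains.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 20 clusters
× 100 cells (≈ 500 genes), the size at which every planted structure is
comfortably recoverable while a full run of the suite stays fast; the
lineage-arithmetic checks use the full 30,699-cell scale directly, since
they need only a sparse transgene block. Fixed seeds make the stochastic
recovery tests (marker recovery ≥ 90%, exact TF-code recovery, ≥ 90%
bulk mapping, permutation-null calibration within three binomial SEs of
5%) reproducible regression tests rather than flaky assertions.

Other numerical conventions collected in one place: BH adjustment always
runs over the tested set within its scope (per cluster for markers, per
scope for pseudobulk, over clusters for sex bias); zero-variance vectors
yield correlation 0 rather than NA; rank-sum variances of all-tied
vectors yield p = 1; ties in every ranking (top markers, top correlated
TFs, arg-max assignment) break by the stated statistic first and
lexicographic ID last, so outputs are deterministic; percentage rounding
is half-up to one decimal.

# Known limitations

* The Wilcoxon normal approximation is what the field's toolkits use,
  but for clusters of only a handful of cells an exact test would differ;
  clusters under three cells are skipped entirely.
* Sex-bias detection treats cells as independent draws; correlated
  capture within samples would inflate significance, which the
  effect-size floor only partially offsets.
* The cluster-defining-neuropeptide ceiling (4 clusters) and the marker
  logic detection fractions are field-reasonable but unpublished; results
  that depend on them should cite the recorded settings.
* Bulk mapping assumes the bulk profiles and the atlas share enough
  biology for correlation to rank correctly; with < 10 shared genes the
  function refuses to guess.
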