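---
title: "Quantifying oligodendrocyte population topography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oligodendrocyte population topography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molmap)
```

Mature oligodendrocytes (MOLs) are not one cell type: transcriptomics
distinguishes populations (MOL1, MOL2, MOL5/6, alongside OPC/COP precursor
states) that occupy different tissue compartments — MOL2 enriched in spinal
cord white matter, MOL5/6 in gray matter — and respond differently to injury.
`molmap` implements the quantification machinery needed to measure such
claims: decoding targeted in situ sequencing (ISS) reads, assigning them to
segmented cells, calling populations from marker counts, testing regional and
injury effects, and selecting manifold-structured genes for subclustering.
Every stage has a synthetic generator that emulates its input with full
ground truth, so the whole chain is testable end to end.

## ISS decoding

An ISS experiment reads a 4-base barcode over 4 sequencing cycles; each base
reports in one fluorescence channel (A = Cy5, C = Texas Red, G = Cy3,
T = AF488). For a spot's cycle the called base is the channel with the
highest intensity, and its quality is

$$q_c = \frac{\max_k I_{ck}}{\sum_k I_{ck}} \in [1/4,\, 1],$$

1 for an unambiguous one-hot signal, 1/4 for a completely uninformative one.
Choices the upstream protocol leaves open, and how we fixed them:

* **Per-spot quality** is the *minimum* of the per-cycle qualities: one bad
  cycle invalidates a barcode, which is the conservative combination.
* **Threshold** `q_min = 0.5`, the midpoint between random (0.25) and
  perfect (1); both the value and whether thresholding acts per cycle or per
  spot are configurable (`decode_spots(per_cycle = )`), since with the
  minimum combiner the two coincide.
* **Ties** in the argmax go to the lowest channel in the fixed A, C, G, T
  order; an all-zero cycle calls quality 0, which forces `low_quality` at any
  positive threshold.
* **No crosstalk correction** is applied before calling; the decoder sees
  intensities as measured.

Spots whose barcode passes the threshold but is absent from the barcode book
are reported `unexpected`, not dropped silently; `barcode_frequency()`
partitions total counts across assigned genes and these categories.

## Segmentation and spot assignment

Nuclei are segmented with the standard watershed recipe for blob-like
objects: Otsu foreground threshold, Euclidean distance transform, watershed
flooded from its regional maxima with a minimum seed separation
(`min_sep`, set near the expected nucleus radius). Cell territories are then
grown with `expand_labels()`: every background pixel within a Euclidean
radius of a label takes the *nearest* label, exact ties going to the lower
id, and existing labels are never overwritten — so territories are nested in
the radius. The default expansion of 10 px is on the order of one cell body
at the simulated scale and is configurable; decoded spots are assigned to
the territory under their coordinates (0-based, x = column, pixel-center
convention) and a cell's region is the strip containing its nucleus
centroid, matching how regions of interest are drawn over nuclei.

## Cell typing

Two assays, two rule styles, both with *non-exclusive* flags (each
population's percentage is computed independently over the denominator; a
cell may carry two flags):

* **Puncta mode** (RNAscope-style): lineage is the Sox10 immunostain
  boolean; a population is flagged when its marker count reaches the
  molecule cutoff — Ptgds ≥ 12 (MOL5/6), Klk6 ≥ 4 (MOL2), Egr2 ≥ 3 (MOL1),
  Ptprz1 ≥ 7 (OPC/COP). Boundaries are inclusive: count = cutoff flags,
  cutoff − 1 does not.
* **ISS mode**: lineage requires Sox10 *and* Plp1 reads at threshold `t`
  (default 1 read, configurable — the assay's positivity threshold is a
  protocol choice); a MOL population needs in addition both genes of one of
  its marker pairs (MOL2: Anxa5+Klk6 or Anxa5+Hopx; MOL5/6: Ptgds+Car2 or
  Ptgds+Grm3), i.e. triple/quadruple co-expression. OPC/COP deliberately
  bypass the Plp1 gate (Sox10 + Ptprz1 only): progenitors are identified by
  Sox10 co-labeling alone, so the "flags imply lineage" rule holds for MOL
  populations but not for OPC/COP — an intentional asymmetry.

`population_percentages()` supports the denominators used across the
figures: OL lineage cells (default), all nuclei, Aspa+ mature OLs, or
reporter-positive lineage cells for fate-mapping cohorts. Regions with an
empty denominator yield missing values with a warning rather than zeros.

## Composition statistics

Cluster frequencies are column-normalized to percentages per sample;
condition differences are reported in absolute percentage points
(heatmap-ready long format). Regional/age effects are tested with a two-way
ANOVA on per-animal percentages — the experimental unit is the animal, not
the cell — using Type-II sums of squares, appropriate for the unbalanced
cohort sizes typical of such designs (3–9 animals per cell). Pairwise
contrasts use the pooled residual variance,
$t = (\bar y_1 - \bar y_2)/\sqrt{\mathrm{MSE}(1/n_1 + 1/n_2)}$ on the
model's residual df, Sidak-adjusted as $p' = 1 - (1-p)^m$. The comparison
family (hence $m$) is explicit configuration; the default family is the
within-region contrasts between levels of the second factor, matching
per-region age/condition bars.

## Moran's I manifold filter

To subcluster heterogeneous cells, genes are filtered by spatial
autocorrelation *on the expression manifold*: a kNN graph (k = 15, union
symmetrization, row-standardized weights) is built on a 3D embedding, and
each gene's Moran's I

$$I = \frac{N}{S_0}\,
\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}$$

is tested by Monte-Carlo permutation of cell labels (`nperm = 999`), with
the add-one estimator $p = (1 + \#\{I_{perm} \ge I_{obs}\})/(1 + nperm)$ so
p is never exactly zero. Genes at $p \le \alpha$ (default 0.01) survive a
round; rounds iterate (cap 30) until the retained set is stable. The
embedding can be recomputed from the retained genes between rounds via the
`reembed` hook; the default keeps the graph fixed, which makes the retained
sets provably nested and the procedure much easier to validate — the
per-round re-embedding used in exploratory practice is available but
data-dependent. Expression is library-size normalized to $10^4$ per cell and
log1p-transformed before testing. The final gene set drives a Ward-linkage
hierarchical clustering (genes scaled to zero mean/unit variance, Euclidean
distance) cut at a user-chosen number of clusters; the number of clusters is
a judgment call on real data and is therefore a parameter, not a default.

The permutation test is implemented blockwise — each permutation reorders
the whole centered matrix and updates every gene's exceedance count — so
hundreds of genes with a thousand permutations cost seconds. A dense
double-sum implementation of I exists only in the test suite as an
independent oracle; the sparse path must agree with it to 1e-10.

## QC, differential expression and 2D volcanoes

`qc_filter()` keeps cells with detected genes in `[min, max]` and
mitochondrial fraction strictly below the ceiling, with presets
`corpus_callosum` (200–3000 genes, < 5%) and `spinal_cord` (500–7000 genes,
< 10%). The report attributes each removed cell to the *first* criterion it
fails (min genes, max genes, mito), so kept + removed always equals input.

Differential expression within a population is a Wilcoxon rank-sum test per
gene on normalized expression. The implementation enumerates the exact
permutation distribution (midranks under ties) when the combined sample
size is ≤ 10 and otherwise uses the normal approximation with tie and
continuity correction. The approximation's one-sided tail stays within 0.05
of the exact enumeration across all tie-free configurations with 2–4 units
per group; a two-sided p doubles both tails and with them the discrepancy,
which is a convention effect rather than an accuracy loss. Both a per-cell
and a per-sample-average mode are provided because testing cells treats
them as independent replicates while testing per-sample cluster averages
respects the animal as the unit; the default is per-cell, and the choice
materially affects p-values, so it is surfaced rather than hidden.

Log fold changes are `log2((mean_A + 1)/(mean_B + 1))` on the normalized
scale; the pseudocount of 1 stabilizes low-expression genes. FDR control is
Benjamini–Hochberg, and significance is called at q < 0.01. A 2D volcano
places one comparison's LFC on each axis and annotates each gene with the
*lower* of its two raw p-values; genes absent from either comparison are
excluded and listed, never silently dropped. Gene sets are embedded as the
mean member LFC per axis. Cluster markers are found one-vs-rest (Wilcoxon,
LFC ≥ 0.25, q < 0.01) and ranked by the z score of the cluster mean against
the gene's global mean and SD, reporting the top 20.

## The synthetic-data generators

The generators define the conditions under which the machinery is
validated; their defaults are fixed study conditions, not tuning knobs.

* **Tissue**: disk nuclei (unambiguous segmentation truth) packed with a
  hard minimum center distance (2·max radius + margin, so expanded
  territories cannot collide), in axis-aligned region strips (trivial
  point-in-region tests). Each region has a lineage fraction (default WM
  0.75, GM 0.80; the rest are Sox10-negative "Other" nuclei) and a
  population mix *among lineage cells* (WM: MOL2 0.30, MOL5/6 0.25, MOL1
  0.15, OPC/COP 0.30; GM: MOL2 0.10, MOL5/6 0.60, MOL1 0.10, OPC/COP 0.20).
  Stating the mix on the lineage denominator makes the planted values
  directly the estimand of the composition table.
* **ISS spots**: per-cell Poisson counts at population-specific means
  (MOL5/6 express Ptgds at 12 spots/cell; gates Sox10/Plp1 at 8/10),
  uniform placement in the nucleus disk, one-hot intensities plus a
  crosstalk fraction on wrong channels and additive truncated-Gaussian
  noise — the simplest model that degrades the quality score smoothly.
  Background spots draw barcodes uniformly from the full 4^4 space,
  emulating off-target products that mostly decode as "unexpected".
* **Puncta**: negative binomial with size 20 — puncta are discrete molecule
  counts, near-Poisson within a homogeneous population with mild cell-size
  overdispersion — with means at 3× the cutoff on-target and cutoff/3
  off-target. With those separations each population's cells carry their
  own flag ≥ 95% of the time; note that low cutoffs (Egr2's 3) make *some*
  off-target false flags unavoidable at mean cutoff/3, which is why
  recovery is stated as per-population recall.
* **Count matrices**: negative binomial (size 10; within-cluster UMI noise
  is near-Poisson) around gamma-distributed baseline means, with planted
  cluster markers, condition-DE genes (baseline floored at 2 counts/cell —
  effects are planted in detectably expressed genes), mito and library-size
  outliers, a cluster-separated 3D Gaussian-blob embedding, and spatially
  autocorrelated genes. Spatial genes follow the bounded gradient
  $\mu = \mu_0 (1 + 0.9\tanh(s \cdot u_1))$ of the first embedding
  coordinate with alternating signs across genes: the sign alternation
  keeps per-cell totals flat along the gradient, since a one-sided profile
  would leak spatial structure into *every* gene through library-size
  normalization (an artifact of the generator, which the permutation test
  then rightly detects). The mitochondrial fraction is simulated directly
  as metadata because the QC filter consumes only the fraction.

What the generators deliberately do not emulate — optics and PSFs, cycle
misregistration, segmentation errors from irregular nuclei, doublets,
transcriptome-wide correlation structure, batch effects — bounds what
passing tests show: they validate the *quantification logic* under its own
stated models, not robustness to every failure mode of real tissue.

## Problem sizes and numerical choices

The shipped tests exercise: decoding on ~3,000 spots over a 12-gene book;
segmentation on 50–200 nuclei in fields up to 1200²; Moran oracle checks on
100 random graphs of up to 200 cells against the dense formula (agreement
to 1e-10); filter recovery with 20 planted spatial genes among 200 at
α = 0.01 and 999 permutations on 400 cells; DE recovery at |LFC| = 1 with
~100 cells per group; ANOVA null calibration over 2,000 balanced 2×2
designs; and a four-animal end-to-end composition experiment at 180 cells
per animal. These sizes make every statistical check pass or fail on
3-standard-error margins while the whole suite runs in about a minute.

Degenerate inputs are contracts, not surprises: constant genes are an error
for a single Moran test, silently non-spatial (p = 1) in the matrix path,
and variance-zero columns are zeroed before clustering; zero-total cells
stay zero in normalization with a warning; zero-denominator regions and
zero-total composition columns go missing with warnings; single-unit exact
Wilcoxon returns p = 1 with a warning.

## Known limitations

Segmentation assumes blob-like nuclei; heavily overlapping or irregular
nuclei need a different segmenter (territories and assignment accept any
label image, so the stage is replaceable). The kNN graph is built from a
dense distance matrix, fine to a few thousand cells. The iterative filter's
stopping behavior with per-round re-embedding depends on the embedding
method supplied by the hook and is not guaranteed to converge. Computing
the 3D embedding itself is out of scope: it is consumed as input.
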