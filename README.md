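# molmap

Spatial mapping and injury response of mature oligodendrocyte (MOL)
populations.

Mature oligodendrocytes are transcriptionally heterogeneous: populations
such as MOL2 and MOL5/6 occupy different tissue compartments (MOL2 enriched
in spinal cord white matter, MOL5/6 in gray matter and corpus callosum) and
shift differently with age and after injury. Measuring that topography from
imaging and single-cell data takes a chain of bespoke quantification steps,
and this package implements that chain as tested, reusable R functions for
anyone quantifying targeted in situ sequencing (ISS), RNAscope-style puncta
counts, or single-cell RNA-seq of the oligodendrocyte lineage:

* **ISS decoding** — per-cycle base calling with the quality score
  `q = max signal / sum of signals`, per-spot thresholding (Q = min over
  cycles), gene lookup against a barcode book, and barcode frequency
  accounting (`call_bases`, `decode_spots`, `barcode_frequency`).
* **Segmentation and assignment** — Otsu + distance-transform watershed for
  nuclei, nearest-label territory expansion with an exact Euclidean radius
  cap, and spot-to-cell assignment into a cell-by-gene matrix
  (`segment_nuclei`, `expand_labels`, `assign_spots`).
* **Cell typing** — molecule-cutoff calling for puncta tables (Ptgds ≥ 12,
  Klk6 ≥ 4, Egr2 ≥ 3, Ptprz1 ≥ 7 over Sox10+ cells) and co-expression
  gating for ISS counts (Sox10+Plp1 lineage gate plus marker pairs;
  OPC/COP by Sox10 co-labeling), with per-region percentages over
  configurable denominators (`classify_puncta`, `classify_iss`,
  `population_percentages`).
* **Composition statistics** — column normalization to percentages,
  condition-change matrices in percentage points, and two-way ANOVA
  (Type-II SS) with Sidak-corrected pairwise contrasts
  `p' = 1 − (1 − p)^m` on per-animal observations (`column_normalize`,
  `composition_change`, `two_way_anova_sidak`).
* **Moran's I manifold filter** — spatial autocorrelation
  `I = (N/S0) Σ w_ij (x_i − x̄)(x_j − x̄) / Σ (x_i − x̄)²` of gene
  expression over a kNN graph on a 3D embedding, Monte-Carlo permutation
  significance, iterative spatial filtering, and Ward hierarchical
  subclustering on the retained genes (`knn_graph`, `morans_i`,
  `mc_pvalue`, `iterative_spatial_filter`, `hierarchical_subcluster`).
* **QC / DE / 2D volcano** — gene-count and mitochondrial-fraction
  filtering with corpus callosum (200–3000, <5%) and spinal cord
  (500–7000, <10%) presets, Wilcoxon rank-sum DE (exact enumeration at
  small n, tie-corrected normal approximation otherwise), BH-FDR, 2D
  volcano tables taking the lowest p of two comparisons, pathway embedding
  by mean member LFC, and one-vs-rest marker finding with the 0.25
  fold-change cutoff and top-20 z-score ranking (`qc_filter`,
  `wilcoxon_de`, `bh_fdr`, `volcano2d`, `pathway_embed`, `find_markers`).
* **Synthetic data** — generators for ground-truthed tissues, nuclei
  images, ISS spot tables, puncta tables and count matrices with planted
  cluster/DE/spatial structure (`sim_config`, `gen_tissue`,
  `render_nuclei_image`, `gen_iss_spots`, `gen_puncta_counts`,
  `gen_expression_matrix`).

## Worked example

Simulate a two-region tissue whose white matter plants MOL2 at 30% of
lineage cells and whose gray matter plants MOL5/6 at 60%, then run the full
chain — render, simulate spots, decode, segment, expand, assign, type,
compose:

```r
library(molmap)
cfg <- sim_config(n_cells = 150, field = c(1024L, 1024L))
res <- run_iss_experiment(cfg, seed = 11, expansion = 4)
table(res$decoded$status)
#> assigned
#>     4135
subset(res$composition, population %in% c("MOL2", "MOL5/6"))
#>  region population n_population n_denominator percentage
#>      WM       MOL2           15            63   23.80952
#>      WM     MOL5/6           14            63   22.22222
#>      GM       MOL2            7            56   12.50000
#>      GM     MOL5/6           30            56   53.57143
```

All 4,135 simulated spots decode as `assigned` at the default noise level,
and the recovered composition tracks the planted mix (WM MOL2 23.8% vs 30%
planted, GM MOL5/6 53.6% vs 60% planted) within binomial sampling error at
~60 lineage cells per region. Repeating the experiment over several
simulated animals and feeding the per-animal percentages to
`two_way_anova_sidak(comp, "percentage", "population", "region")` flags the
MOL2 white-vs-gray contrast at a Sidak-adjusted p far below 0.05.

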