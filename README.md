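# ltfscore

Simulation and scoring for ex vivo **live tumor fragment (LTF)** cytokine
assays. Tumor specimens are cut into small viable fragments, cultured in
multi-well plates, and their response to immune checkpoint inhibitors
(ICIs) is read out as induced cytokine secretion into the conditioned
media. `ltfscore` implements the computational core of such a platform for
analysts and platform engineers:

- **Heterogeneity simulation** — partition a marker-labeled 2D cell map
  (e.g. CD3+ centroids from a stained section) into slices or cuboid
  fragments, simulate randomized pooling into wells, and quantify the
  well-to-well coefficient of variation of marker counts:
  CV% = 100·SD/mean of pooled counts, with the Poisson closed form
  CV ≈ 100/√E[pool count] as the homogeneous-tissue reference.
- **Assay handling** — long-format multiplex cytokine tables with
  limit-of-quantitation censoring (values above the ULOQ are clamped and
  flagged; values below the LLOQ are retained but flagged; excluded
  analytes dropped), %-quantifiable QC, replicate CVs, CCK8 viability
  rates and viable-voxel fractions.
- **Cross-well scoring** — per specimen × analyte deltas Δ = mean(ICI) −
  mean(IgG) at the endpoint time, standardized per analyte with a
  MAD-trimmed modified Z-score
  `z = 0.6745 (x − med*) / MAD*` (trim window ±2 MAD, scores saturated to
  [−10, 10]), upregulation calls at z ≥ 5, Ward clustering of the Z
  matrix, and biomarker enrichment (per-analyte Fisher exact tests plus a
  Mann–Whitney rank test on per-specimen upregulated-analyte counts).
- **Sequential scoring** — for same-well control-then-treatment designs:
  least-squares slopes of cumulative concentration in the control
  (~4–20 h) and treatment (~20–48 h) phases,
  FC = slope(ICI) / max(slope(IgG), floor), the maximum FC across
  replicate wells, and classification as increase (> 1.5), no change
  (0.5–1.5) or decrease (< 0.5).
- **Synthetic cohorts** — a generator with known ground truth (baseline
  rates, well-composition multipliers, effect multipliers, responder
  flags) so every pipeline stage is testable without patient data.

See the methods vignette (`vignettes/ltfscore-methods.Rmd`) for the
models, parameter choices and limitations.

## Worked example

Quantify how fragmentation geometry controls sampling noise on a
clustered section, then score a small synthetic cohort sequentially:

```r
library(ltfscore)

map <- generate_cell_map(map_config(seed = 1))  # 6 x 6 mm, ~5000 CD3+ cells
compare_designs(map,
  list(fragmentation_scheme("slice", 300),
       fragmentation_scheme("cuboid", 300),
       fragmentation_scheme("cuboid", 100)),
  pool_sizes = 2, n_pools = 300, seed = 1, n_perm = 199)
#>       scheme   mode size_um pool_size pooled_area_mm2 n_fragments mean_count cv_percent p_vs_slice
#> 1  slice_300  slice     300         2             3.6          20        514      19.04         NA
#> 2 cuboid_300 cuboid     300        40             3.6         400        511      14.70      0.005
#> 3 cuboid_100 cuboid     100       360             3.6        3600        500       7.77      0.005
```

At the same pooled tissue area (3.6 mm² per well), pooling many small
randomized fragments suppresses the well-to-well CV of T-cell content from
19% (two whole slices) to 15% (300 µm cuboids) to 8% (100 µm cuboids);
the permutation test confirms the dispersion difference from slices
(p = 0.005). `fragment_geometry(300, 200)` gives the corresponding tissue
arithmetic: 0.09 mm² face area, 0.027 mm³ per fragment, 5.4 mm³ for a
200-fragment well.

```r
cfg <- cohort_config(n_specimens = 6, seed = 8)
co  <- generate_cohort(cfg)             # specimens S001-S003 are responders
res <- score_sequential(co$measurements, cfg$panel)
dplyr::filter(res$summary, analyte %in% c("IFN-gamma", "CXCL10", "IL-1Ra"))
#>    specimen_id analyte   max_fc class
#>  1 S001        CXCL10    6.480  increase
#>  2 S001        IFN-gamma 3.491  increase
#>  3 S001        IL-1Ra    1.261  no_change
#>  4 S002        CXCL10    3.947  increase
#>  5 S002        IFN-gamma 2.937  increase
#>  ...
#> 13 S005        CXCL10    1.150  no_change
#> 14 S005        IFN-gamma 1.262  no_change
#> 15 S005        IL-1Ra    1.402  no_change
```

The three generated responders show maximum slope fold changes of 2.9–6.5
for the T-cell response cytokines IFN-γ and CXCL10 ("increase"), while
the constitutive IL-1Ra stays mostly within the 0.5–1.5 "no change" band
and the non-responders (S004–S006) cluster near FC ≈ 1 — with occasional
boundary misclassifications at FC just above 1.5, which is what the
replicate-well maximum is designed to surface.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "ltfscore", package = "ltfscore"))')
Rscript "$cli" simulate-cohort --out-dir cohort --n-specimens 8 --seed 7
Rscript "$cli" score-sequential --measurements cohort/measurements.csv \
        --panel cohort/panel.csv --out scored
```

Subcommands: `simulate-map`, `simulate-cohort`, `heterogeneity`, `qc`,
`score-crosswell`, `score-sequential`. Every run writes a `manifest.json`
recording parameters, seed, package version and input digests.

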