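---
title: "Models and methods behind ltfscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ltfscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfscore)
```

## The problem

Ex vivo live-tumor-fragment (LTF) platforms cut a tumor specimen into small
viable fragments, culture them in multi-well plates, and read out response
to immune checkpoint inhibitors (ICIs) as induced cytokine secretion into
the conditioned media. Two statistical obstacles dominate the analysis:

1. **Tissue-composition sampling noise.** Immune cells are spatially
   clustered, so the cell content of a well depends on which pieces of
   tissue landed in it. Comparing an ICI-treated well against a control
   well confounds treatment effect with composition differences.
2. **Censored, wide-ranging concentrations.** Multiplex panels quantify
   each analyte only between a lower and an upper limit of quantitation
   (LLOQ/ULOQ), and baseline secretion differs by orders of magnitude
   across cytokines and specimens.

`ltfscore` implements the computational core of such a platform: a
fragmentation/pooling simulation that quantifies obstacle 1, and two
scoring procedures — cross-well and sequential same-well — that address
obstacle 2 under the censoring rules of the assay, together with a
synthetic-data generator that makes every stage testable end to end.

## Fragmentation and randomized pooling

A tissue section is modeled as a 2D point pattern of marker-positive cells
(e.g. CD3+ T cells) on a rectangular domain. `generate_cell_map()` draws
the pattern as a homogeneous Poisson background superposed with a Thomas
cluster process: cluster centers are Poisson with intensity
$\kappa$ (parents/mm$^2$), each center receives a
$\mathrm{Poisson}(\mu)$ number of offspring displaced isotropically with
Gaussian SD $\sigma$. Parents are drawn on the domain extended by
$4\sigma$ so clusters centred just outside the section still contribute
(edge correction). The defaults (6 × 6 mm domain, background 30
cells/mm², $\kappa = 2$/mm², $\mu = 60$, $\sigma = 150$ µm) describe a
strongly clustered infiltrate whose cluster extent (~2–3 cluster SDs,
i.e. 300–450 µm) exceeds a 300 µm fragment; this is the regime in which
fragment geometry matters, and it was fixed as the package's reference
clustered-tissue condition after a design study (below).

`partition_map()` assigns cells to fragments by half-open intervals
$[\mathrm{lo}, \mathrm{lo} + e)$ — no cell is ever counted twice, and
boundary behavior is exactly testable. Partial fragments at the domain
boundary are discarded so every fragment represents the same tissue
volume. Slices are full-height strips of the stated thickness; cuboids
are square grid cells.

`simulate_pooling()` mimics dispensing: each in-silico well receives a
uniform random sample of `pool_size` fragments drawn without replacement,
independently re-randomized across wells, and the well-to-well coefficient
of variation of pooled marker counts
$\mathrm{CV} = 100\,\mathrm{SD}/\mathrm{mean}$ measures composition noise.
Two closed forms anchor the simulation in tests:

* on homogeneous (Poisson) tissue the pooled count is Poisson, so
  $\mathrm{CV} \approx 100/\sqrt{E[\text{pool count}]}$ regardless of
  fragment geometry (with a finite-population factor $\sqrt{1 - n/N}$
  because pools are drawn without replacement from $N$ fragments);
* on clustered tissue, variance per unit area grows with fragment size up
  to the cluster scale, so at **matched pooled tissue area** the pool CV
  is ordered slice > 300 µm cuboid > 100 µm cuboid.

`compare_designs()` tabulates CVs for several schemes at matched pooled
area (pool sizes are rescaled by fragment footprint so each design pools
the same amount of tissue) and compares dispersions between the slice
scheme and each cuboid scheme with a two-sample permutation test on
mean-normalized pool counts. A permutation test was chosen because pool
counts are neither normal nor independent of their mean; no distributional
assumption is needed.

`fragment_geometry()` records the cutting arithmetic: a 300 µm edge gives
a 0.09 mm² face and 0.027 mm³ volume; 200 fragments are 5.4 mm³ of
tissue — about the yield of one 18-gauge core needle biopsy, which is why
cross-well replication is infeasible for biopsies and a sequential
strategy is needed.

## Measurement model and censoring

Measurements are long-format records
(`specimen_id, well_id, treatment, analyte, time_h, concentration_pg_ml,
censor`). Concentrations are cumulative: media are not refreshed, so the
expected time course is non-decreasing and its slope is a production rate
(pg/mL/h).

`apply_loq()` implements the censoring convention of the assay:
concentrations above the ULOQ are set to the ULOQ and flagged
`clamped_uloq`; concentrations below the LLOQ are **retained unchanged**
but flagged `below_lloq`, so each downstream analysis can decide whether
to drop them; panel-excluded analytes are removed entirely. The operation
is idempotent. The QC denominator of `pct_above_lloq()` is the panel size
after exclusions (30 analytes for the default 36-analyte panel with six
exclusions). Replicate variability (`replicate_cv()`) uses the sample
(n−1) SD on raw concentrations — replicate counts are small (3–5 wells)
and the platform reports CVs of concentrations, not of log
concentrations; computing CVs on the raw scale is therefore the
documented choice, with the caveat that log-scale CVs would differ for
strongly skewed analytes.

## Cross-well scoring (resections)

With enough tissue, pooled fragments are dispensed into dedicated ICI and
IgG control wells. For each specimen × analyte, `treatment_delta()` takes
the difference of replicate-well means of the cumulative concentration at
the endpoint time. The endpoint (terminal sampling time by default) is
used rather than a sum over sampling times because the media accumulate:
the terminal value *is* the cumulative readout.

Deltas are standardized per analyte across specimens with a MAD-trimmed
modified Z-score, `mad_trimmed_modified_z()`:

1. $\mathrm{med} = \mathrm{median}(x)$,
   $\mathrm{MAD} = \mathrm{median}(|x - \mathrm{med}|)$ (raw MAD, no
   consistency constant);
2. trim to $\{x_i : |x_i - \mathrm{med}| \le 2\,\mathrm{MAD}\}$
   (inclusive window);
3. recompute $\mathrm{med}^*$ and $\mathrm{MAD}^*$ on the trimmed set;
4. score **all** samples, including trimmed-out ones (they must appear in
   the heatmap): $z_i = 0.6745\,(x_i - \mathrm{med}^*)/\mathrm{MAD}^*$;
5. saturate to $[-10, 10]$.

If $\mathrm{MAD}^* = 0$ the scale falls back to $1.2533\times$ the mean
absolute deviation of the trimmed set (the standard modified-Z fallback);
if that is also zero all scores are 0. Normalization is per analyte
across specimens — columns of a specimen-by-analyte heatmap are then
comparable — because cross-analyte concentration scales differ by orders
of magnitude; per-specimen normalization would let one hot specimen mask
its own responses. Upregulation is called at $z \ge 5$ (inclusive), a
deliberately conservative criterion given saturation at 10.

`cluster_z()` applies Ward-linkage agglomerative clustering (Euclidean
distance, `hclust(method = "ward.D2")`) independently to specimens and
analytes of the saturated matrix; missing cells are zero-imputed for
clustering only (zero is the neutral point of the saturated scale) and
counted. `enrichment()` links calls to biomarker status: per analyte a
2×2 Fisher exact test (reported with the sample cross-product odds
ratio), and across analytes a Mann–Whitney rank test on per-specimen
upregulated-analyte counts (normal approximation with tie-corrected
variance and continuity correction; a fully tied comparison is reported
as $p = 1$, "no evidence", rather than NA).

## Sequential scoring (core needle biopsies)

Biopsies cannot support replicate cross-well arms, so control and
treatment are applied sequentially to the *same* well: IgG from the start,
ICI from the switch time (~20 h), with media sampled at ~4, ~20 and ~48 h.
`phase_slopes()` fits least-squares slopes of cumulative concentration on
the **actual** sample timestamps within the control window
$[t_\mathrm{start}, t_\mathrm{switch}]$ and the treatment window
$[t_\mathrm{switch}, t_\mathrm{end}]$; the switch-time sample belongs to
both windows (with three samples this is the only way both windows hold
two points). The response statistic is the slope fold change
$\mathrm{FC} = s_\mathrm{ICI}/\max(s_\mathrm{IgG}, \mathrm{floor})$, with
the denominator floored at LLOQ/(control-window duration) — the smallest
production rate distinguishable from no accumulation — to keep FCs
bounded and physically interpretable; floored FCs are flagged, as are
wells with any ULOQ-clamped sample in a window. Negative treatment
slopes are allowed (FC below 0.5 is a meaningful "decrease"); negative
control slopes are floored like zero. Per specimen × analyte the
**maximum** FC across replicate wells is reported (a positive response in
any replicate suggests sensitivity), and FCs are classified as increase
(> 1.5), no change (0.5–1.5, boundaries inclusive), or decrease (< 0.5).
`concordance()` compares class labels between designs as a simple percent
agreement over shared specimen × analyte keys.

## The synthetic cohort generator

`generate_cohort()` draws cohorts from the model the scoring procedures
assume. For specimen $s$, well $j$, analyte $a$ at time $t$:

$$C(t) = r\,w\,\min(t, t_s) + m\,r\,w\,\max(t - t_s, 0), \qquad
  C_\mathrm{obs}(t) = C(t)\,\varepsilon_t,$$

with $r$ the specimen × analyte baseline rate (lognormal across the
cohort), $w$ a mean-1 lognormal well-composition multiplier drawn once
per well and shared across analytes (tissue composition, not assay noise,
drives cross-analyte correlation within a well), $m$ the effect
multiplier applied after the switch $t_s$ ($m > 1$ only in responder
specimens, responsive analytes and non-control arms), and
$\varepsilon_t$ mean-1 lognormal noise per sample. Multiplicative
lognormal noise is the natural choice for strictly positive
concentrations whose variability is reported as CVs. The composition CV
shrinks as $\mathrm{CV}_1/\sqrt{n_\mathrm{frag}}$ with the number of
pooled fragments — the pooling law the heterogeneity module quantifies
spatially. Biomarker status affects only the responder probability, not
baseline rates.

Defaults, chosen once as realistic study conditions and then frozen:
40 specimens; 10 analytes of which 5 (IFN-γ, CXCL10, TNF-α, IL-2, CXCL9)
are treatment-responsive while IL-1Ra and the rest are not; biomarker
prevalence 0.4 with responder probabilities 0.8 / 0.2 given status;
baseline rates lognormal with median 5 pg/mL/h and log-SD 0.5 (≈ 53 % CV
across specimens, a typical cross-patient spread for constitutive
cytokine secretion); effect multipliers uniform in 3–6; 200 fragments per
well with a single-fragment composition CV of 0.5; measurement noise CV
0.1; samples at 4/20/48 h with the switch at 20 h; three replicate wells
per arm.

**Seed discipline.** One master seed; each (specimen, well) pair gets an
independent substream via a fixed affine-hash splitting rule, so
enlarging a cohort never changes specimens already generated.

A design study (run before the validation suite was written) established
that these conditions support the package's quantitative claims: the
MAD-trim scorer has a breakdown point near 50 % and the default responder
mix (0.4·0.8 + 0.6·0.2 = 44 % responders) deliberately sits close to it,
which makes the cross-well power property a demanding test of the whole
pipeline rather than a formality; with log-SD 0.5 the rank test on
upregulated counts rejects in very close to 80 % of replicate cohorts.
The non-rejections are themselves informative: they concentrate in
cohorts where the binomial responder draw pushes responders past half the
cohort, at which point the trimmed MAD is computed over a
responder-dominated sample, scores deflate and upregulation calls
collapse — the breakdown behavior any median/MAD-based scorer must show
once "outliers" become the majority. The
same study fixed the clustered-map parameters: with cluster SD 75 µm
(clusters smaller than a fragment) slice and cuboid designs differ only
marginally, while at SD 150 µm the ordering slice > 300 µm > 100 µm is
essentially deterministic.

## Numerical choices and degenerate inputs

* Half-open fragment intervals; ties in `hclust` and `which.max` broken
  by input index; partitioning is invariant to cell order.
* CV of pool totals with mean 0 is reported as a flagged missing value,
  never infinity; replicate CV groups with fewer than two usable wells
  likewise.
* The modified-Z fallback chain (MAD* → 1.2533·MeanAD → all-zero) makes
  constant delta vectors score 0 rather than error.
* `apply_loq()` is idempotent: a value sitting exactly at the ULOQ keeps
  its clamp flag on re-application.
* Validation-suite problem sizes: 1000 random vectors for the modified-Z
  oracle; 12 × 12 mm Poisson maps with 1000 pools per design point (the
  quoted Monte-Carlo SE combines the pool-resampling and
  realized-population terms, and the without-replacement finite-population
  factor is used where the sampling fraction is non-negligible); 40
  seeded clustered-map replicates; 500–1000 scored synthetic wells for
  recovery and null rates; 100 replicate cohorts for the enrichment power
  property; exhaustive enumeration of all 2×2 tables with total ≤ 20 for
  the Fisher cross-check.

## What passing tests do and do not show

The generator emulates the *statistical* structure of the assay:
clustered spatial distributions, per-specimen baselines, composition
heterogeneity that shrinks with pooling, a post-switch effect multiplier,
multiplicative noise, LOQ censoring. It does not emulate spatial
correlation between composition and responsiveness, drug wash-in kinetics
at the phase switch, secretion saturation or consumption, non-lognormal
assay error, plate effects, or necrotic/tumor-free specimens. Passing
tests therefore demonstrate that the pipelines recover known truth under
the stated model, not that the model captures every failure mode of real
tissue. Kit-specific LLOQ/ULOQ values are user inputs; the defaults are
nominal. Clinical-cohort-scale results (clustering of dozens of
resections, patient-specific fold changes) require patient data that are
not publicly deposited; the validation suite and the acceptance script
instead recompute the platform's analytic quantities from synthetic
cohorts with known ground truth.
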