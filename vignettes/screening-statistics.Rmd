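---
title: "Multi-parameter plate-screen statistics: per-well summarization, B-scores and MAD-band hit calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter plate-screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The problem

High-content screens image live cells in multiwell plates and extract
several quantitative readouts per well: here, reporter fluorescence for
*insulin* and *pdx1* promoter activity (GFP and RFP channels), Hoechst
nuclear-stain intensity (condensed, intense staining marks apoptotic
nuclei), and the number of segmented cells. Two features of such data
dominate the statistics:

* **Within-well heterogeneity.** A well contains hundreds to thousands of
  cells with strongly right-skewed fluorescence. Thousands of per-cell
  measurements must be collapsed to one value per well without letting a
  few extreme cells drive it.
* **Plate-geometry bias.** Perimeter rows and columns systematically read
  low (evaporation, thermal gradients, edge optics). Left uncorrected,
  edge wells masquerade as hits or mask real ones.

`hcscreen` implements the full statistical path from per-cell tables to
hit calls: robust per-well summarization, per-plate B-score
normalization by two-way median polish, replicate aggregation,
cytotoxicity exclusion, hit calling against a median ± 2·MAD band, and
Kruskal–Wallis row/column diagnostics — plus a seeded synthetic-screen
generator with ground truth, used to validate the whole pipeline.

## Per-well summarization

For each well and channel the package reports the **median** per-cell
average intensity as the headline value and the **99th quantile** as an
auxiliary: the median ignores outlying cells, while the upper quantile
deliberately follows them, which matters when only a small subpopulation
responds. Quantiles interpolate linearly between order statistics at
position $1 + (n-1)p$ (`stats::quantile` type 7); the convention is a
configurable argument (`quantileP`) because "99th quantile" alone does
not pin one down. The per-cell *average* intensity (not the total) feeds
the screen because promoter activity is a per-cell property; totals are
retained in the table. The median of the per-cell intensity variances is
kept as a further auxiliary but unused by default hit calling. Wells with
no cells are flagged invalid (`no_cells`); an optional `minCells` floor
can flag unstable low-count wells, off by default.

## The B-score

For one plate and one parameter, arrange the well values on the
$r \times c$ grid and fit the additive model

$$y_{ij} = \mu + R_i + C_j + \varepsilon_{ij}$$

by **Tukey's two-way median polish**: alternately subtract row medians
and column medians (rows first), accumulating them into row effects,
column effects, and — by folding in the median of each just-updated
effect vector — the overall term. Because medians are used, a minority
of extreme wells (true hits, toxic extracts) barely moves the estimated
row/column effects. Medians are taken over non-missing wells only, which
is how excluded wells (DMSO controls, imaging artifacts, empty wells)
are accommodated: they are explicit `NA`s, never zeros.

The residual $r_{ij} = y_{ij} - \hat\mu - \hat R_i - \hat C_j$ is scaled
by the plate's robust dispersion:

$$B_{ij} = \frac{r_{ij}}{1.4826 \cdot \mathrm{median}\,|r_{ij}|}$$

The constant 1.4826 makes the scaled MAD estimate the standard deviation
under normality; `madConstant = 1` gives the raw-MAD convention. By
construction $\mathrm{median}\,|B_{ij}| = 1/1.4826 \approx 0.6745$ on
every non-degenerate plate — a useful internal check. B-scores are
invariant to shifting or positively rescaling the plate, so they are
comparable across plates, replicates and parameters.

### Numerical choices

* **Sweep order and bookkeeping.** Rows are swept before columns; the
  median of the updated effects is folded into the overall term after
  each sweep. The residuals — the only quantity used downstream — depend
  only on the sweep order, not on the fold-in bookkeeping.
* **Convergence.** Iteration stops when the summed absolute residual
  change over a full row+column sweep pair falls below
  `tol * (1 + sum(|values|))` (default `tol = 1e-6`), or after `maxIter
  = 100` sweep pairs with `converged = FALSE` rather than an error. The
  polish typically contracts geometrically (ratio ~0.75 on noisy
  plates), so the default tolerance is reached in tens of sweeps. Note
  that `stats::medpolish` stops on the change of $\sum|r_{ij}|$, a
  weaker criterion that can halt while individual cells still move; the
  two agree closely but not to machine precision.
* **Degenerate plates.** If the residuals are numerically zero (an
  exactly additive plate), there is no dispersion to scale by;
  `bscorePlate` raises an error naming the plate. Noiseless fixtures can
  opt into `onDegenerate = "zero"` for all-zero B-scores. The threshold
  is relative (`1e-12` of the plate's median magnitude), so rescaling a
  plate does not change the verdict.
* **Unusable lines.** A row or column with no usable wells has no
  median; that is an error naming the line, not a silent skip. The
  synthetic screen's control layout deliberately alternates DMSO wells
  between columns 1 and 12 so no plate line is ever fully excluded.

### What the B-score cannot do

The additive model has no interaction term: a synergistic row-by-column
effect is split between the marginal effects and the residual, which can
produce both false positives and false negatives. Replicate screens are
the practical mitigation. Relatedly, if many affected wells happen to
share one row or column, the polish partially absorbs their effect into
that line's estimate; randomizing extract positions across replicates
(which the generator does, and real screens should) makes this averaging
out.

Rank preservation: subtracting additive estimates and dividing by a
positive scalar preserves the ranking of the true effects *exactly* in
the noiseless limit when the polish recovers the bias exactly — for
instance under pure row bias with a dense effect grid whose row and
column medians vanish, or under perimeter bias with sparse hits, at most
one per plate line. With both row and column bias plus dense effects,
medians do not separate the terms exactly and preservation is only
approximate; on noisy plates it is statistical, not exact. The tests
assert the exact cases and the pipeline relies on nothing stronger.

## Replicate aggregation and hit calling

Per extract and parameter, the replicate B-scores are averaged:
`mean_bscore` with `sem = sd/√n` (sample standard deviation, $n-1$
denominator). Extracts seen in one replicate have no SEM and are never
called. An extract occupying several wells within one replicate is an
error unless `pool = "mean"` is requested explicitly.

**Cytotoxicity exclusion** precedes hit calling: extracts whose mean
cell-count B-score is ≤ −2 *and* whose mean Hoechst B-score is ≥ +2
(conjunctive by default; `either`, `cell_count_only` and a rank-based
mode are available) are set aside. Dead wells have uninterpretable
reporter readouts and would widen the hit band.

The **hit band** for a parameter is computed from the post-exclusion
extract means: center = median, halfwidth = $k \cdot 1.4826 \cdot
\mathrm{MAD}$ with $k = 2$. An extract is a **hit** when its whole
mean ± SEM interval lies strictly outside the band; touching the line is
not a hit (a conservative reading of non-overlap), and the side gives
the direction. Decisions are monotone: moving the mean further out at
fixed SEM, or shrinking the SEM at fixed mean, never converts a hit into
a non-hit.

## Bias diagnostics

`biasReport` runs Kruskal–Wallis tests of well values grouped by plate
row and by column, before normalization (`raw`) and after (`bscore`).
The tie-corrected H statistic is referred to $\chi^2_{g-1}$
(`stats::kruskal.test`); with 8–12 wells per group times many plates the
chi-square approximation is adequate, so no permutation p-values are
computed, and ties are always corrected. The pooled-across-plates mode
is the default "overall" view; per-plate mode diagnoses individual
plates, where note that control wells parked on perimeter columns halve
those groups and weaken single-plate column tests. `prototypicalPlate`
pools many plates into per-row/per-column box-plot statistics (quartiles
use the same type-7 convention as the summaries), the standard way to
visualize a perimeter depression. `screenConcordance` reports the
squared Pearson correlation of extract means between two screens.

## The synthetic screen generator

No raw screen data ships with the package; `syntheticConfig` +
`generateWellLevel` / `generateCellLevel` produce screens with known
ground truth, and the test suite and acceptance script run the pipeline
against them. The generative model is deliberately the additive model
the B-score assumes, so that method error is attributable:

$$y = \mu_p + R_i + C_j + \theta \sigma_p + N(0, \sigma_p^2)$$

The defaults are the study conditions the generator emulates:

* 1319 extracts on 96-well plates; 8 DMSO controls per plate (one per
  row, alternating columns 1 and 12); 88 sample wells per plate, hence
  15 plates; 5 replicate screens. Extract-to-well assignment is
  re-randomized per replicate (a fixed permutation derived from the
  seed); each replicate's physical plates carry unique ids, as barcoded
  library plates do.
* Perimeter depression of 2 within-plate SDs on the outer rows and
  columns (corners twice), the magnitude at which raw-data diagnostics
  reject essentially always. A multiplicative-bias switch exists for
  robustness exercises; it violates the additive model on purpose.
* 15% cytotoxic extracts at −7σ on cell count and +6σ on Hoechst. The
  magnitudes are calibrated, not arbitrary: with 15% of wells carrying
  large effects, the plate MAD inflates to ≈1.23σ and the polish absorbs
  ≈0.7σ, so an effect θ lands near $(θ-0.7)/1.23$ B-score units. The
  defaults put toxic extracts ≈2 SD beyond the ±2 exclusion cutoffs,
  which is what "clearly cytotoxic" looks like in a screen where ~15% of
  wells die: a handful of surviving cells and intensely condensed
  nuclei.
* 0.5% true hits at 4–5σ on insulin and/or pdx1 (one in five a
  down-hit) — a handful of real effects among >1000 extracts, so the
  bulk of the library serves as its own negative control.
* 0.5% of sample wells masked as imaging artifacts per replicate;
  λ = 50 cells per well (Poisson), per-cell intensities log-normal
  (sdlog 0.5) parameterized by the median so the cell-level and
  well-level generators agree as λ grows.

Because effects are injected in units of σ and the within-plate residual
dispersion is σ, σ units and B-score units coincide up to MAD estimation
error, making spiked effect sizes directly comparable to band widths.

What the generator does *not* emulate: image pixels and segmentation
error, non-additive row×column interactions (except via the
multiplicative switch), spatial autocorrelation beyond row/column
structure, dose–response structure, or infection-efficiency
heterogeneity between cell batches. Passing recovery tests therefore
demonstrates that the pipeline is correct and well-calibrated *under its
own model assumptions*; they do not certify performance on real screens
whose biases are non-additive.

## Problem sizes and determinism

The test suite validates the polish against an independently coded
brute-force oracle on 100 random 8×12 plates with up to 20% missing
wells (agreement to 1e-9), runs the bias-removal study on 200
study-scale screens (15 plates each, pooled diagnostics), and runs the
full default screen (1319 extracts × 5 replicates) end to end, checking
hit sensitivity, null call rate, and exclusion accuracy against ground
truth. All generators draw from seeded, isolated RNG streams; the same
configuration and seed reproduce every output byte for byte (the run
manifest records the seed and a hash of the resolved configuration, and
deliberately contains no timestamps).

## A worked example

```{r example, eval = FALSE}
library(hcscreen)
res <- runScreen(pipelineConfig(simulate = TRUE, seed = 1,
                                outputDir = "screen-run"))
res$recovery$per_parameter
subset(res$bias, parameter == "insulin",
       c(grouping, stage, statistic, df, p_value))
head(res$hits)
```

The run writes `wells.csv`, `bscores.csv`, `effects.csv`,
`extracts.csv`, `hits.csv`, `bias_report.csv`, `recovery.csv`, the
simulated inputs, a resolved configuration echo and a manifest into
`screen-run/`.

## Known limitations

* The additive-bias assumption is inherited from the B-score itself;
  synergistic plate effects are out of model.
* Cytotoxicity cutoffs (±2, conjunctive) reproduce a qualitative rule;
  real screens should inspect the ranked cell-count plot before trusting
  any fixed threshold, and the rank-based mode exists for exactly that
  comparison.
* Extracts at multiple doses are treated as distinct extracts; there is
  no dose–response modeling.
* No multi-parameter joint hit score is provided; insulin and pdx1 are
  called independently and cross-referenced downstream.
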