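# microcolony

Quantitative analysis of yeast **microcolony fitness assays**: time-lapse
bright-field microscopy in which thousands of clonal microcolonies (1 to
~100 cells each) are imaged hourly at low magnification, their areas
tracked, and their individual growth and stress-survival phenotypes
measured in parallel. The package targets researchers studying
growth-rate heterogeneity, persistence and bet hedging in clonal microbial
populations — settings where the *variance* and tails of the growth-rate
distribution matter as much as its mean.

## What it computes

For each microcolony the specific growth rate µ is the least-squares slope
of log area versus time,

    A(t) = A0 * exp(mu * t),    mu = d log A / dt   [1/h],

with the Pearson correlation r of log A on t as fit quality. Around this
estimator the package implements the full assay chain:

* **Segmentation** — dual-threshold bright-field segmentation: colonies are
  simultaneously the brightest (cell centers) and dimmest (cell rims)
  objects in a field; high and low threshold masks are morphologically
  closed and only connected components intersecting *both* masks are kept,
  rejecting one-sided debris. Includes the saturated-pixel focusing rule
  (most saturated frame + 10 µm).
* **Tracking** — greedy centroid-proximity linking with termination on
  neighbour/edge contact, abort on large area drops, and grouping of
  de-novo objects within 0.65 × the absorbing colony's Feret diameter.
* **Growth analysis** — per-colony µ with a five-timepoint minimum, 35 µm
  neighbour / 55 µm edge spatial QC, per-well reference-strain
  normalization, distribution summaries (slow growers = below half the
  median), binned rank-sum comparisons, and area-to-cell-count calibration
  with Bland–Altman statistics.
* **Heat-shock survival** — rigid plate-shift estimation from isolated
  colonies, realignment, survivor (≥ 400 px gained in 16 h) /
  non-survivor (< 300 px) calling with an ignored band, binned Fisher
  tests, multiple logistic regression of survival on growth rate and
  genotype with parsimonious AIC model selection, and the
  arcsine-square-root plating test.
* **Marker screen** — the slope < −2 / DM > 5 screen for slow-growth
  markers on tabular gene data, and the age-expression-ratio (AER)
  analysis of replicative-age contributions to expression noise.
* **Synthetic benchmark** — a seeded time-lapse generator (exponentially
  growing lobed-disk colonies under the bright/dim optical contract,
  growth-anticorrelated marker fluorescence, rigid shock shifts, logistic
  survival) with exact ground-truth manifests, so every stage is testable
  without microscope data.

See `vignettes/microcolony-methods.Rmd` for the model, parameter
rationale, and limitations.

## Worked example

```r
library(microcolony)

fields <- default_scenario(n_fields = 2, seed = 1)   # 128 colonies
run <- run_growth_pipeline(fields, times = 0:8, fluorescence = TRUE)
rec <- run$records

summarize_distribution(rec$mu[rec$included])
#> <growth-rate distribution> n = 128, mean = 0.372, median = 0.3748,
#>   fraction below half-median = 0.0391

bin_and_compare(rec[rec$included, ], "mean_fluor", "mu",
                edges = c(0, 0.2, 0.32, 0.44, 0.5))
#>           bin   lo   hi  n  mean     sem        p degenerate
#> 1     [0,0.2] 0.00 0.20  5 0.684 0.07225 1.60e-04      FALSE
#> 2  (0.2,0.32] 0.20 0.32 15 0.278 0.00650 1.07e-08      FALSE
#> 3 (0.32,0.44] 0.32 0.44 86 0.200 0.00276 6.64e-01      FALSE
#> 4  (0.44,0.5] 0.44 0.50 18 0.141 0.00217 3.06e-10      FALSE
```

The mean rate of 0.372 h⁻¹ (~112-minute doubling) with a 3.9% slow tail
reflects the generator's bulk + slow-tail mixture; marker fluorescence
density falls monotonically across growth-rate bins because the generator
plants a growth-anticorrelated marker — the binned rank-sum comparison
recovers both extremes of the anticorrelation at small p while the central
bin, indistinguishable from the population, is not significant.

```r
shock <- run_survival_pipeline(shock_scenario(n_fields = 6, seed = 1))
survival_by_bin(shock$records, "pre_mu", edges = c(0, 0.2, 0.5))
#>         bin  lo  hi  n n_survivor pct_survival     p degenerate
#> 1   [0,0.2] 0.0 0.2  3          3        100.0 0.089      FALSE
#> 2 (0.2,0.5] 0.2 0.5 45         19         42.2 0.089      FALSE
```

All three slow growers survive the shock versus 42% of the bulk —
graded, growth-rate-dependent persistence, here at n too small for
significance (p = 0.089; the test suite exercises larger cohorts).

A thin CLI over the same functions lives at `inst/cli/microcolony.R`
(subcommands `simulate`, `segment`, `track`, `growth`, `screen`).

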