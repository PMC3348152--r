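---
title: "Methods: microcolony growth, survival and marker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcolony growth, survival and marker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcolony)
```

## The assay and its model

Plating exponentially growing yeast at low density on a glass-bottomed
multi-well plate and imaging every field hourly at low magnification turns a
population-fitness measurement into thousands of parallel single-microcolony
measurements. Each microcolony is a clonal cluster of 1 to roughly 100
cells growing as a monolayer, so its projected area is a faithful proxy for
cell number, and area growth is exponential over the observation window:

\[ A(t) = A_0 e^{\mu t}, \]

with \(\mu\) the *specific growth rate* — the slope of \(\log A\) against
time, in h\(^{-1}\). A rate of 0.4 h\(^{-1}\) corresponds to a ~104-minute
doubling time. The package estimates \(\mu\) per colony by ordinary least
squares on \(\log(\text{area in px})\) versus hours, with the Pearson
correlation \(r\) of that fit as the per-colony quality score. The natural
log (not \(\log_{10}\)) is used throughout: typical bulk rates near
0.38 h\(^{-1}\) only correspond to realistic yeast doubling times under the
natural log.

Working at the colony scale sidesteps single-cell segmentation entirely:
the unit of observation is the connected colony object, and all downstream
statistics (rate distributions, survival, marker screens) are per-colony.

## Segmentation: the dual-threshold AND rule

In bright-field at 10x, yeast are simultaneously the *brightest* objects in
a field (cell centers) and the *dimmest* (cell perimeters), on an
intermediate background. Segmentation exploits exactly this signature:

1. Build a high mask (pixels above the high threshold) and a low mask
   (pixels below the low threshold).
2. Subject each mask to `morph_rounds` of dilation followed by the same
   number of rounds of erosion (a closing), fusing speckled centers and
   broken rims into continuous objects.
3. Label connected components of the union and keep only components that
   intersect **both** cleaned masks; drop components below `min_object_px`.

Step 3 is the debris filter: dust, precipitates and illumination artifacts
are bright *or* dark, but essentially never both in the paired
colony-specific arrangement, so they fail the AND condition.

The absolute threshold values are hardware-dependent and therefore not
fixed by the method; the package defaults to scale-free robust per-frame
estimates, `median ± 5 × MAD`. At the synthetic generator's default
contrast (background 0.50, interior 0.80, rim 0.15, noise sd 0.02) these
sit far from both tails of the background noise (5σ implies a false pixel
rate of ~3×10⁻⁷) while leaving wide margins to the colony intensities.
Absolute overrides are accepted for calibrated rigs. `morph_rounds = 3`
with a 3×3 cross element closes the 1–2 px rim gaps but can only bridge
gaps up to ~6 px, an order of magnitude below the 35 µm (~52 px)
neighbour-exclusion radius, so cleanup cannot merge colonies that the QC
filters would accept. Connected components are 4-connected; after even one
round of dilation with a 3×3 element any 8-connected colony is also
4-connected, so the choice is immaterial at colony scale.

The focusing-offset rule mirrors plate-focusing practice: about 10 µm below
the ideal focal plane yeast appear "large and white", so among a stack of
candidate offsets the one whose image has the most saturated pixels marks
that plane, and the returned offset adds 10 µm to it. Ties break toward the
lowest offset, making the rule deterministic.

## Tracking rules

Microcolonies barely move between hourly frames, so linking is greedy
nearest-centroid within `max_displacement` (default 15 µm/frame), with
ties broken toward the candidate whose area ratio is closest to 1. Three
rules bound the lifetime of a track:

* **Neighbour contact** — when two objects' masks come within 1 px of each
  other, both tracks terminate (their areas are no longer attributable).
  The contact frame itself is recorded.
* **Edge contact** — an object touching the outermost row/column terminates
  its track after the touching point is recorded.
* **Area-drop abort** — an area decrease exceeding
  `area_drop_abort_fraction` (default 25%) between consecutive frames
  almost always indicates a segmentation failure, so the track is aborted
  and the aberrant measurement is *not* recorded.

Objects appearing de novo in later frames are usually single cells that
drifted off a nearby colony. They are merged into the nearest active track
when within `0.65 ×` that track's Feret diameter (its longest straight-line
span), otherwise ignored. Two readings of the 0.65 rule are possible —
against the newcomer's span or the absorber's; the package uses the
absorbing colony's span, since the newcomer is typically a single cell
whose span carries no information about the plausible drift radius.

Tracks shorter than five recorded timepoints are excluded from growth
fitting. Spatial QC excludes colonies whose time-averaged centroid lies
within 55 µm of the field edge (truncation bias) or within 35 µm of the
nearest neighbour's (close fast-growing pairs merge before five timepoints
accrue, biasing the surviving close-pair records slow). Neighbour distance
is centroid-to-centroid between time-averaged centroids. The two filters
commute; reasons are stored sorted so the output is order-independent.

The default pixel pitch is 0.6708 µm/px (0.45 µm²/px), back-derived from
the printed pixel/area equivalences of the survival thresholds below; it is
configurable everywhere it enters (displacement gates, QC radii, isolation
threshold).

## Heat-shock survival

Removing and replacing the plate for the shock translates every colony by
one rigid vector. The shift is estimated as the mean centroid displacement
of *isolated* colonies (nearest neighbour beyond `isolation_threshold`,
default 100 µm; at least three are required), then all post-shock
centroids are corrected by it and matched back to pre-shock tracks.
Rotation is not modelled: at these magnifications residual rotation after
re-seating is far below the matching gate.

A colony is called a **survivor** if it grows by ≥ 400 px (180 µm², about
eight cells) within 16 h after the shock, a **non-survivor** if it grows by
< 300 px (135 µm², about six cells), and is **ignored** in the [300, 400) px
band. Growth is the endpoint difference from the *first post-shock frame*
(not the last pre-shock area, which would conflate shock-time shrinkage
into the change; a config flag restores the alternative). The ignored band
makes the two calls robust to the exact cut-offs.

## Statistics

* **Binned comparisons** report per-bin mean ± SEM and a two-sided
  Wilcoxon–Mann–Whitney p-value of the bin against the *remaining* records.
  Comparing against the complement (rather than the full population
  including the bin) keeps the two samples independent and makes the
  degenerate case — a bin holding every record — well-defined; it is
  flagged rather than tested. The test is exact (full enumeration) for
  untied samples up to 20 per group and a tie-corrected normal
  approximation otherwise, the policy implemented by `stats::wilcox.test`.
* **Binned survival** uses Fisher's exact test (two-sided by summing table
  probabilities at or below the observed table's) of each bin's
  survivor/non-survivor counts against the complement.
* **Logistic survival model.** Survival is binary, so its joint dependence
  on pre-shock growth rate and genotype is fit by logistic regression.
  Four models are compared — full (main effects + interaction), main
  effects, and each single effect — by AIC, with one refinement: models
  within 2 AIC units of the best are treated as statistically
  indistinguishable and the most parsimonious of them is selected. A plain
  lowest-AIC rule would admit a spurious interaction in ~16% of datasets
  generated without one (P(χ²₁ > 2)); the 2-unit parsimony margin drops
  this to ~5% and matches the usual "not significantly better" reading of
  model comparison. Complete separation is detected explicitly and the
  error names the separating covariate.
* **Plating survival** compares strains on arcsine-square-root transformed
  replicate proportions with a Student's t test; the transform is defined
  at 0 and 1, so extreme proportions are data, not errors.
* **Slow growers** are operationally colonies growing below half the
  population median rate; the fraction is scale-invariant by construction.
* **Reference normalization** divides each rate by the mean rate of
  reference-strain colonies in the same well, optionally rescaling so a
  control strain's grand mean equals one. The reference mean uses
  included-only records (QC-excluded reference colonies carry the very
  biases the filters exist to remove); a config flag could widen this, but
  the package takes included-only as the definition.

## The marker screen

Candidate markers of slow growth must (i) anti-correlate with bulk growth
rate — chemostat expression-versus-growth-rate regression slope strictly
below −2 — and (ii) vary strongly from cell to cell — DM
(distance-to-median expression noise, synthetic dextrose medium) strictly
above 5. The background set is genes with both values reported; strict
inequalities follow the thresholds' definitions. The replicative-age
analysis bins genes by log₂ of the age expression ratio (AER, mean young
expression over mean old expression) and reports per-bin DM with rank-sum
p-values, plus the share of DM variance explained by |log AER| (R² of a
linear fit). The published analysis does not print its bin edges, so edges
are a required argument, not a default pretending to match.

## The synthetic generator

Every stage above is validated against a generator whose ground truth is
exact by construction:

* Colonies are filled disks with a small seeded lobed boundary
  perturbation (amplitude 4%, 3–6 lobes); the rasterized footprint is
  calibrated to `round(A₀ e^{µt})` pixels exactly (the radius is chosen as
  the k-th smallest shape-normalized pixel distance), while the manifest
  stores the analytic area, so manifest area ratios obey the exponential
  law to machine precision.
* Intensities follow the optical contract (interior above background, 1–2
  px rim below it) with additive Gaussian noise; a fixed seed makes frames
  bit-identical. Per-frame noise seeds derive from the field seed and the
  timestamp, so the generator never disturbs the caller's RNG stream.
* Growth rates are drawn from a bulk-plus-slow-tail mixture — Normal(0.38,
  0.05²) h⁻¹ with a 5% weight Uniform(0, 0.15) h⁻¹ tail, truncated to
  [0, 0.5] — echoing the continuous distribution with a slow minority seen
  in clonal populations; the truncation keeps colonies within field bounds
  over 9 h. Marker fluorescence is growth-anticorrelated,
  \(F = 0.9\,e^{-4\mu}\), emulating a trehalose-synthase-like slow-growth
  marker.
* Heat shock applies a rigid translation, freezes non-survivors, and grows
  survivors at their post-shock rate; survival is drawn with logistic
  probability decreasing in µ.
* The default plate scenario lays colonies on a jittered lattice (120 px
  pitch, ±8 px jitter, ≥ 90 px edge margin, 64 colonies per 1024² field —
  a density comparable to ~30 colonies per 10x field of view) spaced so
  that footprints stay disjoint and clear of the QC margins for 9 h; the
  shock scenario plates 8 colonies per field so that isolated colonies are
  available for realignment, mirroring low-density plating practice.

What the generator does **not** emulate: physical optics (point-spread
function, shading, defocus blur), three-dimensional cell piling in large
colonies, budding morphology, illumination drift, or colony-shape change
over time (shapes scale isotropically). Passing the synthetic benchmarks
therefore demonstrates correctness of the *algorithms* under the stated
optical contract, not robustness to every real-world artifact; threshold
and morphology parameters remain the knobs to retune on real data, and the
image noise/contrast defaults are stated choices, not values fitted to
real micrographs.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant-area tracks report
µ = 0 with r = 0 and a degenerate-fit flag (the correlation is undefined);
uniform frames segment to zero objects (MAD = 0 collapses both
thresholds); a focusing stack without saturated pixels, fewer than three
isolated colonies, and post-shock series shorter than the window are
errors, not guesses. Greedy matching ties break deterministically (area
ratio, then order), and the defocus saturation count is strict, so all
pipelines are reproducible at fixed seeds.

The test-suite scenarios use 512 colonies (8 fields × 64) for the
end-to-end growth benchmark and 32 shocked colonies across 4 fields; the
acceptance script scales the same scenario to 2,048 colonies (32 fields).
These sizes give tight empirical bounds (e.g. ~2,000 dividing colonies for
the log-linearity fraction) while keeping a full run in minutes on one
CPU. Statistical cross-checks run at the sizes where their oracles are
exact: full enumeration for rank-sum and Fisher tests at n ≤ 10 per group,
and n = 5000 cohorts for logistic-recovery checks.

## Known limitations

* Termination by neighbour contact discards the contact frame onward, so
  dense platings lose fast growers preferentially — the same technical
  bias the spatial QC filters address; the generator's default spacing
  avoids it, real data relies on the 35 µm filter.
* A colony whose track was terminated keeps appearing in later frames and
  may be absorbed as "de novo" area by a close neighbour; at QC-compliant
  spacings this cannot happen (the 0.65 × Feret radius is far below the
  neighbour distance), but it is a known hazard of the blunt de-novo rule
  in crowded fields.
* The plate-shift estimator assumes pure translation; a visibly rotated
  re-seat violates its model and will surface as a large realignment
  residual rather than an error.
* Fluorescence density is a plain mean over the colony mask with no
  background subtraction or flat-field correction; comparisons are valid
  within an imaging configuration, not across them.

## A worked pipeline

```{r worked, eval = FALSE}
fields <- default_scenario(n_fields = 2, seed = 1)
run <- run_growth_pipeline(fields, times = 0:8)
rec <- run$records

# distribution of included growth rates
summarize_distribution(rec$mu[rec$included])

# marker fluorescence against growth-rate bins
sim <- simulate_timelapse(fields[[1]], 0:8, fluorescence = TRUE)
run_f <- run_growth_pipeline(fields[1], 0:8, fluorescence = TRUE)
bin_and_compare(run_f$records, "mean_fluor", "mu",
                edges = c(0, 0.2, 0.3, 0.4, 0.5))

# heat shock: call survival and model it
shock <- run_survival_pipeline(shock_scenario(n_fields = 4, seed = 1))
rec_s <- shock$records
rec_s$genotype <- "wt"   # single-genotype demo; add a second for the model
survival_by_bin(rec_s, "pre_mu", edges = c(0, 0.15, 0.3, 0.5))
```
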