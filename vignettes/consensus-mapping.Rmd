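---
title: "Consensus mapping of suitability ensembles: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus mapping of suitability ensembles: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmconsensus)
```

## What the pipeline assumes

`sdmconsensus` treats a set of published habitat-suitability predictions as
equally valid estimates of one species' potential distribution. No model is
weighted, recalibrated or skill-scored: the only per-model operation is the
choice of a presence threshold, and everything after binarization is a
symmetric function of the ensemble. The substantive assumptions are:

* suitability surfaces are probability-like but **not comparable across
  models** in absolute value — hence per-model thresholds rather than a
  common cutoff;
* occurrence records mostly represent established populations, but a small
  fraction may not (sporadic individuals, sink habitats) — hence a fixed
  omission fraction (default 5%) rather than the minimum training presence;
* all inputs live in, or have been projected to, a single **projected
  equal-area CRS**, so that cells of the common grid have equal area and
  area percentages are cell-count percentages. The package verifies CRS
  identity whenever grids are combined and refuses to combine mismatches; it
  does not reproject. Reprojection, where needed, is a pre-processing step
  for the user's GIS tooling.

## Thresholding

The fixed-omission threshold is a quantile of the suitability values at the
occurrences. The quantile convention matters at small sample sizes and under
heavy ties, so it is explicit. The default `lower_empirical` rule returns
the largest *observed* value whose strictly-below fraction is at most the
omission fraction `p`. This guarantees, exactly and by construction, that no
more than `p` of the calibration occurrences fall below the threshold — the
property the method is named for — and involves no interpolation, so results
are identical across platforms. The conventional interpolated quantile
(`linear_interpolation`, type-7) is available for comparison but can violate
the strict bound at small `n`.

Two further conventions: a cell whose value equals the threshold is
**suitable** (an occurrence sitting exactly at the threshold should not be
omitted), and multiple occurrences in one cell all count toward the quantile
(`dedupe_cells = TRUE` switches to one-per-cell thinning; the default
reflects that the pipeline does not otherwise thin its occurrence input).
Thresholds are calibrated at each model's native resolution, before any
harmonization, and future projections reuse the present-day threshold of
the matching model — the transfer refuses mismatched model ids.

## Harmonization

The common grid defaults to 25-km square cells — intermediate among native
resolutions of roughly 1 to 55 km — over the intersection of all model
extents, i.e. the largest region where every model is informative. Counts
are `ceiling(extent / cell_size)`, with an optional lattice anchor for runs
that must share cell boundaries.

Aggregating a fine binary map into a coarse cell uses **area-weighted
majority**: the cell is suitable when suitable source area is at least half
of the non-nodata overlap. Two boundary rules are deliberate:

* an exact 50/50 split classifies as suitable — the precautionary reading
  for a vector-risk map (configurable via `fraction_cutoff`);
* a cell is nodata when more than half of it is nodata or outside the
  source extent; otherwise the valid part decides.

When the target is *finer* than the source, each target cell takes the class
of the source cell containing its centre; inventing sub-cell structure by
area-splitting a coarse cell would manufacture precision the source does not
have. Only categorical aggregation is provided — continuous resampling is
out of scope, except for the generator-internal area-weighted mean used to
build synthetic model surfaces.

## Consensus, trajectories, zones

Agreement is the per-cell sum of binary maps; a cell is nodata as soon as
any contributor is nodata, which restricts the analysis to the common
extent (the `lenient` mode sums available models instead, for exploratory
use). The classification rule is data, not code: `consensus_rule(n,
min_agree)` with default `min_agree = floor(n/2) + 2`, i.e. 5 of 7 and 4 of
5 for the default ensemble sizes. Categories are 1 (consensually
unsuitable), 2 (high uncertainty, about half the models agreeing), 3
(consensually suitable); the rule is symmetric, so flipping every binary
map swaps categories 1 and 3.

Trajectories cross the two timeframes into codes `10*present + future`.
Because published headline shares can be read against different
denominators, `area_report()` exposes each aggregate with its member codes
and its share of the study area, and additionally the share of the newly
suitable area for its subsets — both bases, explicitly, rather than a
single ambiguous percentage.

Zone summaries compute **exact polygon–cell intersection areas**
(Sutherland–Hodgman clipping + shoelace area) by default; fractions are
taken over the zone's non-nodata overlap. A centre-membership mode exists
for very large grids, and both are validated against a Monte-Carlo oracle
in the tests. The baseline zone category is the widest-coverage one, ties
toward higher severity. The worst-case override fires when the
second-largest category covers at least one third of the zone *and*
worsens the trajectory; trajectory severity is ordered lexicographically by
(future, present) category, since prospective risk is dominated by the
future state. Two points were genuinely open design choices — whether both
timeframes may be substituted, and how trajectories are ordered. The
default substitutes each timeframe independently
(`mode = "single"` restricts to one substitution), and the ordering above
is the one under which "more unfavourable" is monotone in the future
category first. With the threshold at 1 the override is provably inert.

## The synthetic study system

The generator's defaults describe the study conditions under which the
pipeline is exercised and tested:

| parameter | default | rationale |
|---|---|---|
| extent | 2000 × 2000 km | continental scale; ~6000 25-km common cells |
| latent grid | 5-km cells | finer than all but one model resolution |
| `n_models` / futures | 7 / 5 | ensemble sizes of the motivating analysis |
| resolutions | 25, 18, 5, 5, 50, 55, 1 km | heterogeneous, ~1–55 km span |
| scales | alternating unit / percent | exercises normalization |
| `autocorrelation_length` | 200 km | synoptic-scale climate gradients |
| `model_noise_sd` | 0.1 | models agree except near transitions |
| `n_occurrences` | 500 | order of a curated occurrence compendium |
| `future_shift` | 0.3 at the northern edge | marked poleward expansion |
| `n_zones` | 65 | urban-area cohort size |

The latent field is white noise smoothed by a separable Gaussian kernel
(edge-renormalized), then rank-transformed to a uniform marginal — chosen
over spectral synthesis because the bandwidth maps directly to a
correlation length and the code stays dependency-free. Model surfaces add
independent smoothed noise rescaled to `model_noise_sd`, clip to [0, 1] and
aggregate to the model's native grid over a jittered extent; occurrences
are rejection-sampled with acceptance probability equal to latent
suitability; zones are jittered rectangles in disjoint slots, guaranteeing
zero pairwise overlap.

What the generator does **not** emulate: real coastlines and land masks
(no nodata in generated surfaces), differing climate scenarios between
models, non-stationary anisotropic autocorrelation, and spatial clustering
of occurrence effort. Passing tests therefore demonstrate the pipeline's
arithmetic and its statistical behaviour under the stated structure, not
fidelity to any particular real ensemble.

Every generator function seeds the RNG from `cfg$seed` plus a fixed
per-operation offset, so each artefact is reproducible both in isolation
and within `generate_ensemble()`.

## Problem sizes and numerical choices

The test suite runs the pipeline on a 500-km, 10-km-latent configuration
(seven models, 200 occurrences, 9 zones) and the recovery checks on the
full default system; the acceptance script runs the default system end to
end. Coordinates round-trip through text rasters at 10 significant digits;
grid alignment is checked with an absolute tolerance of 1e-9 CRS units.
Degenerate inputs fail loudly: empty extent intersections, occurrence sets
with no grid overlap, all-nodata grids, misaligned grids and cross-CRS
combinations are all errors, never silent repairs.

One verification worth stating precisely: with low model noise (sd 0.05),
the present-day consensus categories recover the latent suitable/unsuitable
truth — latent field thresholded at its own 5%-omission value — on at least
95% of common-grid cells whose latent value is at least 0.1 from the
threshold; with high noise (sd 0.3) the high-uncertainty class concentrates
at cells nearer the threshold than the confidently classified ones. Both
are computed by `evaluate_recovery()` and asserted in the acceptance tests.

## Known limitations

* No reprojection: inputs must already share the working CRS.
* Zones are single outer rings; holes and multipolygons are unsupported.
* The lenient (per-cell ensemble size) mode leaves the rule adjustment to
  the caller.
* The harmonization rule is the standard area-weighted majority; where an
  ensemble's provenance prescribes a different conversion, the
  `fraction_cutoff` and `any_suitable` rules are the supported variations.
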