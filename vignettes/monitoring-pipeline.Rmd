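---
title: "The grid-plus-random monitoring pipeline: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The grid-plus-random monitoring pipeline: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibesim)
```

`sibesim` implements the computation chain behind a long-term intertidal
macrozoobenthos survey: design and yearly maintenance of a station
network, simulation-based design evaluation, laboratory processing
rules, hierarchical biomass imputation, geostatistical mapping, and the
published three-file data model. This vignette is the package's own
account of the underlying models, the tunable parameters and why their
defaults are what they are, and what the synthetic-world experiments do
and do not demonstrate about real field data.

## The synthetic mudflat world

Field campaigns are simulated on a virtual mudflat whose statistical
structure matches what the downstream analysis assumes.

**Latent density surfaces.** Each species' log density is a Gaussian
random field with exponential covariance,

$$\mathrm{cov}(h) = \sigma^2_{\mathrm{partial}}\, e^{-h/r},$$

plus a nugget (uncorrelated micro-scale) component, around a mean log
density. Densities are the exponential of this field, i.e. log-Gaussian:
patchy, positive, right-skewed — the texture benthic density maps show.
Throughout the package `r` is the *e-folding* distance; correlation
drops to ~5% at about three times `r`. The exponential family is the
default because observed correlograms of mudflat species decay smoothly
and monotonically; a spherical alternative is selectable in
`variogram_model()`. Fields are drawn by Cholesky factorisation of the
covariance matrix (with a relative jitter of 1e-9 on the diagonal for
numerical positive-definiteness), which is exact and, at the raster and
station-set sizes used here (up to a few thousand points), fast.

**Sampling a station.** A visit applies the field protocol: counts are
Poisson with mean `density × core area` (0.0173 m² from the boat,
0.0177 m² by foot; ~92% of stations are boat-sampled by default);
individual lengths are lognormal per species and individuals under the
1-mm sieve mesh are discarded; individual ash-free dry mass (AFDM)
follows the power law $m = a L^b$ with multiplicative lognormal noise.
The noise sd defaults to 0.15 on the log scale, the residual spread
typical of species-level biomass–length fits in this kind of programme;
its coefficient of variation, $\sqrt{e^{\sigma^2} - 1} \approx 15\%$, is
the yardstick the imputation-recovery experiments are judged against.

**Subsampling.** When an eligible taxon exceeds 100 individuals in a
sample, only a binomial subsample targeting ~30 individuals is measured
and the fraction recorded. The trigger of 100 is a package choice (field
protocols state the ~30-individual target but no trigger); any value
comfortably above the target reproduces the relevant behaviour, namely
that corrected densities `count / fraction / area` stay unbiased — which
the tests verify directly.

**Measurement pathologies.** Lengths and masses are deleted with
per-species probabilities, and "broken" individuals carry only a shell
width (width = length / 6.5), mirroring the razor-clam records whose
lengths must be estimated downstream.

**Sediment.** Grain-size spectra are a two-mode mixture: a mud mode
(lognormal around 20 µm) and a sand mode centred on the local
median-grain-size field, mixed by the local mud-fraction field and
binned to the 126 geometric classes spanning 0.04–2000 µm that
laser-diffraction analysers report.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: tidal hydrodynamics and sediment transport,
between-year population dynamics (each year is a fresh field draw),
species interactions, taxonomic misidentification, and the real Wadden
Sea geography. The generator's value is that its ground truth is known
exactly, so recovery and unbiasedness can be asserted; transfer to real
data rests on the field data resembling log-Gaussian patchy surfaces,
not on these tests.

## Sampling design and its evaluation

`generate_design()` lays a grid of nodes at `origin_offset + k × spacing`
(500 m default) over the intertidal mask, keeps nodes on mudflat cells,
then appends random stations placed uniformly over the total in-mask
gridline length until the random share of all stations reaches the
target. Two conventions matter:

- *The random fraction is random/total*, not random/grid: the published
  per-year percentages (e.g. 330 random of 3,892 total ≈ 8%) only
  reproduce under this reading. The achieved count solves
  `n_r = round(f · (n_g + n_r))`.
- *Uniform-over-gridline-length* placement is the maximum-entropy
  reading of "random distances from grid stations along gridlines";
  raster cells are half-open `[x, x+cell)`, so a point on a shared edge
  belongs to exactly one cell.

Yearly maintenance (`update_design()`) deactivates stations whose cell
stopped being mudflat (identifiers are retained forever and never
reused), adds grid stations on newly emerged nodes, and per tidal basin
adds or deactivates random stations until each basin's random share is
within two percentage points of the target.

`evaluate_designs()` compares five equal-sized layouts — simple random,
grid, two transect variants, and grid with a random subset of nodes
replaced by gridline-random stations — under fields of increasing
autocorrelation. The transect geometries are parallel lines at the grid
spacing with along-line spacing of half (`transect_A`) or one
(`transect_B`) grid spacing; the historical transect definitions are not
published, so these serve as representative members of that family and
only relative orderings are interpreted. Autocorrelation levels bracket
the grid spacing: ranges of 0 (pure nugget), 250, 500 and 1000 m at
fixed sill. Three criteria are computed per replicate:

1. **Minimum detectable difference** between two periods or areas from
   the two-sample normal power formula at α = 0.05 and power = 0.80,
   using the design's sample standard deviation.
2. **Mean absolute prediction error** of ordinary kriging (under the
   design's own fitted variogram) at uniform hold-out points.
3. **Range bias**, fitted range minus generating range.

Fields are simulated jointly at all designs' stations and the hold-out
points by one Cholesky draw per replicate — statistically identical to
sampling a continuous surface at those points, and what makes 200-
replicate runs cheap. The headline property, reproduced by the tests at
200 stations and 200 replicates, is that adding random stations to the
grid reduces the absolute range bias: the grid alone has no station
pairs closer than the spacing, exactly the lags that separate nugget
from short-range structure.

## Laboratory rules

- **Fragment counting.** From 2011 on, polychaete counts are heads (+
  wholes). Before 2011 loose heads and tails were tallied;
  `max(heads, tails) + wholes` is used, which cannot double-count one
  fragmented animal. Sand-mason worms count whole individuals only.
- **Razor-clam lengths** from shell-fragment widths: length = 6.5 ×
  top width or 6.6 × bottom width, flagged estimated so downstream fits
  can exclude them.
- **Standardization** divides by the subsample fraction and the core
  area of the platform, in that order; it is exactly homogeneous in the
  count and unbiased under binomial subsampling.
- **Sediment reduction.** Classes are geometric, so interpolation inside
  a class is log-linear for both the 63-µm mud split (the straddling
  class contributes its log-linear share — 63 µm is not a class edge of
  the 126-bin grid) and the median (the size where the cumulative volume
  curve crosses 0.5). With mass on both sides of a gap, the median is
  reported at the first crossing.

## Biomass–length models and imputation

Missing AFDM is predicted from length where possible. The model is a
LOESS (span 0.6, degree 2) of log mass on **log length**: the power-law
allometry is exactly linear on that scale, so the smoother carries no
systematic bias at small lengths, where log mass is strongly curved
against raw length — the noiseless-recovery test (a = 10⁻⁵ g, b = 3,
within 1% over the interior length range) fails on the raw-length axis
for any span. Log mass also spans orders of magnitude, which makes a
single residual spread — and hence one outlier fence — meaningful across
lengths.

**Outlier fences** sit at the residual quartiles ± 2 × IQR, the standard
Tukey construction with k = 2 ("outside twice the interquartile range"
also admits a median-anchored reading; the quartile-anchored form is
used). On clean Gaussian residuals these fences flag well under 1% of
records. An absolute guard of 1e-8 on the log scale prevents
floating-point dust from being flagged when residual spread is
numerically zero. One removal pass is followed by one refit; iteration
counts beyond one are not specified by the protocol and further passes
changed nothing in synthetic experiments.

**Hierarchical scale selection.** For each record the candidate pools
are season (all years pooled), year, region, and tidal basin, coarse to
fine; the *finest* level holding at least 75 complete records is fitted
(45 for species under 11 mm, whose records are plentiful but short-
ranged; 30 for the mean fallback). "Region" is not defined by the
published protocol; the package defaults to a west/east split of the
tidal basins and accepts any configurable grouping. The selector is
deterministic, and its full decision table over all count ladders in
{0..120}⁴ is verified against an independent brute-force oracle in the
acceptance tests.

**Dispatch.** Records with a length use the LOESS prediction (method 24
in the species table), clamped to the training length range — no
extrapolation beyond observed lengths, requests outside are served the
domain-edge value and flagged. Records without length use the
hierarchical mean (method 12), or for taxa so designated the average of
*prior* years only (method 25). Every imputation carries a provenance
tag (method, level) into an audit table; the published `biota.csv`
schema is never widened.

## Correlograms, variogram fitting and kriging

The correlogram is derived from the empirical semivariogram (Matheron
estimator) as `corr(h) = 1 − γ(h)/σ²`, because the same fitted γ then
drives the kriging — a Moran's I per distance class is available as an
alternative estimator label. Default lag bins are 10 bins of width
spacing/2 up to 5 × spacing; bins under 10 pairs are flagged unreliable
and excluded from fitting.

Fitting is weighted least squares with pair-count weights and four range
starts to avoid local minima. The range search is bounded above by twice
the largest usable lag: beyond the observed lag span the range is simply
not identifiable, and an unbounded search lets single realisations run
to absurd values that dominate mean-bias summaries. A fit whose
spatially structured component is numerically zero is flagged
`unidentifiable` (nugget-only data carry no range information).

Ordinary kriging solves the bordered system once per station set and
shares the factorisation across prediction cells (25-m default
resolution). Its contracts are checked numerically: weights sum to one
at every cell to 1e-8, and with a zero nugget the surface reproduces
every observation exactly. A singular system (duplicated stations with
zero nugget) falls back to nearest-neighbour prediction with a warning.
Cells farther than three ranges from any station are flagged
low-confidence. For right-skewed density fields a `log1p` transform is
available; the back-transformed surface is a median-type estimate and
carries retransformation bias, so it is labelled as such rather than
corrected.

## The data model

The three published files are written with their exact column names
(including the published spellings `occurance` and
`taxonomic_indentification_level`), missing values as empty fields, and
dates in ISO-8601. `biota.csv` stores no absence rows; `zero_fill()`
reconstructs them, emitting exactly |samples| × |taxa| rows.
Percentages in campaign summaries are rounded half-up — banker's
rounding fails to reproduce several printed cells. The averages row is
computed over an explicit year range, defaulting to 2008–2019: the
printed means equal that range's arithmetic means, although the
published footnote mentions only the COVID-reduced 2020 campaign as
excluded; both behaviours are selectable.

## Problem sizes and determinism

The test and acceptance runs use the study's stated sizes where the
property is about those sizes — 200 stations × 200 replicates for the
design comparison, 400 stations × 50 fields for range recovery, the
full {0..120}⁴ ladder sweep — and compact worlds (≤ 1,600 raster cells,
≤ 1,024 stations) elsewhere, chosen so each property is measured with
comfortable Monte-Carlo margin. Every stochastic component takes an
explicit seed; identical configuration and seed reproduce worlds,
campaigns and designs byte-for-byte, with per-stream child seeds kept
within the 32-bit integer range.

## Known limitations

- The generator draws years independently; it cannot exercise analyses
  of temporal trend or persistence.
- Kriging is isotropic ordinary kriging; tidal-flat anisotropy and
  environmental covariates (universal kriging) are out of scope.
- The transect variants stand in for unpublished historical geometries;
  only orderings among designs, not their absolute metrics, are
  meaningful.
- The west/east "region" default is a convention; real deployments
  should configure the grouping used operationally.
- The equirectangular planar↔WGS84 conversion is adequate for synthetic
  worlds tens of kilometres across, not for precise geodesy.
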