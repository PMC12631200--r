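---
title: "Methods: early detection of defoliator damage from canopy spectra and LiDAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early detection of defoliator damage from canopy spectra and LiDAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defoliascan)
```

## The problem

Defoliating caterpillars (*Dendrolimus*-type pests) consume conifer
needles from the lower crown upward. Management depends on catching trees
in the **mild** stage — defoliation percentage (DP) at or below 30 %,
before growth losses set in — yet that is exactly when canopy-viewed
spectral change is weakest. The pipeline in this package stages individual
trees as mild (DP ≤ 30), moderate (30 < DP < 50) or severe (DP ≥ 50) by
fusing two complementary observables:

- per-tree mean canopy reflectance over 145 narrow bands spanning
  400–1000 nm (UAV hyperspectral imagery), which responds to chlorophyll
  and water loss; and
- the per-tree LiDAR point cloud, which responds to the *structural*
  change — missing needles, thinner lower crown, weaker returns — that
  precedes clear spectral change.

## Band selection

Adjacent hyperspectral bands are strongly correlated; classification
works as well, and more robustly, on a handful of well-chosen bands.

**ISIC.** For band $i$, with classes $z = 1,\dots,m$, class means
$m_{z,i}$ and standard deviations $S_{z,i}$, the instability index between
classes is the mean over unordered class pairs

$$\mathrm{ISIC}_i \;=\; \binom{m}{2}^{-1} \sum_{z<j}
  \frac{S_{z,i}+S_{j,i}}{\lvert m_{z,i}-m_{j,i}\rvert},$$

the ratio of within-class spread to between-class separation: low values
mark separable bands. The leading constant is stated ambiguously in the
literature this index comes from; we use the mean over the $m(m-1)/2$
pairs. Any fixed positive constant produces the same band *ranking* and
rescales the difference series uniformly — and the threshold below is
tuned, so the choice is behaviour-neutral. When a class pair has equal
means at a band (to machine tolerance) the band's ISIC is $+\infty$:
such a band is maximally unstable, and any finite threshold removes it
through the propagation rule below rather than through an epsilon hack.

**D filtering.** $D_i = \lvert \mathrm{ISIC}_i - \mathrm{ISIC}_{i+1}\rvert$
flags bands whose instability jumps relative to their neighbour. Band $i$
is removed iff $D_i > T$; the last band, which has no right neighbour, is
judged by its left difference. An $\infty$ ISIC propagates $\infty$ to
both adjacent $D$ entries. This attribution (each $D_i$ charged to band
$i$) is a design choice — the source material does not say which band of
an offending pair to drop — and retention is monotone in $T$ by
construction.

**Threshold tuning.** $T$ is tuned by wrapper search: a coarse grid over
$[0, \max D_{\text{finite}}]$ (9 points by default), then two refinement
rounds that shrink the step tenfold around the incumbent. The objective is
mean stratified 10-fold cross-validated accuracy of the random-forest
classifier on the retained bands; among thresholds within 0.005 of the
best accuracy the one retaining fewest bands wins (then the smaller
threshold). Identical retained sets are cached, so the search cost is
bounded by the number of *distinct* subsets, not grid points.

**SPA.** The successive projections algorithm is a greedy
collinearity-minimizing forward chain on the column-centered reflectance
matrix: starting from a given band, each step selects the band whose
residual norm is largest after orthogonal projection onto the span of the
bands already chosen. We implement it by deflation (numerically equivalent
to explicit Gram–Schmidt, which serves as the brute-force oracle in the
tests) and stop early when all residual norms fall below a relative
tolerance of $10^{-9}$, which keeps the selected columns linearly
independent. Chains are launched from every band by default; the pipeline
subsamples starts (15 evenly spaced) to bound the wrapper cost. For each
size $k$ the best chain prefix by CV accuracy defines the accuracy curve;
the chosen size is the smallest $k$ within 0.005 of the curve maximum —
"fewest bands at equal accuracy" throughout.

**ISIC-SPA** chains the two: the D-threshold filter denoises the grid,
then SPA decorrelates within the retained subset. Both stages are recorded
in the result.

## Vegetation indices and the Spearman search

Four index families are built over the selected bands: NDSI
$(R_1-R_2)/(R_1+R_2)$, DSI $R_1-R_2$, RSI $R_1/R_2$ and RA
$R_1/(R_2+R_3)$. RSI and RA are ratio forms: a product form of RSI would
be informationally redundant with DSI, and RSI is canonically a ratio
index. All *ordered* distinct pairs (triples for RA) are enumerated and
scored by $\lvert\rho\rvert$, the Spearman correlation (Pearson on
mid-ranks) between the index and the ordinal stage codes 1 < 2 < 3;
ordered enumeration costs a factor of two but sign differences are
absorbed by the absolute value, and ties break lexicographically by
wavelength so the search is deterministic. Requested wavelengths resolve
to the nearest grid band, since named wavelengths (686, 759, 926 nm) do
not fall exactly on a 145-point grid over [400, 1000] nm.

## LiDAR metrics

Metrics are computed on points above a 0.5 m height threshold (ground and
understorey returns excluded), ten per tree:

- `elev_percentile_{10,20,25,30}th` — linear-interpolation percentiles of
  $z$ (the most common percentile convention; fixed for reproducibility);
- `elev_AIH_5th` — the accumulated-interval-height percentile: the
  smallest $z$, in ascending order, at which the running sum of point
  heights reaches 5 % of the total. On $z = \{1,2,3,4\}$ the cumulative
  sums are 1, 3, 6, 10, so AIH$_{50}$ = 3 while the ordinary median is
  2.5. Because points are weighted by height, AIH reacts strongly to loss
  of *low* points — the defoliator's signature — and, unlike ordinary
  percentiles, it is not translation-equivariant;
- `int_mean`, `int_std`, `int_skewness`, `int_kurtosis`, `int_p50` —
  moments of return intensity on the filtered points. Kurtosis is
  *excess* kurtosis from population central moments (Gaussian → 0; a
  symmetric two-point distribution → −2).

A tree with fewer than 10 filtered points is flagged and excluded
downstream with a warning rather than yielding unstable metrics.

## Screening and classification

Each candidate feature (4 VIs + 10 LiDAR metrics) is kept only if the
Kruskal–Wallis test across all three stages *and* the pairwise
mild-vs-moderate test are both significant at $p < 0.01$. The pairwise
criterion is the early-detection filter: canopy-top elevation percentiles,
for instance, typically separate severe trees but not mild from moderate,
and are dropped. P-values are raw — no multiple-testing correction — which
matches the screening convention the pipeline follows; with 14 candidate
features at $\alpha = 0.01$ the expected false-retention count is small,
but this is a caveat worth knowing.

Classification uses a stratified 6:4 split (per-class train count =
nearest integer to 0.6 × class size; for 103/99/82 trees this gives
170 train / 114 test with per-class test counts 41/40/33), a
500-tree random forest with square-root feature subsampling and a fixed
seed, and confusion-matrix metrics: OA, Cohen's Kappa, per-class
producer's (recall) and user's (precision) accuracies. Feature importance
is permutation-based mean decrease in accuracy on an explicit held-out
set, averaged over 10 seeded permutations with its dispersion reported —
the same estimand as out-of-bag MDA up to the choice of evaluation set,
but with the evaluation set stated rather than implicit.

## The synthetic-data generator

Field campaigns of this kind are rarely deposited, so the generator is a
first-class module, not a test fixture. It emulates:

- **Stand design**: 103/99/82 trees per stage; DP drawn uniformly on
  [5, 30], (30, 50) and [50, 90] per stage — covering each interval
  without piling up on the defining boundaries;
- **Spectra**: a smooth healthy-conifer template (green peak, chlorophyll
  wells, red-edge ramp, NIR plateau, weak 970 nm water dip) on a 145-band
  grid evenly spaced over [400, 1000] nm (spacing ≈ 4.17 nm; the stated
  4 nm resolution and 145-band count cannot both hold, and the band count
  is what downstream indexing needs). Damage adds a DP-proportional
  reflectance gain in a smooth red-edge window (the blue-shift signature)
  and a DP-proportional loss in a smooth NIR window (water/biomass loss,
  e.g. at 926 nm); with noise off these responses are exactly monotone in
  DP band-by-band. Noise is a smooth correlated component (Gaussian bump
  mixture, 60 nm length-scale, sd 0.01) plus white per-band noise
  (sd 0.004) — the correlated part matters, because SPA and ISIC exploit
  adjacent-band correlation. No quantitative effect sizes are published
  for this system; the defaults (red-edge gain 0.0012, NIR loss 0.0010
  reflectance per unit DP) were chosen once as spectroscopically plausible
  and produce overlap between adjacent stages rather than trivial
  separation. They are tunable but not calibrated to any instrument.
- **Crowns**: a conical crown (mean 5 m length, 1.5 m radius, base at
  1.5 m, with tree-to-tree variation in all three) sampled at 189
  points/m² ground-projected density. Defoliation removes a DP/100
  fraction of points by per-point Bernoulli draws weighted toward low
  heights (weight $(1-u)^2$ in relative crown depth by default) —
  bottom-up feeding. Intensities are Gaussian on an 8-bit-like 0–255
  scale, with the mean declining 0.6 per unit DP, a per-tree random
  offset (sd 10, emulating incidence-angle and calibration variation
  between crowns), and a spread that grows with DP (exposed bark and
  mixed returns increase heterogeneity).

What the generator does **not** emulate: radiative transfer (no
PROSPECT/SAIL), occlusion between crowns, terrain, ground returns, GPS or
segmentation error, or any covariance between a tree's spectral and
structural noise beyond their shared dependence on DP. Tests passing on
synthetic data therefore demonstrate that the *algorithms* behave as
specified under the assumed damage phenomenology — not that any
particular accuracy level transfers to a real stand.

With uniform (unbiased) point removal the cumulative-height quantile
`elev_AIH_5th` is approximately unbiased under thinning, so it shows no
systematic DP trend; only lower-crown-biased removal drives it upward.
The test suite asserts exactly this contrast, which is the metric's
design rationale.

## Reproducibility and numerical choices

- One root seed fans out to fixed per-stage seeds (spectra, clouds,
  selection CV, split, forests, importance), so stages can be rerun in
  isolation and a rerun with the same config reproduces every number
  bit-identically (tested).
- Stratified folds and splits are deterministic in the seed; per-class
  train counts use half-up rounding, not banker's rounding.
- ISIC's zero-denominator rule, the D propagation rule and the
  "fewest-bands within 0.005" tie-breaks are all exact, not tolerance
  fudges; the SPA early-stop tolerance is $10^{-9}$ relative.
- Degenerate inputs fail loudly: empty grids, single-class data, classes
  with fewer samples than folds, thresholds that remove every band, and
  clouds with fewer than 10 filtered points are errors, not silent NAs.

## Problem sizes used by the test and acceptance runs

The oracle suites run on small random instances (ISIC: 100 datasets up to
~20 × 8; SPA: 50 matrices up to 8 × 6, all starts, against explicit
Gram–Schmidt). Recovery experiments plant class signal at the bands
nearest 686/759/926 nm in 75-tree stands and ask ISIC-SPA to find at
least two of the three planted bands across seeds; the planted bands
carry *complementary* class-response patterns (early-saturating, late,
graded), because a collinearity-minimizing selector will — correctly —
keep only one of several perfectly redundant bands. Pipeline-level checks
(fusion ordering, determinism) run the full default 284-tree stand with
the red-edge/NIR trio as fixed bands; the selection algorithms themselves
are exercised by the recovery experiments, which keeps the wrapper-search
cost where it is informative. The acceptance script runs the complete
ISIC-SPA pipeline on the default stand.

## Known limitations

- The ISIC leading constant is an interpretation (behaviour-neutral, but
  an interpretation); so are the ratio readings of RSI/RA and the
  AIH definition, which the source processing software names but does not
  define.
- The screen applies no multiple-testing correction.
- Wrapper selection accuracy curves are seed-dependent; the package fixes
  seeds rather than averaging over them, trading variance for exact
  reproducibility.
- Synthetic accuracies are not forecasts of field accuracies (see the
  generator's non-goals above).
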