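---
title: "Methods: from worm images to longevity biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from worm images to longevity biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormspan)
```

## The problem

Genetically identical *C. elegans* reared in a uniform environment still
differ widely in lifespan. When single animals are followed by daily
brightfield and fluorescence microscopy from hatching to death, a set of
early-adulthood measurements — body length and its maintenance, movement
after light stimulation, brightfield texture "decrepitude", red-channel
autofluorescent age-pigment accumulation, and the level and spatial
pattern of microRNA promoter::GFP reporters — each predicts a sizeable
fraction of an individual's remaining lifespan. wormspan implements the
full chain from image series to those statistics: segmentation,
straightening and registration, biomarker measurement, day-window
summaries, cross-validated regression, diagnostic dichotomization,
partial-correlation networks and time-resolved ridge prediction, plus a
seeded synthetic generator so that every stage is testable without any
external data.

## The synthetic study conditions

The generator, not real microscopy, defines the conditions under which the
package is tested, so its defaults are fixed and documented here.

**Cohort tables.** Lifespans are Gaussian with mean 10.7 d and SD 1.9 d —
the cohort-level moments observed for 463 individually cultured animals in
the study this pipeline reproduces — truncated below at the end of the
day-3–7 observation window. Truncation at day 7 removes about 2.6% of
draws (matching the observation that fewer than 3% of animals die before
day 7) and biases the mean by only ~0.12 d; truncating one sampling
interval later would remove ~8% and shift the mean by ~0.3 d, so the
window end is used. For each named biomarker the per-animal day-window
slope is linear in lifespan, `s_i = a + b L_i + eps_i`, with the noise
variance chosen against the *realized* lifespan draws so that
`Var(bL)/Var(s)` equals the requested planted R². Daily values are the
line through the window midpoint with slope `s_i` plus per-day Gaussian
jitter (SD 0.5 by default), so the day-window least-squares slope is
itself an estimate and that code path is exercised; at the default scales
the slope-estimation noise attenuates a planted R² of 0.27 by less than
0.01. The linear-Gaussian form is the simplest model with an exact planted
R²; nonlinear aging trajectories, the mild left skew of the real lifespan
distribution, and death-related measurement artifacts are deliberately not
modeled — passing tests show the statistics are computed correctly, not
that real worms are linear.

**Images.** A worm is a spline through seeded random control points with a
smooth half-width profile that is positive in the interior and zero at the
tips (canvas 120 × 480 px, arc length ≈ 300 px — small enough for
seconds-scale tests). Brightfield frames are a dark body (intensity 0.35,
interior speckle scaled by a roughness knob standing in for age-related
texture change) on a bright background (0.85); fluorescence frames add
Gaussian hotspots at the head, vulva and tail and/or a diffuse body
signal over a dim background, which mirrors the transition between
tissue-specific and diffuse reporter expression that the expression PCA is
meant to capture. Sequential frames are rigidly displaced by a configurable
number of pixels; camera noise is added last, and the ground truth (mask,
centerline, arc length, vulva pixel, hotspot centers) describes the
noiseless geometry. The rendering is deliberately not photorealistic: no
PDMS edge artifacts, no defocus, no death-related posture changes.

## Segmentation and geometry

A logistic patch classifier (per-patch mean, SD, min, max and center value
at radius 4 — features the source protocol leaves unspecified; these five
suffice on brightfield contrast) yields a probability map; the mask is the
largest connected component above 0.5 with holes filled. The centerline is
the least-cost 8-connected path through the inverted Euclidean distance
transform, cost `(max(DT) − DT) + 10⁻³` per step, so the optimum follows
the interior ridge with a mild shortness bias; Dijkstra's algorithm (via
igraph) finds it, and the raw pixel path is smoothed with a short
endpoint-preserving running mean before resampling to 1-px arc spacing —
without this the 8-connected staircase inflates arc length by several
percent. Head/tail seeds default to the two mask pixels at maximal
geodesic distance; explicit points can (and in tests do) come from ground
truth, replacing the interactive clicks of the original protocol.
Brightfield/fluorescence frame pairing maximizes the mutual information of
the joint 64 × 64-bin intensity histogram, ties going to the earliest
frame. All coordinates are 1-based (row, column), the R convention.

Straightening samples the image by bilinear interpolation along
perpendiculars to the centerline; off-worm pixels carry validity flags and
are excluded from all statistics. The "unit worm" standard is a fixed
100 × 24 grid (a resolution/speed compromise) with per-age mean arc length
and width profile; warping maps each animal's normalized arc position and
width-scaled transverse coordinate onto it. Longitudinal registration uses
five evenly spaced interior control points (arc positions 1/6 … 5/6,
endpoints pinned), a monotone piecewise-linear map, and coordinate-wise
hill climbing on `cor(image∘warp, reference) − λΣd²` with steps shrinking
0.05 → 0.005; the quadratic penalty (λ = 1 by default, on correlation
units) keeps the objective smooth and pins control points that the image
content does not constrain. The vulva anchor, when present, initializes
the middle control point. Population alignment alternates mean-image
computation with per-image alignment until the mean changes by less than
1% of its dynamic range; on warped copies of a common template this
converges in 2–3 iterations. Only longitudinal (stretch/compress) warping
is performed — no lateral displacement — and cross-channel alignment is
handled by frame pairing, not warping.

## Biomarkers

Fluorescence is corrected as `(raw − dark) / normalized-flat / exposure`
with negatives clipped, making frames acquired at 1/10/100 ms
bracketing comparable; bracket selection reduces to the longest
non-overexposed frame. Summaries default to the 95th percentile (linear
interpolation, `quantile` type 7) over the whole body or the head region,
defined as the initial 20% of arc length. Size measures treat the animal
as a solid of revolution of its half-width profile: length `L`, volume
`π∫w²ds`, surface area `2π∫w ds`.

The motion score starts from four statistics over in-animal pixels: the
fraction changing relative intensity by more than 18% — with
`|a−b| / max(mean(a,b), ε)` as the symmetric definition of relative
change — and the mean pixel-wise coefficient of variation, each before and
after light stimulation. Pre-stimulation change fractions average over
consecutive pre-frame pairs (spontaneous movement); each post-stimulation
frame is compared to the last pre-stimulation frame (stimulus-evoked
movement), which is the only reading consistent with a uniform intensity
rescaling counting as a 100% change. The texture signature samples 17 × 17
patches inside the outline (per-patch mean removed, stride 4 by default),
clusters 30 textons per two-day age bin from day 3–4 through 15–16 by
k-means (210 overall; ages past 16 reuse the last bin), and histograms
nearest-texton assignments. Both feature sets are mapped to days of life
remaining by ν-SVR with an RBF kernel (motion: C = 10, ν = 0.8, γ = 0.3;
texture: C = 5, ν = 0.6, γ = 0.004), predictions always coming from folds
not containing the scored animal. Autofluorescence bleed-through into the
GFP channel is below 10% relative intensity in the source data and
correcting it changed nothing there, so no unmixing is applied by default.

## Expression-pattern PCA

Aligned fluorescence images have their per-image mean subtracted first, so
components describe only the spatial distribution of expression, not
brightness; invalid pixels are zeroed and excluded from the orientation
convention. The eigendecomposition runs on the image-by-pixel matrix (the
Gram route when pixels far outnumber images). Signs are fixed so the mean
PC loading over the head region is positive: positive scores then mean
head/vulva/tail-specific expression and negative scores diffuse body
expression. Scores are projections divided by the training-score SD —
standard deviations from the training mean. Fitting uses all images from
day 3 onward; scoring windows are a separate parameter.

## Statistics

Lifespan is the midpoint of the last-alive/first-dead bracket (the
expectation under a uniform prior on death time within the interval);
never-dead animals are right-censored and excluded from regressions.
Day-window summaries are the in-window mean and the least-squares slope of
observed points only (no interpolation of missed days). OLS regressions
report coefficients in unit-free SD terms so their magnitudes are
comparable; significance uses `F = R² df_err / ((1 − R²) df_model)` with
`df_model = p`, `df_err = n − p − 1`. Leave-one-out R² comes from held-out
residuals via the exact hat-matrix identity (verified in tests against n
explicit refits); it can be negative. The survival prediction index is the
standardized-weight OLS on the seven summaries (length mean/slope, motion
mean/slope, texture mean/slope, autofluorescence slope). Diagnostic tests
dichotomize predictions and outcomes about their means — the choice that
balances sensitivity and specificity — and compare cohort lifespan
distributions with the two-tailed two-sample Kolmogorov–Smirnov test.
Kernel density estimates use a Gaussian kernel with Scott's rule-of-thumb
variance `σ²n^(−0.2)`. Raw p-values are reported throughout; no
multiple-testing correction is applied, matching the analysis this
package reproduces. Collinear predictors (condition number above 10⁸) are
rejected with the offending pair named; excluded animals are dropped
before all statistics with counts reported.

The partial-correlation network is the PC algorithm's skeleton phase at
α = 0.001: starting from the complete graph, an edge X–Y is removed as
soon as any conditioning subset S of the pair's neighbours (sizes
0, 1, 2, …) makes the partial-correlation t-test non-significant — this is
algebraically the t-test on X's coefficient in the regression of Y on
{X} ∪ S, the "multiple-regression independence test", and is brute-force
checkable. Edge orientation is deliberately not inferred (it was not
robust in the source analysis); processing order is fixed lexicographic,
with an order-independent "stable" variant available. The consensus across
datasets marks an edge solid when every dataset containing both endpoints
finds it, dashed when only some do; nodes with no edges anywhere are
reported unplaceable — with a marker explaining only ~10% of lifespan
variance at n ≈ 150, the α = 0.001 test frequently lacks the power to
place it at all.

Time-resolved prediction regresses lifespan on all raw daily values of one
biomarker up to each age plus all pairwise products (squares included;
products stay within one biomarker, since per-biomarker curves are the
object of interest), using ridge regression with the penalty minimizing
`GCV(λ) = n·SS_res/(n − tr H)²` over a 50-point log grid spanning 10⁻⁴ to
10⁴ (the source analysis fixes neither the grid nor the exact GCV form;
both are exposed in the API). The reported per-age R² is in-sample at the
chosen penalty, which matches the curve being reproduced and is therefore
somewhat more optimistic than the held-out day-window models; an honest
split is available but off by default.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (`quantile` type 7), fixed.
* Interpolation of images: bilinear everywhere; invalid pixels excluded
  from correlations and summaries.
* Constant-intensity images make the alignment correlation undefined: an
  identity warp is returned with a warning. Constant predictor columns,
  empty masks, empty regions, degenerate dichotomization splits and
  zero-variance KDE inputs raise informative errors.
* Hill climbing resolves ties by keeping the incumbent; k-means and fold
  assignment are seeded; PCA signs follow the head-region convention, so
  all fits are deterministic given inputs and seeds.
* Problem sizes in the test-suite and acceptance script (400-animal
  cohorts, 50-seed Monte-Carlo means, 20-worm segmentation suites,
  2000-sample network recovery) were chosen so that Monte-Carlo error is
  well inside each tolerance while a full run stays in the minutes range
  on a laptop core.

## Known limitations

The generator plants signal only in day-window slopes, so window means are
uninformative by construction except through noise; real biomarkers carry
correlated mean and slope information. Texture roughness is an amplitude
knob on i.i.d. speckle, which exercises the texton machinery but has no
age-specific spatial structure, so per-age-bin dictionaries are equivalent
to a pooled one on synthetic data. The PC skeleton assumes Gaussianity
through its partial-correlation test, as in the source analysis.
Right-censoring is handled only by exclusion — survival-curve modeling is
out of scope. The published supplementary tables are not redistributed
with the package; `replicate_published_analysis()` runs on them when the
user supplies files in the documented layout.
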