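---
title: "Methods: focal adhesion morphometrics, biosensor dynamics and substrate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal adhesion morphometrics, biosensor dynamics and substrate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesio)
```

adhesio quantifies four aspects of PKA signaling at focal adhesions
(FAs): FA morphology and radial distribution in fixed-cell images,
two-channel colocalization, ratiometric biosensor dynamics within
individual FAs, and fold-enrichment screening of candidate kinase
substrates. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where the
underlying workflows left genuine freedom. Every empirical number
quoted here is computed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the package does not
itself measure.

## FA segmentation and morphometrics

The segmentation pipeline follows the standard FIJI particle-analysis
recipe for adhesion markers: median filter (radius 1.5 px), rolling-ball
background subtraction (radius 50 px), a binary threshold at `k` times
the mean of the background-subtracted image with `k` restricted to
9–15, connected-component analysis, and moment-based shape descriptors.

Decisions inside that recipe:

* **Median radius 1.5 px is exactly a 3×3 window.** The set of pixels
  within Euclidean distance 1.5 of a pixel centre is the 3×3
  neighbourhood, implemented as a pmin/pmax sorting network for speed;
  larger radii fall back to a constant-time median filter.
* **Rolling ball as grayscale opening.** The background is estimated by
  erosion-then-dilation with a flat disc of the stated radius. For
  structures much smaller than the disc this is the classic rolling-ball
  behaviour. The estimate is computed on a 3×3 mean-smoothed copy of the
  image (the image itself is never smoothed): an erosion over thousands
  of pixels otherwise tracks the extreme low tail of the read noise and
  underestimates the background by several noise standard deviations,
  which in turn inflates the `k × mean` threshold enough to lose every
  FA. The classic implementation pre-smooths for the same reason.
* **Threshold semantics.** The mean is taken over the whole
  background-subtracted image, read literally from the workflow this
  reproduces; this makes the threshold depend on FA density, which is
  one reason the original operators inspected a range of `k`. Values of
  `k` outside [9, 15] are rejected. The threshold is strictly
  greater-than. `k = "auto"` picks the `k` whose FA count changes least
  against `k + 1` — a reproducible plateau heuristic standing in for the
  original manual choice of the "most representative" threshold.
* **8-connectivity, 0.25 µm² minimum area.** Components are 8-connected.
  No minimum area is inherent to the recipe; 0.25 µm² (≈ 10 px at
  0.16 µm/px) suppresses single-pixel noise while lying well below real
  nascent adhesions. An optional `max_area_um2` (e.g. 15 µm²) isolates
  the largest adhesion class when that sub-analysis is wanted.
* **Moments with a 1/12 pixel correction.** Ellipse-equivalent axes use
  the eigenvalues of the pixel-coordinate covariance plus 1/12 (the
  variance of a unit pixel) per coordinate, so an n×m rectangle has
  aspect exactly n/m and a single pixel is well defined (aspect 1). The
  estimator choice (moments rather than a bounding-box fit) is a
  package decision; the original macro does not state its estimator.
* **Radial position.** `r_rel` is the FA-to-cell-centroid distance
  divided by the centroid-to-boundary distance along the same ray,
  clamped to [0, 1]; the boundary is found by ray marching through the
  binary cell mask (step 0.25 px). When no whole-cell channel exists,
  the convex hull of all segmented FA pixels stands in for the cell
  outline. A degenerate FA at the cell centroid has `r_rel = 0`.
  `polar_unwrap()` (rows = angle clockwise from "up", columns = radius,
  bilinear interpolation) is a visualization aid; quantitative radial
  statistics always come from `relative_radial_distance()`.

Distribution comparisons use the two-sample Kolmogorov–Smirnov test
with the asymptotic p-value, matching the usage for FA radial
histograms; the statistic is validated in the tests against a
brute-force ECDF scan over exhaustively enumerated small samples.

## Colocalization

Pearson's correlation, Li's ICQ and Manders M1/M2 operate on masked
pixel vectors. Conventions that needed fixing:

* ICQ counts zero products (a pixel exactly at either channel mean) as
  non-positive — they stay in the denominator. The source plugins do
  not document their convention; this one is deterministic and keeps
  ICQ in [−0.5, 0.5].
* Manders uses the threshold-count form by default (fraction of
  above-threshold pixels overlapping), matching "relative amount of
  signal that overlaps" phrasing; the intensity-weighted form is
  available via `intensity_weighted = TRUE`.
* Constant channels make correlation and ICQ undefined: that is an
  error, not a silent 0.
* Masked ratio images threshold the structural channel by Otsu unless a
  threshold is given, multiply both inputs by the binary mask, and
  define the ratio only where the masked denominator is positive;
  undefined pixels are NaN flags, never errors.

All three statistics are verified exactly against naive double-loop
implementations, and range/symmetry/affine-invariance properties are
exercised on hundreds of random rasters.

## Biosensor dynamics

The ratiometric readout divides an activity-sensitive channel by an
abundance reference fused to the same adhesion protein, so the ratio
cancels sensor abundance. Analysis decisions:

* **Ratio = Σnum/Σden over FA pixels**, not the mean of per-pixel
  ratios: sum/sum weights pixels by denominator intensity and is far
  more robust to low-denominator pixels at FA edges. Both channels are
  rolling-ball background subtracted first. Smoothing is a −/+1
  boxcar with shrinking edge windows. Frames with a zero denominator
  sum are undefined and are excluded from statistics, not imputed;
  one-frame gaps inside a track are bridged by linear interpolation and
  flagged.
* **Tracking** is greedy nearest-centroid with a 1 µm/frame gate —
  adequate for adhesions, which move far less than their spacing
  between frames; unmatched detections start new tracks, and a track
  missing once may be re-acquired one frame later.
* **Distal orientation.** The axis endpoint farther from the cell
  centroid is distal. Registration rotates each frame's patch so the
  major axis is vertical, distal up, by bilinear resampling on the
  rotated grid, masked to the FA's ellipse-equivalent region.
  Near-circular frames (aspect < 1.2) have no reliable axis and inherit
  the previous frame's orientation; a track that starts near-circular
  cannot be oriented and errors.
* **Kymographs and peak scoring.** Axis positions are normalized to the
  current FA length (0 = medial, 1 = distal, 25 samples, 3-px line
  width). The peak is the global maximum of the ratio matrix; thirds
  are [0, 1/3) medial, [1/3, 2/3) central, [2/3, 1] distal. Ties are
  broken by earliest time then larger position and are flagged in the
  result. Scoring the time-collapsed global maximum (rather than
  tallying per-frame peaks) is a package decision; both conventions
  agree on hot spots that persist, and the synthetic cohorts plant
  persistent hot spots.
* **Growth states.** Rates are least-squares slopes of length versus
  time over sliding 5-min windows stepped per frame, thresholded at
  ±0.02 µm/min with 5-min persistence. Window classes are mapped to
  per-frame classes by majority vote of the covering windows, and
  maximal same-class frame runs spanning ≥ 5 min become segments. The
  majority-vote step matters: windows straddling a growth-to-shrinkage
  transition average to near-zero slope, and classifying their whole
  span as Stable would manufacture a spurious ≥5-min Stable segment in
  a track that merely switches behaviour; with the vote, a 6-min growth
  followed by 6-min shrinkage yields exactly one Growing and one
  Shrinking segment. A track may legitimately contribute segments to
  several states. Per-state statistics (min/mean/max of the smoothed
  ratio within each segment) are compared by one-way ANOVA with Tukey
  HSD; a constant-response cohort is reported as p = 1 rather than an
  ill-conditioned F-test. Ratio-versus-|rate| associations are OLS fits
  with r² and two-sided p, undefined below 3 points.

## Substrate screen

Screening follows the kinase-catalyzed biotinylation design: per trial,
one lysate is split into ctrl (kinase + plain ATP), neg (ATP-biotin, no
kinase) and exp (ATP-biotin + kinase) reactions. Conventions:

* Zero intensity means not detected (the MaxQuant convention); decoy
  (`REV__`) and contaminant (`CON__`) rows are dropped at load.
* Control-enriched removal: ctrl > exp in a strict majority of trials
  where both were detected, or detected exclusively in ctrl. The
  per-trial rule behind "higher intensities in unlabeled samples" is
  not stated anywhere; majority-of-evaluable-trials is the neutral
  reading.
* Enrichment is exp/neg per trial; neg = 0 with exp > 0 is flagged +Inf
  (exclusive to the experimental sample — maximal enrichment) and by
  default counts toward hit calling (`count_inf = FALSE` switches this
  off); both zero makes the trial not evaluable.
* A hit needs enrichment ≥ threshold in ≥ `min_trials` trials; the
  standard lists are ≥1.5-fold (all possible hits) and ≥6.0-fold (high
  stringency), each in ≥2 of 4 trials. By construction the 6.0-fold
  list is nested in the 1.5-fold list, and raising either parameter can
  only shrink the list — both properties are tested. Output ordering
  (descending median finite enrichment, then accession) is a
  reproducibility choice.
* The motif scanner is a transparent consensus scorer, deliberately
  simple: strong = R at −3 and −2 (R-R-x-S/T, the canonical RRAS/RRAT
  class), moderate = R at −3 only or K-R at −3/−2. The score is a
  weighted determinant fraction (−3 and −2 basic residues weighted
  twice, hydrophobic +1 once; R = 1, K = 0.6) in [0, 1]. It substitutes
  a neural-network site predictor used in the original workflow and
  makes no claim to reproduce that network's probability cutoffs; it
  answers the coarser question "does this candidate contain at least
  one moderate-to-strong PKA consensus site".

## The synthetic-data generator

Every stage is validated against planted ground truth, because the
imaging and proteomics data this kind of study rests on are not
reproducible at desk scale. What the generator emulates, and what it
does not:

* **Scenes** (`generate_cell_image`): a circular cell (closed-form
  `r_rel` truth) with non-overlapping elliptical FAs, Gaussian PSF
  blur, additive Gaussian read noise clamped at zero. Defaults — chosen
  once as typical of a 60×-objective fibroblast field — are 256×256 px
  at 0.16 µm/px, cell radius 15 µm, background 100 AU, FA intensity
  400 AU, noise σ = 20 AU (5% of FA intensity), PSF σ = 1 px.
  Overlapping planted FAs are an error: their ground truth would be
  ambiguous. Not modelled: photobleaching, stage drift, 3-D PSFs,
  uneven illumination, FA clustering/splitting. Segmentation passing
  on these scenes shows the pipeline recovers well-separated elliptical
  adhesions at realistic noise; it says nothing about touching or
  irregular adhesions.
* **Movies** (`generate_ratio_movie`): the denominator channel tracks
  FA geometry (linear length change at a planted rate); the numerator
  is the denominator times a planted activity field — uniform, or a
  Gaussian hot spot (amplitude 1, width 0.12 of the FA length) centred
  in the distal/central/medial third at 5/6, 1/2 and 1/6 of the axis;
  an inhibitor step multiplies activity by (1 − drop) over a frame
  interval. FAs shrinking below one pixel are truncated and recorded.
  Acquisition regimes mirror the two real protocols: 3 frames/min for
  dynamics and 3-s intervals for kymographs.
* **Trajectories** (`generate_length_trajectory`): linear trend plus
  i.i.d. Gaussian length noise, labelled by the ±0.02 µm/min rule. The
  validation cohorts draw rates per class — Growing U(0.03, 0.10),
  Stable U(−0.01, 0.01), Shrinking U(−0.10, −0.03) µm/min in equal
  thirds — because the three behaviours are distinct phenotypes in
  peripheral FAs; rates arbitrarily close to the decision boundary are
  unclassifiable by any estimator at finite noise, and planting them
  would measure the boundary's sharpness, not the classifier.
* **Quantitation tables** (`generate_quant_table`): per-protein base
  intensities are lognormal (median 10⁸, sdlog 1, the scale of LFQ
  intensities). Because each trial's three reactions are run from one
  lysate split, per-trial abundance variation is shared across
  conditions: the generator draws one lysate factor per protein and
  trial and applies per-reaction lognormal noise to the
  kinase-containing conditions relative to the trial's negative
  control, so `lognormal_noise_sigma` is exactly the sdlog of the
  measured enrichment ratio. Planted hits multiply the experimental
  condition by `planted_fold` in every trial before noise;
  control-enriched proteins get 5× control intensity; missing values
  zero entries independently at `missingness_rate` (default 0.05).
  Screen-recovery validation runs at `missingness_rate = 0`: under the
  +Inf convention, a censored negative control is indistinguishable
  from maximal enrichment, so planted-truth false-discovery counts at
  nonzero missingness measure the censoring convention, not the fold
  rule. Peptide-level effects, shared peptides and
  intensity-dependent missingness are not modelled.

All generator randomness flows from a single per-call seed through a
private RNG stream (the caller's `.Random.seed` is untouched), and
identical specs with identical seeds are bit-reproducible.

## Validation problem sizes

The acceptance script and test suite use: 50 ten-FA scenes for
segmentation recall and area error; 300 trajectories at σ = 0.05 µm for
classifier accuracy; 300 single-FA movies (64×64 px, 7 frames at 3-s
intervals) with 60/25/15% distal/central/medial hot spots for peak
scoring; a 30/30/25 growing/stable/shrinking cohort with a +0.2 planted
stable-state ratio offset; and 1000-protein tables with 50 planted
8-fold substrates. These sizes give binomial confidence intervals tight
enough to detect recovery failures of a few percent while keeping a
full validation run to about a minute.

## Known limitations

* The `k × mean` threshold inherits the cell-density dependence of the
  workflow it reproduces; fields with very different FA densities are
  not directly comparable at a fixed `k`.
* The rolling-ball background is a flat-disc opening, not a true
  sphere; for background varying on scales near the ball radius the
  two differ.
* Tracking is greedy and single-hypothesis; densely packed or fast
  adhesions can fragment into multiple tracks rather than swap.
* Absolute biosensor ratio values depend on optics and are not
  meaningful across instruments; only relative and within-FA patterns
  are analyzed.
* The motif scanner is a consensus filter, not a trained site
  predictor; its score ranks determinant matches, not phosphorylation
  probability.
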