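---
title: "Outline morphometrics of grape pips: models, choices and limits"
author: "pipmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of grape pips: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipmorph)
```

## The problem

Grape pips (seeds of *Vitis*) carry taxonomic signal in their dorsal
silhouette: wild Eurasian pips are elongate with a pronounced stalk-like
beak, North American wild species are squatter, and domesticated forms are
more elongate still. Archaeobotanists and palaeobotanists exploit this by
scanning seeds, extracting their outlines, summarizing each outline with a
fixed-length shape descriptor, and classifying specimens of unknown
affinity (archaeological or fossil material) against a reference collection
of modern accessions. `pipmorph` implements that entire chain — silhouette
to outline to elliptic Fourier descriptors to discriminant classification —
together with a synthetic seed-shape generator, so every stage is testable
without access to proprietary seed-image collections.

## From image to outline

A scan is thresholded (Otsu by default, or a fixed cutoff), the largest
foreground component is kept, components smaller than 1% of it are treated
as scanner dust, and interior holes are filled: a seed silhouette is simply
connected. The boundary is traced as the sub-pixel 0.5-level iso-contour of
the binary mask (`grDevices::contourLines`), which gives smoother outlines
than pixel-edge chains and therefore less spurious high-harmonic power; the
pixel-edge trace (`EBImage::ocontour`) serves as a cross-check in the test
suite, not in the pipeline. Pixel coordinates become millimetres via the
scan resolution (`mm = px * 25.4 / dpi`). Outlines are stored
counter-clockwise — coefficient signs depend on orientation, so one
convention keeps all specimens comparable — and resampled to 360 points at
exactly uniform arc-length spacing. Resampling preserves the first point;
start-point standardization belongs to the descriptor normalization, not to
the imaging stage.

One numerical caveat, documented here because it looks like a bug when first
encountered: uniform arc-length division is *not* exactly idempotent. The
resampled polygon's chords are not exactly equal, so re-dividing it moves
vertices by a small amount (well below the point spacing, zero for a
uniform circle). Tests assert exact idempotence only where it holds.

## Elliptic Fourier descriptors

A closed outline `(x(t), y(t))`, parameterized by arc length `t` over one
period `T`, expands as

$$x(t) = a_0 + \sum_{n\ge1} a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T},$$

and likewise `y(t)` with coefficients `c_n, d_n`. Coefficients are computed
from the chord-length parameterization of the polygon by the classical
closed-form per-segment accumulation — exact for polygons and indifferent
to unequal point spacing, unlike an FFT of resampled coordinates. The
harmonic power `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2` quantifies each
harmonic's contribution; the package truncates at six harmonics (24
coefficients), a rank at which the synthetic seed shapes retain well over
95% of their 20-harmonic power while higher ranks mostly add digitization
noise.

A subtlety of the arc-length convention: an axis-aligned ellipse sampled
uniformly in its *parametric angle* has exactly one harmonic, but the same
ellipse parameterized by *arc length* does not — a percent-scale share of
its power sits in odd higher harmonics. The package follows the arc-length
convention consistently; closed-form identities are therefore checked on
the circle (where the two parameterizations coincide) and on the
normalization algebra applied to analytic coefficients.

### Normalization

Descriptors are standardized using the first-harmonic ellipse: position
terms are zeroed, the parameter origin is shifted so the first point lies
on the major axis, the plane is rotated to align that axis with x, and all
coefficients are scaled by the semi-major axis magnitude. The normalized
first harmonic is `(1, 0, 0, d1)` with `d1 > 0` the axis ratio; `a1`, `b1`
and `c1` are retained in the 24-coefficient vector even though
normalization fixes them, keeping the conventional feature dimension
(downstream selection ignores constant columns).

Two ambiguities need deterministic resolution:

* **The joint 180° start/rotation flip.** Both orientations satisfy the
  first-harmonic conditions. The package compares candidates by the
  skewness of `x(t)`: a pip's beak-bearing end makes that skewness positive
  when the asymmetric end points along +x, and the flip negates it. This is
  robust to coefficient noise, unlike any rule keyed to a single
  near-zero coefficient; exactly symmetric shapes fall back to a
  lexicographic comparison of harmonic-2+ coefficients.
* **Near-circular first harmonic** (axis ratio above 0.99): the standard
  orientation angle becomes ill-conditioned, so the package anchors the
  start angle on harmonic 2 instead, scanning for the angles that minimize
  its off-diagonal energy and disambiguating the discrete minima with the
  same skewness rule. This keeps the normalization map continuous where the
  first ellipse degenerates.

Normalized descriptors are invariant to translation, rotation, scaling and
starting point to 1e-8, verified over random poses in the test suite.

## The statistical engine

The classification follows the standard cascade for this kind of material:

1. **PCA** (covariance, centred, unscaled) of the 24 coefficients, with a
   deterministic sign convention. For discriminant analyses the PCA is
   fitted on the reference specimens and unknowns are projected into it;
   components are retained up to 99% cumulative variance, and the LDA
   consumes these uncorrelated scores (a `lda_input = "raw"` switch feeds
   the coefficients directly instead).
2. **Stepwise selection by Wilks' lambda** with partial-F thresholds
   F-to-enter 3.84 and F-to-remove 2.71 — the defaults of the legacy
   statistical packages whose stepwise LDA this reproduces. Greedy forward
   entry with backward elimination; `f_enter > f_remove` guarantees
   termination; constant and collinear columns are never selected; ties
   break to the lowest column index. If nothing reaches the entry
   threshold the caller falls back to all non-constant variables, with the
   event logged.
3. **Pooled-covariance LDA** with equal priors by default (reference group
   sizes are sampling artifacts of seed collections; proportional priors
   are available). The posterior for specimen `x` and group `g` is
   proportional to `prior_g * exp(-Mahalanobis^2(x, mean_g)/2)`. A ridge of
   `1e-8 * trace/dim` is added once if the pooled covariance is numerically
   singular — 24 near-collinear coefficients with small groups can be rank
   deficient — and a remaining singularity is an error naming the offending
   variables. Posterior ties resolve to the first group in model order and
   are reported.
4. **Leave-one-out cross-validation** refits the model for every held-out
   reference specimen *with the variable set held fixed* — the selection is
   run once on the full reference set, matching the single published model
   a practitioner reports. Row-percentage confusion matrices and the
   overall cross-validated percentage summarize the result.
5. **Unknown-group allocation**: unknowns are assigned by maximum
   posterior; under a threshold rule a specimen is assigned only if its
   maximum posterior reaches `p_min` (0.90 by default, boundary inclusive)
   and is otherwise counted "unassigned".

Report tables round to one decimal, half away from zero; full-precision
values live in the CSV outputs, and identical configurations reproduce
byte-identical report files.

## The synthetic generator

Because no seed-image collection ships with the package, the generator
stands in for one, and it is first-class, tested code. Seventeen class
templates (11 Eurasian-style, 6 North American-style, one flagged as the
wild-grapevine reference) are built deterministically from a parametric pip
silhouette — an egg-like body with a beak-like apical extension — measured
into normalized 20-harmonic descriptors. Specimens are template mean plus
independent Gaussian noise per coefficient (harmonic-`h` dispersion
`sd_base / sqrt(h)`, `sd_base` defaulting to 1% of the semi-major axis, a
plausible within-accession scale), reconstructed as 360-point outlines,
scaled to a physical seed size (~6 mm long at 3 mm semi-major scale),
randomly rotated, rasterized at 600 dpi and written as PNG silhouettes with
the same manifest schema the imaging stage ingests — so cohorts exercise
the whole pipeline, not just the math core.

Two design points deserve emphasis:

* **Dispersion lives in the feature harmonics (1–6).** Reconstructing a
  Fourier series at uniform parameter values and re-measuring it under
  arc-length parameterization is not the identity map; it mixes
  coefficient noise across harmonics (a speed perturbation of order
  `2*pi*h*sigma_h` shifts the parameterization and hence every measured
  harmonic). Noise placed beyond the measured feature space would leak into
  it and inflate within-class variance beyond the generator's nominal
  model. Restricting dispersion to harmonics 1–6 keeps the generated class
  structure expressible in the analysis's own coordinates. Higher harmonics
  still differ *between* classes — fine apical detail is class-specific —
  they just do not vary within a class.
* **Separation is calibrated on realized, not nominal, distances.** Even
  within the feature harmonics the re-measurement map compresses the
  gap-to-noise ratio severalfold. `template_separation()` reports the
  nominal Mahalanobis distance of the generative model;
  `realized_separation()` estimates the distance the classifier actually
  experiences by Monte Carlo through reconstruction and re-measurement.
  Realized distance scales linearly in the separation multiplier, so a
  target minimum separation is met by a single multiplicative calibration,
  and a property test confirms an independently drawn cohort lands within
  10% of the requested separation.

The **fossil distortion** model emulates the deformation of mummified
seeds: multiplicative amplitude jitter on harmonics 2–3 (standard deviation
`0.05 * d`) plus smoothed Gaussian displacement along the outline normal
(`0.02 * d` mm), for intensity `d`. It raises within-class variance
monotonically in `d` and flattens posteriors, which is exactly the failure
mode reported for heavily distorted fossil material.

`cascade_fixture()` assembles the full study shape: 18 reference classes
(the 17 templates plus an eastern ecotype variant of the wild-grapevine
class, offset by roughly a third of a species-level difference) at 30
specimens each — 540 reference seeds — plus 70 unknowns drawn from the
wild-grapevine template with distortion, split into two "assemblages" of 60
and 10. Its six analyses are data-driven configurations over one engine:
an ordination of the two unknown assemblages, Eurasian vs North American
discrimination, 11 Eurasian species, the 5-species subset, the 0.90
threshold allocation, and the western/eastern ecotype comparison. The
fixture calibrates its separation multiplier so the unknowns' source class
sits at least 4 realized Mahalanobis units from its nearest five-species
neighbour.

```{r cascade, eval = FALSE}
fx <- cascade_fixture(seed = 42)
fx$runs$eurasian5_lda
glance(fx$runs$threshold_allocation$threshold)
autoplot(fx$runs$eurasian5_lda$cv)
```

## What passing tests do and do not show

The generator produces smooth, simply connected, one-seed-per-image
silhouettes with Gaussian class structure in descriptor space. Passing the
suite therefore demonstrates that the chain measures, normalizes and
classifies such shapes correctly and reproducibly — it does not certify
performance on real scans, where lighting gradients, touching seeds, broken
beaks, ventral-view confusion or non-Gaussian within-accession variation
can all intrude. No taphonomic model stands behind the fossil distortion
beyond low-frequency warping and boundary roughening; real compression
damage is richer. Dorsal views only; no multi-view fusion.

## Numerical choices, in one place

* Iso-contour level 0.5; components under 1% of the largest discarded;
  holes filled; minimum 50 foreground pixels.
* 360 outline points; 20 harmonics computed, 6 retained (24 features);
  harmonic-power reference total 20 harmonics.
* Normalization: `a1 = 1`, `b1 = c1 = 0`, `d1 > 0`; flip disambiguation by
  x-skewness with lexicographic fallback; near-circular threshold at axis
  ratio 0.99 with harmonic-2 anchoring.
* Stepwise 3.84 / 2.71; PCA retention 0.99; equal priors; ridge
  `1e-8 * trace/dim`; posterior threshold 0.90 inclusive; ties to the first
  group; reports rounded to one decimal, half away from zero.
* Fixture sizes: 18 classes x 30 reference specimens, 70 unknowns, 600 dpi,
  minimum realized neighbour separation 4. These defaults are the
  conditions under which the package's own acceptance checks run; the test
  suite's lighter orchestration checks use 12 specimens per class without
  rasterization.

## Known limitations

* The arc-length re-measurement map means generative coefficients and
  measured features differ by a fixed linear mixing; the package calibrates
  separations through the map rather than inverting it (the inverse
  fixed-point iteration is not a contraction for noisy draws).
* Stepwise inference is descriptive, not inferential: partial-F thresholds
  are conventions, and no selection-aware p-values are produced.
* The ridge fallback changes the model slightly when triggered; it is
  logged, and fits that remain singular fail loudly rather than silently.
* Quadratic or regularized discriminants beyond the ridge are out of scope,
  as are landmark methods and Procrustes superimposition.
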