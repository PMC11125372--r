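# pipmorph

Outline morphometrics and discriminant classification of grape pip
(*Vitis* seed) silhouettes.

Seed image analysis is the standard tool for assigning grape pips of
unknown affinity — archaeological or fossil material — to modern reference
species. A scanned dorsal silhouette is reduced to a closed outline, the
outline to a fixed-length shape descriptor, and the descriptor is
classified against a reference collection. `pipmorph` implements the whole
chain in R:

1. **Imaging** — threshold a scan (Otsu or fixed cutoff), keep the largest
   connected component, fill holes, trace the sub-pixel boundary, convert
   to millimetres, and resample to 360 points equidistant along the
   curvilinear abscissa.
2. **Descriptors** — elliptic Fourier coefficients of the closed outline
   from the chord-length parameterization,

   $$x(t) = a_0 + \sum_n a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},$$

   and likewise $y(t)$ with $c_n, d_n$; normalization for size, rotation,
   position and starting point via the first-harmonic ellipse; truncation
   to the first six harmonics — 24 coefficients per outline, a rank that
   captures over 95% of the total harmonic power on seed-like shapes.
3. **Classification** — PCA of the coefficients; stepwise linear
   discriminant analysis on the uncorrelated component scores (Wilks'
   lambda, F-to-enter 3.84 / F-to-remove 2.71); leave-one-out
   cross-validated confusion matrices; posterior allocation of an
   "unknown" group, optionally under a minimum-posterior threshold
   (p >= 0.90) below which specimens are left unassigned.
4. **Synthetic cohorts** — a deterministic generator of seed-like shape
   classes (pyriform body, beak-like apex; Eurasian-style vs North
   American-style geometry) with controlled between-class separation,
   within-class dispersion and a fossil-distortion model, rasterized to
   PNG silhouettes so the full pipeline is testable without proprietary
   seed images.

Everything is data-frame in, tibble out, and composes with the pipe;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Quick example

```r
library(pipmorph)

dir <- tempfile("pips")
coh <- sample_cohort(dir, classes = c("sylvestris_like", "riparia_like"),
                     n_per_class = 10, seed = 1)

feats <- outline_cohort(coh$manifest) |>       # PNG -> outlines (mm)
  efd(n_harmonics = 20) |>                     # elliptic Fourier transform
  efd_normalize() |>                           # pose/start standardization
  efd_features(k_harmonics = 6)                # 24 coefficients
feats$group <- coh$manifest$group[match(feats$specimen_id,
                                        coh$manifest$specimen_id)]

loocv_classify(feats)
#> <pip_cv> 20 specimens, 2 groups
#>   100.0% of cross-validated grouped cases correctly classified
```

A wild-grapevine-like class and a North American-style class are far apart
in shape space, so a 20-seed cohort cross-validates perfectly; the
interesting behaviour appears between close Eurasian classes, below.

## The full cascade on a synthetic study

`cascade_fixture()` builds a complete study: 540 reference seeds (17 class
templates plus an eastern ecotype variant of the wild-grapevine class, 30
seeds each), 70 distorted unknowns split into two "assemblages", all
written as 600 dpi silhouettes and re-ingested through the imaging chain,
then pushed through six analyses:

```r
fx <- cascade_fixture(seed = 42)
for (r in fx$runs) print(r)
#> <pip_run> assemblage_pca
#>   assemblage centroid distance 0.002 vs pooled within-SD 0.026
#> <pip_run> continental_lda
#>   95.0% of cross-validated grouped cases correctly classified (n = 540)
#>   unknown plurality: eurasian (100.0%)
#> <pip_run> eurasian11_lda
#>   92.2% of cross-validated grouped cases correctly classified (n = 360)
#>   unknown plurality: sylvestris_like (67.1%)
#> <pip_run> eurasian5_lda
#>   90.6% of cross-validated grouped cases correctly classified (n = 180)
#>   unknown plurality: sylvestris_like (87.1%)
#> <pip_run> threshold_allocation
#>   90.6% of cross-validated grouped cases correctly classified (n = 180)
#>   threshold p >= 0.90: 34.3% unassigned
#> <pip_run> ecotype_lda
#>   90.0% of cross-validated grouped cases correctly classified (n = 60)
#>   unknown plurality: western_sylvestris (84.3%)
```

Reading the output: the two unknown assemblages overlap in the ordination
(their centroid distance is far below the within-assemblage spread), the
unknowns are allocated overwhelmingly to the Eurasian super-group, within
Eurasia to the wild-grapevine-like class they were generated from, and
under the 0.90 posterior threshold about a third of the distorted unknowns
are too ambiguous to assign — the signature of degraded material.
`write_reports()` exports every table as CSV plus aligned text with the
cross-validated percentage as a footnote, byte-identically across reruns
of the same seed and configuration.

## Package layout

| Area | Functions |
| --- | --- |
| Imaging | `read_silhouette()`, `binarize()`, `extract_outline()`, `resample_outline()`, `outline_cohort()`, `read_manifest()`, `write_outlines()` |
| Descriptors | `efd()`, `efd_normalize()`, `harmonic_power()`, `efd_features()`, `efd_reconstruct()`, `write_features()` |
| Statistics | `pip_pca()`, `stepwise_select()`, `pip_lda()`, `loocv_classify()`, `classify_unknown()`, `threshold_allocate()` |
| Synthesis | `seed_templates()`, `sample_outlines()`, `sample_cohort()`, `template_separation()`, `realized_separation()` |
| Orchestration | `analysis_config()`, `run_analysis()`, `cascade_fixture()`, `write_reports()` |

The methods vignette (`vignettes/pipmorph-methods.Rmd`) documents the
model, the normalization conventions, every tunable with its default and
rationale, the generator's design, and known limitations.
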