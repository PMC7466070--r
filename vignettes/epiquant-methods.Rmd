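---
title: "Quantifying dysplasia in regenerated epidermis: methods and design"
author: "epiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dysplasia in regenerated epidermis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

## What the package measures

Regenerated human epidermis (e.g. in skin-substitute xenografts) can develop
local dysplastic areas: regions where the basal and spinous layers are
disorganized, the dermo-epidermal junction (JDE) is altered, basal
keratinocytes lose their normal polarity, and cell-cell cohesion fails,
leaving expanded intercellular spaces. `epiquant` implements the
quantitative-histology and semi-quantitative immunofluorescence readouts used
to characterize such dysplasia on 2-D section images:

1. **Basal keratinocyte polarity.** Healthy basal nuclei are elongated
   perpendicular to the JDE. Each segmented basal nucleus contributes the
   acute angle between its equivalent-ellipse major axis and the local JDE
   tangent, folded into [0, 90] degrees (90 = perpendicular). Angles are
   binned into 18 five-degree categories and classified as nearly parallel
   [0, 30), oblique [30, 60) or nearly perpendicular [60, 90].
2. **Cell-cell cohesion.** Expanded intercellular spaces inside the epidermis
   are pixels at or below a background-derived intensity threshold; their
   area, normalized per epidermis area (`100 * space_px / epidermis_px`),
   gives a semi-quantitative score in arbitrary units.
3. **Marker quantification.** Basal-layer markers (VANGL2-like) are summed
   within a basal-band mask and normalized by the DAPI sum over the same mask;
   epidermis-wide markers (E-cadherin-, alpha-SMA-like) are summed without
   normalization by default. Nuclear markers (ZEB1-like) are counted per cell
   against a negative-control-derived positivity threshold.
4. **Morphometry and statistics.** Abnormal-interval annotations give the
   percentage of section length that is dysplastic; xenografts are classified
   against a 12% threshold (boundary inclusive); cohorts are compared with a
   two-sided Mann-Whitney U test.

Every stage can be exercised on a synthetic section generator with exact
ground truth, so all quantitative claims in the test suite are recoveries of
known inputs rather than comparisons against inaccessible slides.

## Coordinate conventions

Rasters are R matrices indexed `[row, col]` = `(y, x)`, 1-based, origin at the
top-left, y increasing downward. The section axis runs along the columns and
the epidermis lies above the dermis; `auto_orient()` brings arbitrary
90/180-degree-rotated inputs into this frame (long axis horizontal, brightest
tissue class on top). Nucleus axis angles are measured from the +x axis in
[0, 180) in this y-down frame; JDE-relative angles are always folded into
[0, 90] because nucleus axes are undirected.

## The synthetic section generator

`generate_section()` renders, deterministically for a given seed:

- a sinusoidal JDE (amplitude 10 um, wavelength 300 um by default) with the
  epidermis (80 um thick) above and a sparse dermis below;
- a basal layer of elliptical nuclei (10 x 4 um at axis ratio 2.5), one per
  ~5.5 um of junction length (about 145 per 800 um — a fixture choice, not a
  literature value), at alternating depths of 6 and 10 um above the JDE so
  neighbours rarely touch. Their major axes deviate from the local JDE normal
  by a wrapped-normal angle with SD `1/sqrt(polarity_concentration)` radians;
  concentration 0 means uniform orientations on [0, 90]. The folded analytic
  distribution (class masses, median) is available in closed form via
  `polarity_analytic()`, which recovery tests compare against;
- suprabasal nucleus rows (8 x 5 um, roughly surface-parallel) and sparse
  dermal nuclei (uniform orientation);
- dark elliptical intercellular gaps rejection-placed inside the epidermis
  until a target area fraction is met. Gaps are kept 3 um clear of the
  epidermal surface (a compact, horny-layer-like margin) because they are
  intercellular spaces, interior to the tissue; they may swallow suprabasal
  nuclei — which are then removed, mimicking acantholytic cell loss — but
  never basal nuclei, whose angles are the polarity ground truth. Realized
  fractions are recorded per region and globally;
- a DAPI-like nuclear channel, optional marker channels (per-compartment
  intensities, per-compartment nuclear positivity fractions, Gaussian noise),
  and an HES-like RGB composite that is a deterministic colour mapping of
  compartments (background and gaps dark; epidermis brighter than dermis;
  nuclei dark purple) — not a physical stain model, which downstream grayscale
  analysis does not need.

Inside declared abnormal intervals the basal orientation distribution is
uniform on [0, 90], the gap fraction is raised to `target_gap_fraction`
(elsewhere `normal_gap_fraction`, default 0.02), marker intensities are scaled
by `abnormal_scale`, and nuclear positivity fractions switch to
`abnormal_positive_fraction`. Channels are quantized to the 16-bit grid at
generation time so TIFF round trips are lossless. One RNG sub-stream drives
geometry and another each marker, so adding or editing markers never moves
nuclei or gaps.

**What the generator does not emulate:** staining physics and chromatic
variability, scanner artefacts and illumination gradients, nuclear texture,
3-D sectioning effects, and real dysplastic morphology beyond its three dials
(orientation disorder, gap fraction, marker changes). Passing recovery tests
therefore demonstrate that the measurement pipeline is correct and unbiased
under controlled conditions, not that it is robust to every real-slide
artefact.

## Measurement pipeline choices

- **Background threshold** (`background_threshold()`): `mean + k * SD` over
  user-supplied tissue-free rectangles, `k = 3` by default; monotone in `k`.
- **Epidermis/dermis split** (`segment_compartments()`): tissue = pixels above
  the background threshold, largest connected component; tissue intensities
  are clustered (k-means, 3 classes seeded at fixed quantiles) and the
  brightest class seeds the epidermis. Because the epidermis is a band, its
  mask is filled per column between the top and bottom envelopes of the
  bright class; envelopes are made robust to gaps lying on the junction or
  under the surface by a 31-column running median. Filled pixels above the
  epidermal surface are background, not dermis. With ground-truth labels
  (synthetic mode) the split is exact.
- **JDE polyline** (`extract_jde()`): per column, the deepest epidermis pixel
  8-adjacent to the dermis; gaps of up to 5 sampled columns are interpolated,
  larger ones split the polyline into segments.
- **Local tangent**: the PCA principal direction of a +/-10-vertex window
  around the nearest polyline vertex. A one-vertex central difference on a
  pixel staircase carries ~10 degrees of quantization noise; the windowed PCA
  axis suppresses it and is exactly equivariant under rigid rotation
  (vertical tangents included), unlike a y-on-x regression slope. The window
  is exposed (`tangent_window`).
- **Nucleus segmentation** (`segment_nuclei()`): Otsu threshold, Euclidean
  distance transform, watershed with tolerance 0.5 (splits most abutting
  nuclei without fragmenting single elongated ones), moments per label.
  Objects outside `[min_area_px, max_area_px]` are discarded; the upper bound
  (disabled by default) is standard morphometry QC for unresolved doublets,
  whose pooled orientation is meaningless — analyses in this package's tests
  use 50 um^2 (200 px at 0.5 um/px), about 1.6x a single nucleus.
  Near-circular nuclei (eccentricity < 0.05) keep their angle but are flagged
  low-confidence and included by default.
- **Positive-cell calling**: per-nucleus intensity is the **median over the
  1-px-eroded interior of the label** rather than the mean. Watershed
  boundaries between touching nuclei can misassign a sizeable minority of a
  bright neighbour's pixels; a mean-based call then inflates false positives
  severalfold at realistic crowding, while the median is unaffected by any
  sub-majority spill. The mean remains available (`stat = "mean"`). The
  threshold is `mean + 3 SD` of per-nucleus intensities in a negative-control
  compartment, mirroring no-primary-antibody controls.
- **Cohesion scores**: the small-object filter (default 20 px) is applied
  once to the whole-epidermis space mask before per-region counting, so
  per-region `space_px` sums exactly to the whole-section value (additivity
  is asserted in tests). Scores are per-area-normalized so sections of
  different lengths are comparable; absolute arbitrary-unit scales from other
  studies are not reproducible, only contrasts and recoveries are tested.
- **Mann-Whitney U** (`mann_whitney_u()`): midranks for ties; exact p by the
  classic counting recurrence over the U null distribution when both n <= 8
  and the data are tie-free, otherwise a normal approximation with tie and
  continuity corrections (the behaviour of common statistics software). The
  approximation carries an absolute error of order 1e-3 at n ~ 25-30, which
  the test suite accounts for explicitly when comparing against permutation
  oracles. Degenerate inputs (all values identical) return p = 1 with a flag.
- **Xenograft classification** (`classify_xenograft()`): the per-xenograft
  summary over its sections is the mean by default (max available via
  `summary_fun`), and the threshold comparison is boundary-inclusive ("at
  least 12%"). Cohort comparisons pool per-region values by default, as
  cumulated dot plots do; a per-xenograft aggregation (`pool = "xenograft"`)
  avoids pseudo-replication when desired.

## Open choices resolved here

- The three polarity classes are a partition at 30 and 60 degrees, with 30
  assigned to oblique and 60 to nearly-perpendicular (half-open convention,
  top bin closed so 90 is countable); the boundaries are exposed.
- The basal-band width (how the basal-layer mask is drawn) defaults to 15 um
  and is a parameter, not a literature value.
- Whether epidermis-wide marker levels are DAPI-normalized is switchable;
  the default is unnormalized, with normalization reserved for basal-band
  levels.
- Automated positivity calling is a surrogate for manual counting; its
  threshold rule and statistic are both exposed.

## Problem sizes in the test suite

Recovery tests use sections of 800-1100 x 260 um at 0.5 um/px (roughly
150-200 basal nuclei per section); cohort calibration uses pools of 60 + 30
sections of 400 x 220 um, each generated and measured through the full
pipeline exactly once, from which replicate 10-vs-10 cohorts are resampled.
The whole suite runs in a few minutes on one CPU.

## Known limitations

- Per-nucleus angles from *re-segmentation* of a mirrored/rotated raster can
  differ by a few degrees for touching nuclei, because watershed tie-breaking
  is not mirror-equivariant; the angle measurement itself
  (`angle_to_jde()`) is rotation-invariant to well under a degree, and class
  fractions are stable to under one point.
- The epidermis envelope model assumes one epidermal band per column; it is
  not meant for sections with folds, tangential cuts, or detached fragments.
- The intensity-based epidermis/dermis split assumes the epidermis is the
  brightest tissue class, true of the synthetic composite and typical
  HES-like stains after the canonical orientation, but any staining scheme
  violating it requires the ground-truth-label path or a custom mask.
- Absolute arbitrary-unit scales (cohesion a.u., marker a.u.) are
  experiment-internal; only contrasts, ratios and recoveries are meaningful.
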