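# epiquant

Quantitative histomorphometry of regenerated epidermis from 2-D section
images. The package targets studies of epidermal regeneration (e.g.
keratinocyte-derived skin substitutes xenografted in vivo) where local
**dysplastic areas** must be detected and scored: disorganized basal/spinous
layers, loss of basal keratinocyte polarity, non-cohesive (expanded
intercellular) spaces, and epithelial-to-mesenchymal-transition-like marker
changes (reduced VANGL2 and E-cadherin, ectopic ZEB1 and alpha-SMA).

## What it computes

For a section image with a nuclear (DAPI) channel, optional marker channels
and an HES-like brightfield composite:

- **Basal keratinocyte polarity.** Nuclei are segmented
  (Otsu + watershed), each basal nucleus contributes the acute angle `theta`
  in `[0, 90]` between its equivalent-ellipse major axis and the local
  tangent of the dermo-epidermal junction (JDE); angles are binned into 18
  five-degree categories and classified as nearly parallel `[0, 30)`,
  oblique `[30, 60)` or nearly perpendicular `[60, 90]`.
- **Non-cohesive spaces.** Epidermis pixels at or below a threshold derived
  from tissue-free areas (`mean + 3 SD`) form the space mask; the score is
  `100 * space_px / epidermis_px` (a.u.).
- **Marker levels and positive cells.** Basal-band marker levels normalized
  by DAPI (`level = sum(marker) / sum(DAPI)` over the same mask),
  epidermis-wide levels, and per-nucleus positive-cell percentages against a
  negative-control-derived threshold.
- **Morphometry & statistics.** Percent of section length annotated
  abnormal (overlaps merged), xenograft classification against a 12%
  threshold (boundary inclusive), and two-sided Mann-Whitney U tests
  (exact by enumeration for small tie-free samples, tie- and
  continuity-corrected normal approximation otherwise) with significance
  stars at 0.05 / 0.01 / 0.0001.

A synthetic skin-section generator (`generate_section()`) renders sections
with a sinusoidal JDE, controllable basal-nucleus orientation concentration,
gap fraction, marker intensities and positivity fractions — plus exact ground
truth — so the entire pipeline is testable without real slides.

## Worked example

Generate a section whose interval 500-700 um is dysplastic (uniform nuclear
orientations, 12% gap fraction vs 2% elsewhere), then measure it:

```r
library(epiquant)

spec <- section_spec(seed = 42, abnormal_intervals_um = list(c(500, 700)),
                     target_gap_fraction = 0.12, normal_gap_fraction = 0.02)
g   <- generate_section(spec)
sec <- g$section

gray  <- grayscale(hes_rgb(sec))
thr   <- background_threshold(gray, list(c(1, 150, 1, 25)))  # tissue-free box
masks <- segment_compartments(sec, threshold = thr)
jde   <- extract_jde(masks$epidermis, masks$dermis)
band  <- basal_band(masks$epidermis, jde, band_width_um = 15,
                    pixel_size_um = 0.5)
masks <- compartment_masks(masks$epidermis, masks$dermis, masks$background,
                           basal_band = band)

prof <- polarity_profile(sec, jde, masks,
                         roi_intervals_um = list(c(0, 500), c(500, 700)),
                         max_area_px = 200)
prof$summary
#>   roi start_um end_um  n median_angle_deg nearly_parallel oblique nearly_perpendicular
#> 1   1        0    500 93             74.6          0.0215   0.161                0.817
#> 2   2      500    700 37             49.2          0.3514   0.324                0.324

cohesion_by_region(gray, masks$epidermis, list(c(0, 500), c(500, 700)),
                   thr, pixel_size_um = 0.5)[, c("region", "score_au")]
#>   region score_au
#> 1      1     1.98
#> 2      2    11.94

mann_whitney_u(c(2.1, 3.4, 2.8, 3.0), c(8.5, 7.2, 9.1, 6.4))
#> Mann-Whitney U: U = 0 (n1 = 4, n2 = 4), p = 0.02857 [two.sided, exact]
```

Reading the output: the normal region (ROI 1) is strongly polarized — median
angle 74.6 degrees, 82% of basal nuclei nearly perpendicular to the junction
— and cohesive (score 2.0 a.u.), while the dysplastic interval (ROI 2) has
lost polarity (median 49.2 degrees, classes near the uniform 1/3 split) and
shows a six-fold higher non-cohesive-space score (11.9 a.u., tracking its 12%
generated gap fraction).

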