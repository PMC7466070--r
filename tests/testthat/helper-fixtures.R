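# Shared fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default perpendicular-polarity section (800 um, ~145 basal nuclei)
fx_default <- function() cached("default", function() generate_section(section_spec(seed = 42)))

# section with ZEB1-like and VANGL2-like markers and one dysplastic interval
fx_markers <- function() cached("markers", function() {
  zeb <- marker_spec("zeb1", "nuclear",
    compartment_intensity = c(basal = 0.7, suprabasal = 0.7, dermis = 0.75,
                              background = 0.05),
    positive_fraction = c(basal = 0.03, suprabasal = 0.03, dermis = 0.8),
    abnormal_positive_fraction = c(basal = 0.18, suprabasal = 0.18, dermis = 0.8),
    noise_sd = 0.02)
  vangl <- marker_spec("vangl2", "membrane",
    compartment_intensity = c(basal = 0.6, suprabasal = 0.15, dermis = 0.05,
                              gap = 0.02, background = 0.02),
    abnormal_scale = 0.5, noise_sd = 0.02)
  generate_section(section_spec(seed = 5, marker_specs = list(zeb, vangl),
                                abnormal_intervals_um = list(c(250, 550))))
})

# run the measurement pipeline up to compartment masks + JDE + basal band
run_masks <- function(section, band_width_um = 15) {
  gray <- grayscale(hes_rgb(section))
  thr <- background_threshold(gray, list(c(1, 150, 1, 25)))
  m <- segment_compartments(section, threshold = thr)
  jde <- extract_jde(m$epidermis, m$dermis)
  band <- basal_band(m$epidermis, jde, band_width_um, section$pixel_size_um)
  list(masks = compartment_masks(m$epidermis, m$dermis, m$background,
                                 basal_band = band),
       jde = jde, gray = gray, threshold = thr)
}

# measured basal nucleus records with JDE-relative angles; nuclei are
# size-gated on both sides (40..200 px at 0.5 um/px, i.e. 10..50 um^2) so
# debris and unresolved doublets do not contribute orientations
run_basal_angles <- function(section, pl = run_masks(section)) {
  nuc <- segment_nuclei(section$channels$dapi, masks = pl$masks,
                        max_area_px = 200 * (0.5 / section$pixel_size_um)^2)
  nuc$angle <- angle_to_jde(nuc, pl$jde)
  nuc[!is.na(nuc$compartment) & nuc$compartment == "basal", , drop = FALSE]
}

fx_pipeline_default <- function() cached("pipeline_default", function() {
  g <- fx_default()
  pl <- run_masks(g$section)
  list(g = g, pl = pl, basal = run_basal_angles(g$section, pl))
})

# per-section metrics (median basal angle, cohesion score) for cohort studies
section_metrics <- function(seed, concentration, gap_fraction) {
  g <- generate_section(section_spec(width_px = 800, height_px = 440, seed = seed,
                                     polarity_concentration = concentration,
                                     target_gap_fraction = gap_fraction))
  pl <- run_masks(g$section)
  basal <- run_basal_angles(g$section, pl)
  coh <- space_mask(pl$gray, pl$masks$epidermis, pl$threshold)
  c(median_angle = stats::median(basal$angle), cohesion = coh$score_au)
}

# pools of identically parameterized sections, one pipeline run per section
fx_cohort_pools <- function() cached("cohort_pools", function() {
  ctl <- t(vapply(1:60, function(s) section_metrics(1000 + s, 8, 0.02),
                  numeric(2)))
  dys <- t(vapply(1:30, function(s) section_metrics(2000 + s, 0, 0.12),
                  numeric(2)))
  list(control = ctl, dysplastic = dys)
})
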