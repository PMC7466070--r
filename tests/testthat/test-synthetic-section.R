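test_that("spec validation names the offending field", {
  expect_error(section_spec(width_px = -5), "width_px")
  expect_error(section_spec(target_gap_fraction = 1.2), "target_gap_fraction")
  expect_error(section_spec(jde_wavelength_um = 0), "jde_wavelength_um")
  expect_error(section_spec(abnormal_intervals_um = list(c(100, 50))),
               "abnormal_intervals_um")
  expect_error(section_spec(abnormal_intervals_um = list(c(0, 1e6))),
               "abnormal_intervals_um")
  expect_error(marker_spec("m", "nuclear", c(basal = 1.5)),
               "compartment_intensity")
})

test_that("generation is bit-identical for a fixed seed and geometry is stable under marker changes", {
  sp <- section_spec(width_px = 400, height_px = 300, seed = 9)
  g1 <- generate_section(sp)
  g2 <- generate_section(sp)
  expect_identical(g1$section$channels, g2$section$channels)
  expect_identical(g1$truth$nuclei, g2$truth$nuclei)
  expect_identical(g1$truth$gap_mask, g2$truth$gap_mask)
  # adding a marker must not move nuclei or gaps
  sp2 <- section_spec(width_px = 400, height_px = 300, seed = 9,
                      marker_specs = list(marker_spec("m", "nuclear",
                        c(basal = 0.7, background = 0.05),
                        positive_fraction = c(basal = 0.2))))
  g3 <- generate_section(sp2)
  expect_identical(g1$truth$nuclei$x_px, g3$truth$nuclei$x_px)
  expect_identical(g1$truth$gap_mask, g3$truth$gap_mask)
  expect_identical(g1$section$channels$dapi, g3$section$channels$dapi)
})

test_that("ground-truth angles live in [0, 90] and match the analytic distribution", {
  g <- fx_default() # polarity_concentration 8
  ang <- g$truth$nuclei$angle_jde_true_deg
  expect_true(all(ang >= 0 & ang <= 90))
  ba <- ang[g$truth$nuclei$compartment == "basal"]
  an <- polarity_analytic(8)
  p <- an$class_mass[["nearly_perpendicular"]]
  expect_gt(p, 0.8) # a concentrated spec is perpendicular-dominant
  # realized perpendicular share within the binomial 95% CI of the analytic mass
  half <- 1.96 * sqrt(p * (1 - p) / length(ba))
  expect_lt(abs(mean(ba >= 60) - p), half + 1e-12)
})

test_that("zero concentration gives uniform angles over the 18 bins", {
  g <- generate_section(section_spec(width_px = 3000, height_px = 300,
                                     epidermis_thickness_um = 40,
                                     polarity_concentration = 0, seed = 3))
  ba <- g$truth$nuclei$angle_jde_true_deg[g$truth$nuclei$compartment == "basal"]
  expect_gt(length(ba), 200)
  h <- bin_angles(ba)
  gof <- suppressWarnings(stats::chisq.test(h$counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("realized gap fraction tracks the target on a large epidermis", {
  for (tg in c(0.05, 0.15)) {
    g <- generate_section(section_spec(seed = 20 + round(100 * tg),
                                       target_gap_fraction = tg))
    epi_px <- sum(g$truth$compartments %in% 1:2) + sum(g$truth$compartments == 4)
    expect_gte(epi_px, 1e5)
    expect_lt(abs(g$truth$gap_fraction$global - tg), 0.02)
  }
})

test_that("abnormal intervals switch orientation to uniform and raise the gap fraction", {
  g <- generate_section(section_spec(seed = 13, target_gap_fraction = 0.15,
                                     normal_gap_fraction = 0.02,
                                     abnormal_intervals_um = list(c(200, 600))))
  nu <- g$truth$nuclei
  abn <- nu$x_um >= 200 & nu$x_um < 600 & nu$compartment == "basal"
  nrm <- !(nu$x_um >= 200 & nu$x_um < 600) & nu$compartment == "basal"
  # normal zone perpendicular-dominant, abnormal zone not
  expect_gt(mean(nu$angle_jde_true_deg[nrm] >= 60), 0.75)
  expect_lt(mean(nu$angle_jde_true_deg[abn] >= 60), 0.55)
  tab <- g$truth$gap_fraction$by_region
  expect_lt(abs(tab$realized[tab$region == "abnormal"] - 0.15), 0.02)
  expect_lt(abs(tab$realized[tab$region == "normal"] - 0.02), 0.01)
})

test_that("fixtures round-trip losslessly and regenerate from the manifest", {
  g <- generate_section(section_spec(width_px = 300, height_px = 320, seed = 77))
  d <- withr::local_tempdir()
  manifest <- write_fixture(g$section, g$truth, d)
  expect_true(all(c("manifest.json", "truth.json") %in% list.files(d)))
  back <- read_fixture(d)
  expect_equal(back$section$channels, g$section$channels, tolerance = 0)
  expect_identical(back$truth$compartments, g$truth$compartments)
  expect_identical(back$truth$gap_mask, g$truth$gap_mask)
  regen <- generate_section(epiquant:::spec_from_list(back$manifest$spec))
  expect_equal(regen$truth$nuclei$angle_jde_true_deg,
               g$truth$nuclei$angle_jde_true_deg)
  expect_error(write_fixture(g$section, g$truth, file.path(d, "nope", "deep")),
               "nope")
})
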