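# draw ellipses directly on a raster (independent of the section generator)
draw_ellipses <- function(H, W, df, intensity = 0.85, bg = 0.02, noise_sd = 0.02,
                          seed = 1) {
  m <- matrix(bg, H, W)
  for (i in seq_len(nrow(df)))
    m[epiquant:::ellipse_pixels(df$x[i], df$y[i], df$a[i], df$b[i], df$theta[i],
                                H, W)] <- intensity
  set.seed(seed)
  pmin(pmax(m + rnorm(length(m), 0, noise_sd), 0), 1)
}

test_that("nucleus segmentation recovers non-touching nuclei with high precision and recall", {
  set.seed(4)
  # 200 ellipses on a coarse grid, jittered, guaranteed non-touching
  grid <- expand.grid(gx = seq(25, 975, by = 50), gy = seq(25, 475, by = 50))
  grid <- grid[sample(nrow(grid), 200), ]
  df <- data.frame(x = grid$gx + runif(200, -8, 8), y = grid$gy + runif(200, -8, 8),
                   a = 10, b = 4, theta = runif(200, 0, 180))
  img <- draw_ellipses(500, 1000, df)
  nuc <- segment_nuclei(img, min_area_px = 40)
  d2 <- outer(nuc$x, df$x, "-")^2 + outer(nuc$y, df$y, "-")^2
  matched_truth <- apply(d2, 2, min) <= 25 # match radius 5 px
  matched_det <- apply(d2, 1, min) <= 25
  expect_gte(mean(matched_truth), 0.95) # recall
  expect_gte(mean(matched_det), 0.95)   # precision
})

test_that("moment orientation of a single ellipse is accurate to 2 degrees", {
  for (deg in c(30, 75, 120)) {
    img <- draw_ellipses(200, 200, data.frame(x = 100, y = 100, a = 30, b = 10,
                                              theta = deg), noise_sd = 0)
    nuc <- segment_nuclei(img, min_area_px = 40)
    expect_equal(nrow(nuc), 1)
    d <- epiquant:::fold_angle(nuc$major_axis_angle_deg - deg)
    expect_lt(d, 2) # undirected axis difference, folded into [0, 90]
  }
})

test_that("blank and degenerate rasters yield empty record sets, not errors", {
  expect_equal(nrow(segment_nuclei(matrix(0, 50, 50))), 0)
  expect_equal(nrow(segment_nuclei(matrix(0.5, 50, 50))), 0)
})

test_that("angle to the JDE folds the axis difference into [0, 90]", {
  flat <- data.frame(x = 1:200, y = rep(100, 200), segment = 1L)
  rec <- function(axis) data.frame(x = 100, y = 90, major_axis_angle_deg = axis)
  expect_equal(angle_to_jde(rec(90), flat), 90)
  expect_equal(angle_to_jde(rec(0), flat), 0)
  expect_equal(angle_to_jde(rec(120), flat), 60)
  expect_error(angle_to_jde(rec(10), data.frame(x = 1, y = 1)), "2 points")
})

test_that("angle measurement is invariant under rigid rotation of image and polyline", {
  fp <- fx_pipeline_default()
  nuc <- fp$basal; jde <- fp$pl$jde
  a0 <- angle_to_jde(nuc, jde)
  H <- nrow(fp$pl$masks$epidermis); W <- ncol(fp$pl$masks$epidermis)
  # 90 degrees clockwise: (x, y) -> (H + 1 - y, x), axis -> axis + 90
  n90 <- nuc; n90$x <- H + 1 - nuc$y; n90$y <- nuc$x
  n90$major_axis_angle_deg <- (nuc$major_axis_angle_deg + 90) %% 180
  j90 <- data.frame(x = H + 1 - jde$y, y = jde$x, segment = jde$segment)
  expect_lt(max(abs(angle_to_jde(n90, j90) - a0)), 1)
  # 180 degrees: (x, y) -> (W + 1 - x, H + 1 - y), axis unchanged
  n180 <- nuc; n180$x <- W + 1 - nuc$x; n180$y <- H + 1 - nuc$y
  j180 <- data.frame(x = rev(W + 1 - jde$x), y = rev(H + 1 - jde$y),
                     segment = rev(jde$segment))
  expect_lt(max(abs(angle_to_jde(n180, j180) - a0)), 1)
})

test_that("angle histogram uses 18 half-open bins with a closed top bin", {
  expect_equal(bin_angles(0)$counts[1], 1)
  expect_equal(bin_angles(90)$counts[18], 1)
  expect_equal(bin_angles(c(5, 4.999))$counts[1:2], c(1, 1))
  expect_error(bin_angles(c(10, 91)), "\\[0, 90\\]")
  set.seed(8)
  u <- runif(1000, 0, 90)
  h <- bin_angles(u)
  expect_equal(sum(h$counts), 1000)
  # each bin within the binomial 99% CI around 1000/18
  half <- 2.576 * sqrt(1000 * (1 / 18) * (17 / 18))
  expect_true(all(abs(h$counts - 1000 / 18) <= half))
})

test_that("polarity classes partition [0, 90] at 30 and 60 degrees", {
  expect_equal(as.character(classify_polarity(75)), "nearly_perpendicular")
  expect_equal(as.character(classify_polarity(10)), "nearly_parallel")
  expect_equal(as.character(classify_polarity(45)), "oblique")
  expect_equal(as.character(classify_polarity(c(30, 60, 90, 0))),
               c("oblique", "nearly_perpendicular", "nearly_perpendicular",
                 "nearly_parallel"))
  expect_error(classify_polarity(95), "\\[0, 90\\]")
})

test_that("per-ROI profiles recover the generator polarity and flag empty ROIs", {
  fp <- fx_pipeline_default()
  g <- fp$g
  expect_warning(
    prof <- polarity_profile(g$section, fp$pl$jde, fp$pl$masks,
                             roi_intervals_um = list(c(0, 400), c(400, 800),
                                                     c(0.5, 1.5))),
    "no basal nuclei")
  an <- polarity_analytic(8)
  for (i in 1:2) {
    r <- prof$rois[[i]]
    expect_gt(r$n, 40)
    expect_equal(sum(r$histogram$counts), r$n)
    expect_lt(abs(r$class_fractions[["nearly_perpendicular"]] -
                    an$class_mass[["nearly_perpendicular"]]), 0.1)
  }
  expect_true(prof$rois[[3]]$flag_empty)
  expect_equal(prof$rois[[3]]$n, 0)
})

test_that("identically specified sections from different seeds are statistically indistinguishable", {
  for (s in 1:3) {
    ga <- generate_section(section_spec(width_px = 800, height_px = 440,
                                        seed = 300 + s))
    gb <- generate_section(section_spec(width_px = 800, height_px = 440,
                                        seed = 400 + s))
    aa <- run_basal_angles(ga$section)$angle
    bb <- run_basal_angles(gb$section)$angle
    expect_gt(mann_whitney_u(aa, bb)$p_value, 0.01)
  }
})
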