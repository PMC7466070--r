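test_that("marker levels satisfy the exact identities", {
  set.seed(6)
  dapi <- matrix(runif(80 * 80, 0.1, 0.9), 80, 80)
  mask <- matrix(FALSE, 80, 80); mask[20:60, 20:60] <- TRUE
  zero <- marker_level(matrix(0, 80, 80), mask)
  expect_equal(zero$level_au, 0)
  # marker = c * dapi pixelwise: normalized level is exactly c
  lv <- marker_level(0.37 * dapi, mask, dapi = dapi, normalizer = "dapi")
  expect_equal(lv$level_au, 0.37)
  # common gain cancels exactly in the DAPI-normalized level
  lv_gained <- marker_level(3.1 * 0.37 * dapi, mask, dapi = 3.1 * dapi,
                            normalizer = "dapi")
  expect_equal(lv_gained$level_au, lv$level_au)
  expect_error(marker_level(dapi, mask & FALSE), "empty mask")
  expect_error(marker_level(dapi, mask, dapi = matrix(0, 80, 80),
                            normalizer = "dapi"), "degenerate normalizer")
})

test_that("unnormalized levels are additive over a mask partition", {
  set.seed(7)
  marker <- matrix(runif(60 * 60), 60, 60)
  m1 <- matrix(FALSE, 60, 60); m1[, 1:30] <- TRUE
  m2 <- matrix(FALSE, 60, 60); m2[, 31:60] <- TRUE
  whole <- marker_level(marker, m1 | m2)$level_au
  expect_equal(marker_level(marker, m1)$level_au +
                 marker_level(marker, m2)$level_au, whole)
})

test_that("a basal marker halved in dysplastic areas shows a ~0.5 normalized ratio", {
  g <- fx_markers()
  tm <- truth_masks(g$truth)
  W <- ncol(g$section$channels$dapi); H <- nrow(g$section$channels$dapi)
  abn <- matrix(epiquant:::in_intervals(((1:W) - 0.5) * g$section$pixel_size_um,
                                        g$truth$abnormal_intervals_um),
                H, W, byrow = TRUE)
  lvl <- function(cols) marker_level(g$section$channels$vangl2,
                                     tm$basal_band & cols,
                                     dapi = g$section$channels$dapi,
                                     background_mask = tm$background,
                                     normalizer = "dapi")$level_au
  ratio <- lvl(abn) / lvl(!abn)
  expect_gt(ratio, 0.4); expect_lt(ratio, 0.6)
})

test_that("positivity threshold is mean + k*SD of negative-control nuclei", {
  # hand-built label map: three 5x5 nuclei with known constant intensities
  lbl <- matrix(0L, 40, 40)
  lbl[3:7, 3:7] <- 1L; lbl[3:7, 13:17] <- 2L; lbl[23:27, 3:7] <- 3L
  marker <- matrix(0, 40, 40)
  marker[lbl == 1L] <- 0.2; marker[lbl == 2L] <- 0.2; marker[lbl == 3L] <- 0.2
  nuclei <- data.frame(label = 1:3, x = c(5, 15, 5), y = c(5, 5, 25))
  neg <- matrix(TRUE, 40, 40)
  thr <- positivity_threshold(marker, nuclei, lbl, neg)
  expect_equal(as.numeric(thr), 0.2)
  one <- positivity_threshold(marker, nuclei[1, ], lbl, neg)
  expect_equal(as.numeric(one), 0.2)
  expect_true(attr(one, "flag_low_n"))
  expect_error(positivity_threshold(marker, nuclei, lbl, neg & FALSE),
               "negative-control")
})

test_that("a control-derived threshold recovers positive cells in the synthetic section", {
  g <- fx_markers()
  tm <- truth_masks(g$truth)
  nuc <- segment_nuclei(g$section$channels$dapi, masks = tm)
  lbl <- attr(nuc, "label_map")
  px <- g$section$pixel_size_um
  W <- ncol(lbl); H <- nrow(lbl)
  normal_cols <- matrix(!epiquant:::in_intervals(((1:W) - 0.5) * px,
                                                 g$truth$abnormal_intervals_um),
                        H, W, byrow = TRUE)
  thr <- positivity_threshold(g$section$channels$zeb1, nuc,
                              negative_mask = tm$epidermis & normal_cols)
  # ground-truth positive dermal nuclei should be called positive
  truth <- g$truth$nuclei
  derm_pos <- truth[truth$compartment == "dermis" & truth$pos_zeb1, ]
  d2 <- outer(nuc$x, derm_pos$x_px, "-")^2 + outer(nuc$y, derm_pos$y_px, "-")^2
  det <- apply(d2, 2, which.min)[sqrt(apply(d2, 2, min)) <= 5]
  mu <- epiquant:::nucleus_intensity(g$section$channels$zeb1, lbl,
                                     nuc$label[det])
  expect_gte(mean(mu > thr), 0.95)
  # percent positive among dysplastic epidermal nuclei near the set fraction
  abn_nuc <- nuc[!normal_cols[(pmin(pmax(round(nuc$x), 1), W) - 1L) * H +
                                pmin(pmax(round(nuc$y), 1), H)], ]
  pc <- positive_cells(g$section$channels$zeb1, abn_nuc, lbl, thr)
  expect_gt(pc$n_cells, 200)
  half <- 100 * 1.96 * sqrt(0.18 * 0.82 / pc$n_cells)
  expect_lt(abs(pc$percent_positive - 18), half + 1)
  # a threshold above the channel maximum calls nothing positive
  none <- positive_cells(g$section$channels$zeb1, abn_nuc, lbl, 2)
  expect_equal(none$percent_positive, 0)
})

test_that("positive-cell percentages are invariant to a common gain with a re-derived threshold", {
  g <- fx_markers()
  tm <- truth_masks(g$truth)
  nuc <- segment_nuclei(g$section$channels$dapi, masks = tm)
  lbl <- attr(nuc, "label_map")
  ch <- g$section$channels$zeb1
  thr1 <- positivity_threshold(ch, nuc, negative_mask = tm$epidermis)
  thr2 <- positivity_threshold(0.5 * ch, nuc, negative_mask = tm$epidermis)
  p1 <- positive_cells(ch, nuc, lbl, thr1)
  p2 <- positive_cells(0.5 * ch, nuc, lbl, thr2)
  expect_equal(p1$n_positive, p2$n_positive)
  expect_equal(p1$percent_positive, p2$percent_positive)
})
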