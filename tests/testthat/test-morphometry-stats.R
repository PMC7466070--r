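ann <- function(iv, len = 1000) {
  region_annotation("s1", data.frame(label = rep("abnormal", nrow(iv)),
                                     start_um = iv[, 1], end_um = iv[, 2]),
                    section_length_um = len)
}

test_that("abnormal fraction merges overlaps and is exact", {
  expect_equal(abnormal_fraction(ann(cbind(0, 30))), 3.0)
  expect_equal(abnormal_fraction(ann(rbind(c(0, 60), c(40, 100)))), 10.0)
  expect_equal(abnormal_fraction(ann(matrix(numeric(0), 0, 2))), 0.0)
  # invariant under re-ordering and splitting into adjacent pieces
  a <- abnormal_fraction(ann(rbind(c(100, 300), c(500, 650))))
  b <- abnormal_fraction(ann(rbind(c(500, 650), c(100, 300))))
  d <- abnormal_fraction(ann(rbind(c(100, 200), c(200, 300), c(500, 650))))
  expect_equal(a, b); expect_equal(a, d)
  expect_gte(a, 0); expect_lte(a, 100)
  expect_error(ann(cbind(900, 1100)), "intervals")
})

test_that("xenograft classification is boundary-inclusive at the 12% threshold", {
  expect_true(classify_xenograft(rep(12, 6))$above)
  expect_false(classify_xenograft(rep(0, 6))$above)
  r <- classify_xenograft(c(0, 0, 0, 0, 0, 93))
  expect_equal(r$summary_value, 15.5)
  expect_true(r$above)
  # max is the configurable conservative alternative
  expect_true(classify_xenograft(c(0, 0, 0, 0, 0, 13), summary_fun = max)$above)
  expect_error(classify_xenograft(numeric(0)), "at least one")
})

test_that("annotations survive a CSV round trip", {
  a1 <- region_annotation("sec1", data.frame(label = c("abnormal", "roi"),
                                             start_um = c(10, 200),
                                             end_um = c(60, 400)), 1000)
  a2 <- region_annotation("sec2", data.frame(label = "DA", start_um = 5,
                                             end_um = 25), 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(list(a1, a2), path)
  back <- read_annotations(path)
  expect_equal(abnormal_fraction(back$sec1), abnormal_fraction(a1))
  expect_equal(abnormal_fraction(back$sec2), abnormal_fraction(a2))
})

test_that("exact Mann-Whitney p-values match enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 of the 20 labelings are this extreme
  expect_equal(r$method, "exact")
  set.seed(10)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:1000, n1); b <- sample(setdiff(1:1000, a), n2)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(mann_whitney_u(a, b, "greater")$p_value,
                 wilcox.test(a, b, exact = TRUE, alternative = "greater")$p.value)
  }
})

test_that("U complement identity and self-comparison hold", {
  set.seed(11)
  for (i in 1:20) {
    a <- round(rnorm(sample(3:15, 1)), 1); b <- round(rnorm(sample(3:15, 1)), 1)
    ra <- mann_whitney_u(a, b); rb <- mann_whitney_u(b, a)
    expect_equal(ra$u_statistic + rb$u_statistic, ra$n1 * ra$n2)
  }
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  dg <- mann_whitney_u(rep(2, 5), rep(2, 4))
  expect_true(dg$degenerate); expect_equal(dg$p_value, 1)
})

test_that("the normal approximation tracks exact enumeration at n1 = n2 = 8", {
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:10000, 8); b <- sample(setdiff(1:10000, a), 8)
    pe <- mann_whitney_u(a, b, exact = TRUE)$p_value
    pa <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("cohort comparison pools values, reports medians and stars", {
  set.seed(13)
  tab <- data.frame(
    cohort = rep(c("control", "50mGy"), each = 24),
    xenograft_id = rep(rep(1:4, each = 6), 2),
    section_id = rep(1:6, 8),
    metric = "cohesion_au",
    value = c(rnorm(24, 1, 0.3), rnorm(24, 4, 0.6)))
  cc <- cohort_compare(tab, "cohesion_au", "control", "50mGy")
  expect_equal(cc$n, c(24, 24))
  expect_lt(cc$medians[1], cc$medians[2])
  expect_lt(cc$test$p_value, 1e-4)
  expect_equal(cc$stars, "****")
  ccx <- cohort_compare(tab, "cohesion_au", "control", "50mGy", pool = "xenograft")
  expect_equal(ccx$n, c(4, 4))
  expect_equal(ccx$test$method, "exact")
  expect_error(cohort_compare(tab, "nope", "control", "50mGy"), "nope")
  expect_error(cohort_compare(tab, "cohesion_au", "control", "2Gy"), "2Gy")
  expect_equal(significance_stars(c(0.2, 0.03, 0.002, 1e-5)),
               c("NS", "*", "**", "****"))
})
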