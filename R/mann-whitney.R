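# Exact null distribution of the rank sum of a size-n1 subset of ranks 1..n:
# dynamic-programming count of k-subsets by rank sum.
rank_sum_counts <- function(n1, n) {
  smax <- n1 * n
  cnt <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L) # [k+1, s+1]
  cnt[1, 1] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      s_to <- (i:(smax)) + 1L
      s_from <- s_to - i
      valid <- s_from >= 1L
      cnt[k + 1L, s_to[valid]] <- cnt[k + 1L, s_to[valid]] + cnt[k, s_from[valid]]
    }
  }
  cnt[n1 + 1L, ] # counts by rank sum s = 0..smax (s < n1(n1+1)/2 are zero)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is exact
#' (full enumeration of the U null distribution by a count recurrence) when
#' both samples have at most 8 observations and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction is used,
#' matching common statistical-software behaviour. When every value across
#' both samples is identical the test is degenerate and `p = 1` is returned
#' with a flag.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration; default
#'   `NULL` auto-selects as described. Exact enumeration requires tie-free
#'   data.
#' @return an `mwu_result`: list with `u_statistic` (U of sample `a`), `n1`,
#'   `n2`, `p_value`, `alternative`, `method` (`"exact"` or
#'   `"normal_approx_tie_corrected"`) and `degenerate`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater", "less"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) abort_field("a/b", "both samples need >= 1 observation")
  if (any(!is.finite(c(a, b)))) abort_field("a/b", "values must be finite")
  z <- c(a, b); n <- n1 + n2
  r <- rank(z)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(z))
  degenerate <- length(unique(z)) == 1L
  use_exact <- if (is.null(exact)) !ties && n1 <= 8 && n2 <= 8 else exact
  if (use_exact && ties)
    stop("exact enumeration requires tie-free data", call. = FALSE)
  if (degenerate) {
    p <- 1; method <- "normal_approx_tie_corrected"
  } else if (use_exact) {
    cnt <- rank_sum_counts(n1, n)
    us <- (seq_along(cnt) - 1) - n1 * (n1 + 1) / 2 # U values for each rank sum
    keep <- us >= 0
    cnt <- cnt[keep]; us <- us[keep]
    tot <- sum(cnt)
    mu <- n1 * n2 / 2
    p <- switch(alternative,
                two.sided = sum(cnt[abs(us - mu) >= abs(u - mu) - 1e-9]) / tot,
                greater = sum(cnt[us >= u - 1e-9]) / tot,
                less = sum(cnt[us <= u + 1e-9]) / tot)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(z)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-(abs(u - mu) - 0.5) / sigma),
                greater = pnorm(-(u - mu - 0.5) / sigma),
                less = pnorm((u - mu + 0.5) / sigma))
    p <- min(max(p, 0), 1)
    method <- "normal_approx_tie_corrected"
  }
  structure(list(u_statistic = u, n1 = n1, n2 = n2, p_value = p,
                 alternative = alternative, method = method,
                 degenerate = degenerate),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]%s\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$alternative, x$method,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Significance stars at conventional cut-points
#'
#' `****` for p < 0.0001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `NS`.
#'
#' @param p p-value.
#' @return character.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Compare two cohorts on a metric
#'
#' Pools the per-region (or per-section) values of each cohort, as dot plots
#' cumulating multiple regions per section do, reports group medians and a
#' two-sided Mann-Whitney test with significance stars. Set
#' `pool = "xenograft"` to aggregate to one mean value per xenograft first
#' (avoids pseudo-replication; not the default, which mirrors pooled dot
#' plots).
#'
#' @param table data frame with columns `cohort`, `xenograft_id`,
#'   `section_id`, `metric`, `value`.
#' @param metric metric name to compare.
#' @param group_a,group_b cohort labels.
#' @param pool `"regions"` (default) or `"xenograft"`.
#' @return a `cohort_comparison`: list with `metric`, `groups`, `n`,
#'   `medians`, `test` (an `mwu_result`) and `stars`.
#' @export
cohort_compare <- function(table, metric, group_a, group_b,
                           pool = c("regions", "xenograft")) {
  pool <- match.arg(pool)
  need <- c("cohort", "xenograft_id", "section_id", "metric", "value")
  if (!all(need %in% names(table)))
    abort_field("table", paste("needs columns", paste(need, collapse = ", ")))
  d <- table[table$metric == metric, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("metric '%s' not found in table", metric), call. = FALSE)
  pick <- function(g) {
    v <- d[d$cohort == g, , drop = FALSE]
    if (nrow(v) == 0) stop(sprintf("cohort '%s' has no values for metric '%s'",
                                   g, metric), call. = FALSE)
    if (pool == "xenograft")
      as.numeric(tapply(v$value, v$xenograft_id, mean))
    else v$value
  }
  va <- pick(group_a); vb <- pick(group_b)
  test <- mann_whitney_u(va, vb, alternative = "two.sided")
  structure(list(metric = metric, groups = c(group_a, group_b),
                 n = c(length(va), length(vb)),
                 medians = c(stats::median(va), stats::median(vb)),
                 test = test, stars = significance_stars(test$p_value),
                 pool = pool),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d, median %.3g) vs %s (n=%d, median %.3g): p = %.3g %s\n",
              x$metric, x$groups[1], x$n[1], x$medians[1],
              x$groups[2], x$n[2], x$medians[2], x$test$p_value, x$stars))
  invisible(x)
}
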