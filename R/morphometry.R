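#' Region annotation for one section
#'
#' Named 1-D intervals along the section axis, in micrometres, labelling
#' normal regions, abnormal/dysplastic regions (DA) and ROIs.
#'
#' @param section_id identifier.
#' @param intervals data frame with `label` (one of `"normal"`, `"abnormal"`,
#'   `"DA"`, `"roi"`), `start_um`, `end_um`.
#' @param section_length_um total section length in micrometres.
#' @return an object of class `region_annotation`.
#' @export
region_annotation <- function(section_id, intervals, section_length_um) {
  check_scalar(section_length_um, "section_length_um", positive = TRUE)
  if (nrow(intervals) > 0) {
    if (!all(c("label", "start_um", "end_um") %in% names(intervals)))
      abort_field("intervals", "needs columns label, start_um, end_um")
    if (!all(intervals$label %in% c("normal", "abnormal", "DA", "roi")))
      abort_field("intervals", "label must be normal, abnormal, DA or roi")
    if (any(intervals$start_um < 0 | intervals$end_um > section_length_um |
              intervals$start_um >= intervals$end_um))
      abort_field("intervals",
                  sprintf("intervals must satisfy 0 <= start < end <= %g",
                          section_length_um))
  }
  structure(list(section_id = section_id, intervals = intervals,
                 section_length_um = section_length_um),
            class = "region_annotation")
}

merge_intervals <- function(start, end) {
  if (length(start) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Percentage of section length that is abnormal
#'
#' Merges overlapping abnormal intervals, sums their lengths and reports the
#' percentage of the whole section length.
#'
#' @param annotation a [region_annotation()].
#' @param abnormal_labels labels counted as abnormal (default `"abnormal"`
#'   and `"DA"`).
#' @return percentage in \[0, 100\].
#' @export
abnormal_fraction <- function(annotation, abnormal_labels = c("abnormal", "DA")) {
  iv <- annotation$intervals
  iv <- iv[iv$label %in% abnormal_labels, , drop = FALSE]
  m <- merge_intervals(iv$start_um, iv$end_um)
  100 * sum(m$end - m$start) / annotation$section_length_um
}

#' Classify a xenograft by its abnormal-fraction summary
#'
#' Summarises per-section abnormal-length percentages (typically 6 sections
#' per xenograft) and classifies the xenograft as above the dysplasia
#' threshold when the summary reaches it ("at least 12%", boundary
#' inclusive). The summary rule (mean by default; `max` is the conservative
#' alternative) and the threshold are configurable.
#'
#' @param per_section_fractions numeric vector of percentages.
#' @param threshold_percent classification threshold, default 12.
#' @param summary_fun aggregation over sections, default [mean()].
#' @return list with `summary_value`, `above` (logical),
#'   `threshold_percent`, `n_sections`.
#' @export
classify_xenograft <- function(per_section_fractions, threshold_percent = 12,
                               summary_fun = mean) {
  if (length(per_section_fractions) == 0)
    abort_field("per_section_fractions", "needs at least one section value")
  if (any(!is.finite(per_section_fractions) | per_section_fractions < 0 |
            per_section_fractions > 100))
    abort_field("per_section_fractions", "values must be percentages in [0, 100]")
  check_scalar(threshold_percent, "threshold_percent", nonneg = TRUE)
  s <- summary_fun(per_section_fractions)
  list(summary_value = s, above = s >= threshold_percent,
       threshold_percent = threshold_percent,
       n_sections = length(per_section_fractions))
}

#' Read / write region annotations as CSV
#'
#' CSV columns: `section_id`, `label`, `start_um`, `end_um`, plus
#' `section_length_um` repeated per row.
#'
#' @param annotations list of [region_annotation()] objects.
#' @param path CSV path.
#' @return `read_annotations` returns a named list of `region_annotation`s.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    iv <- a$intervals
    if (nrow(iv) == 0)
      iv <- data.frame(label = character(0), start_um = numeric(0), end_um = numeric(0))
    cbind(data.frame(section_id = rep(a$section_id, nrow(iv))), iv,
          data.frame(section_length_um = rep(a$section_length_um, nrow(iv))))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(df$section_id)) {
    d <- df[df$section_id == sid, , drop = FALSE]
    out[[as.character(sid)]] <- region_annotation(
      sid, d[, c("label", "start_um", "end_um")], d$section_length_um[1])
  }
  out
}
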