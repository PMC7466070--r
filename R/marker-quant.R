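#' Semi-quantitative marker level within a mask
#'
#' Sums marker intensities inside a mask after subtracting the background
#' median (estimated over `background_mask`, typically out-of-tissue pixels;
#' subtraction is floored at zero). With `normalizer = "dapi"` the same
#' background-subtracted sum of the DAPI channel over the same mask divides
#' the marker sum, giving a DAPI-normalized level that is invariant to a
#' common intensity gain.
#'
#' @param marker 2-D numeric raster.
#' @param mask logical matrix, non-empty.
#' @param dapi optional DAPI raster (required for `normalizer = "dapi"`).
#' @param background_mask optional logical matrix of tissue-free pixels used
#'   for the background-median estimate (default: no subtraction).
#' @param normalizer `"none"` or `"dapi"`.
#' @param mask_kind label recorded in the result (`"basal_band"`,
#'   `"epidermis"`, `"custom"`).
#' @return a `marker_level`: list with `mask_kind`, `total_signal`,
#'   `normalizer`, `level_au`.
#' @export
marker_level <- function(marker, mask, dapi = NULL, background_mask = NULL,
                         normalizer = c("none", "dapi"),
                         mask_kind = c("custom", "basal_band", "epidermis")) {
  normalizer <- match.arg(normalizer)
  mask_kind <- match.arg(mask_kind)
  if (!identical(dim(marker), dim(mask)))
    abort_field("mask", "must share shape with marker")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  bg_med <- function(ch) {
    if (is.null(background_mask) || !any(background_mask)) 0
    else stats::median(ch[background_mask])
  }
  total <- sum(pmax(marker[mask] - bg_med(marker), 0))
  level <- total
  if (normalizer == "dapi") {
    if (is.null(dapi)) abort_field("dapi", "required for normalizer = 'dapi'")
    if (!identical(dim(dapi), dim(marker)))
      abort_field("dapi", "must share shape with marker")
    td <- sum(pmax(dapi[mask] - bg_med(dapi), 0))
    if (td <= 0) stop("degenerate normalizer: zero DAPI sum in mask", call. = FALSE)
    level <- total / td
  }
  structure(list(mask_kind = mask_kind, total_signal = total,
                 normalizer = normalizer, level_au = level),
            class = "marker_level")
}

# Peel the 1-px boundary off every labelled object (8-connectivity). Pixels
# on a watershed boundary can carry signal bled over from a touching
# neighbour; the interior is what belongs to the nucleus. Objects so small
# that peeling would empty them keep their original pixels.
label_interior <- function(label_map) {
  H <- nrow(label_map); W <- ncol(label_map)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- label_map
  boundary <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    boundary <- boundary | (nb != label_map)
  }
  interior <- label_map
  interior[boundary] <- 0L
  lost <- setdiff(unique(label_map[label_map > 0L]),
                  unique(interior[interior > 0L]))
  if (length(lost) > 0) {
    sel <- label_map %in% lost
    interior[sel] <- label_map[sel]
  }
  interior
}

# Per-nucleus marker intensity over the eroded labelled pixels. The median
# (default) is robust both to single bright pixels and to signal bled across a
# misplaced watershed boundary, which can hand a nucleus a sizeable minority
# of a bright neighbour's pixels; the mean is available for sensitivity
# analyses.
nucleus_intensity <- function(marker, label_map, labels,
                              stat = c("median", "mean"), erode = TRUE) {
  stat <- match.arg(stat)
  if (!identical(dim(marker), dim(label_map)))
    abort_field("label_map", "must share shape with marker")
  if (erode) label_map <- label_interior(label_map)
  sel <- label_map > 0L
  if (stat == "mean") {
    sums <- rowsum(marker[sel], label_map[sel])
    cnts <- rowsum(rep(1, sum(sel)), label_map[sel])
    vals <- stats::setNames(as.numeric(sums / cnts), rownames(sums))
  } else {
    med <- tapply(marker[sel], label_map[sel], stats::median)
    vals <- stats::setNames(as.numeric(med), names(med))
  }
  vals[as.character(labels)]
}

#' Positivity threshold from a negative-control compartment
#'
#' Automated surrogate for manual positive-cell calling: the threshold is
#' `mean + k * SD` of per-nucleus intensities over nuclei whose centroid
#' lies in a compartment known to be negative (e.g. control epidermis for a
#' dermis-restricted marker). With a single negative nucleus the SD is taken
#' as 0 and the result is flagged low-n.
#'
#' @param marker 2-D numeric raster.
#' @param nuclei a `nucleus_records` data frame from [segment_nuclei()].
#' @param label_map integer label matrix (attached to `nuclei` by default).
#' @param negative_mask logical matrix selecting the negative compartment.
#' @param k number of SDs (default 3).
#' @param stat per-nucleus statistic, `"median"` (default, robust to
#'   boundary spill from touching nuclei) or `"mean"`.
#' @return scalar threshold with attributes `n_negative` and `flag_low_n`.
#' @export
positivity_threshold <- function(marker, nuclei, label_map = attr(nuclei, "label_map"),
                                 negative_mask, k = 3,
                                 stat = c("median", "mean")) {
  if (!any(negative_mask)) stop("empty negative-control mask", call. = FALSE)
  rr <- pmin(pmax(round(nuclei$y), 1L), nrow(marker))
  cc <- pmin(pmax(round(nuclei$x), 1L), ncol(marker))
  neg <- nuclei$label[negative_mask[(cc - 1L) * nrow(marker) + rr]]
  if (length(neg) == 0) stop("no nuclei inside the negative-control mask", call. = FALSE)
  mu <- nucleus_intensity(marker, label_map, neg, stat = match.arg(stat))
  s <- if (length(mu) > 1) stats::sd(mu) else 0
  structure(mean(mu) + k * s, n_negative = length(mu),
            flag_low_n = length(mu) < 10)
}

#' Count marker-positive nuclei
#'
#' A nucleus is positive iff its per-nucleus marker intensity (median over
#' the eroded interior of its labelled pixels by default) exceeds the
#' threshold. Counts can be restricted to a set of compartments (e.g.
#' epidermal keratinocytes only).
#'
#' @param marker 2-D numeric raster.
#' @param nuclei a `nucleus_records` data frame.
#' @param label_map integer label matrix aligned with `marker`.
#' @param threshold positivity threshold (see [positivity_threshold()]).
#' @param compartments compartments to include; `NULL` keeps all nuclei.
#' @param stat per-nucleus statistic, `"median"` (default) or `"mean"`; use
#'   the same choice as in [positivity_threshold()].
#' @return a `positive_cell_result`: list with `n_cells`, `n_positive`,
#'   `percent_positive` (`NA` and flagged when `n_cells == 0`) and
#'   `positivity_threshold`; per-nucleus calls in `$calls`.
#' @export
positive_cells <- function(marker, nuclei, label_map = attr(nuclei, "label_map"),
                           threshold, compartments = c("basal", "suprabasal"),
                           stat = c("median", "mean")) {
  check_scalar(as.numeric(threshold), "threshold")
  sel <- if (is.null(compartments)) rep(TRUE, nrow(nuclei))
  else !is.na(nuclei$compartment) & nuclei$compartment %in% compartments
  labs <- nuclei$label[sel]
  if (length(labs) == 0) {
    warning("no nuclei in the requested compartments")
    return(structure(list(n_cells = 0L, n_positive = 0L,
                          percent_positive = NA_real_,
                          positivity_threshold = as.numeric(threshold),
                          flag_empty = TRUE, calls = logical(0)),
                     class = "positive_cell_result"))
  }
  mu <- nucleus_intensity(marker, label_map, labs, stat = match.arg(stat))
  pos <- mu > as.numeric(threshold)
  structure(list(n_cells = length(labs), n_positive = sum(pos),
                 percent_positive = 100 * mean(pos),
                 positivity_threshold = as.numeric(threshold),
                 flag_empty = FALSE, calls = pos),
            class = "positive_cell_result")
}
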