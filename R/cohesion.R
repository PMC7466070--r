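#' Luminance grayscale of an RGB raster
#'
#' Rec. 601 luminance (`0.299 R + 0.587 G + 0.114 B`), range-preserving.
#'
#' @param rgb numeric array `height x width x 3`.
#' @return 2-D numeric matrix.
#' @export
grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    abort_field("rgb", "must be a height x width x 3 array")
  out <- rgb[, , 1] * 0.299 + rgb[, , 2] * 0.587 + rgb[, , 3] * 0.114
  matrix(out, dim(rgb)[1], dim(rgb)[2])
}

#' Detect non-cohesive spaces within the epidermis
#'
#' Marks epidermis pixels at or below the background-derived threshold as
#' expanded intercellular space, removes connected components smaller than
#' `min_object_px` (noise), and scores the section as
#' `100 * space_px / epidermis_px` (arbitrary units per epidermis area).
#'
#' @param gray 2-D numeric raster (grayscale HES view, dark = empty space; use
#'   `1 - gray` upstream for the opposite polarity).
#' @param epidermis_mask logical matrix.
#' @param threshold intensity threshold, typically from
#'   [background_threshold()].
#' @param min_object_px smallest retained space component (default 20).
#' @return a `cohesion_result`: list with `space_mask`, `space_px`,
#'   `epidermis_px`, `score_au`.
#' @export
space_mask <- function(gray, epidermis_mask, threshold, min_object_px = 20) {
  if (!any(epidermis_mask)) stop("no epidermis: empty epidermis mask", call. = FALSE)
  check_scalar(threshold, "threshold")
  check_scalar(min_object_px, "min_object_px", nonneg = TRUE)
  sp <- epidermis_mask & gray <= threshold
  if (any(sp) && min_object_px > 0) {
    lbl <- from_ebi(EBImage::bwlabel(as_ebi(sp)))
    sz <- tabulate(lbl[lbl > 0L])
    small <- which(sz < min_object_px)
    if (length(small) > 0) sp[lbl %in% small] <- FALSE
  }
  structure(list(space_mask = sp, space_px = sum(sp),
                 epidermis_px = sum(epidermis_mask),
                 score_au = 100 * sum(sp) / sum(epidermis_mask)),
            class = "cohesion_result")
}

#' Per-region non-cohesive-space scores
#'
#' Computes the space mask once over the whole epidermis (so the small-object
#' filter is applied globally and per-region space pixel counts sum exactly to
#' the whole-section count), then scores each interval along the section axis.
#' Regions with no epidermis pixels get a `NA` score and a flag.
#'
#' @param gray 2-D numeric raster.
#' @param epidermis_mask logical matrix.
#' @param regions_um list of `c(start, end)` intervals in micrometres.
#' @param threshold intensity threshold.
#' @param pixel_size_um micrometres per pixel.
#' @param min_object_px smallest retained space component.
#' @return data frame with `region`, `start_um`, `end_um`, `space_px`,
#'   `epidermis_px`, `score_au`, `flag_empty`; the whole-section
#'   `cohesion_result` is attached as `attr(, "whole")`.
#' @export
cohesion_by_region <- function(gray, epidermis_mask, regions_um, threshold,
                               pixel_size_um, min_object_px = 20) {
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  whole <- space_mask(gray, epidermis_mask, threshold, min_object_px)
  width_um <- ncol(gray) * pixel_size_um
  out <- NULL
  for (i in seq_along(regions_um)) {
    iv <- regions_um[[i]]
    if (length(iv) != 2L || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > width_um)
      abort_field("regions_um",
                  sprintf("regions must be c(start, end) within [0, %g] um", width_um))
    c0 <- max(1L, floor(iv[1] / pixel_size_um) + 1L)
    c1 <- min(ncol(gray), ceiling(iv[2] / pixel_size_um))
    epx <- sum(epidermis_mask[, c0:c1])
    spx <- sum(whole$space_mask[, c0:c1])
    out <- rbind(out, data.frame(
      region = i, start_um = iv[1], end_um = iv[2],
      space_px = spx, epidermis_px = epx,
      score_au = if (epx > 0) 100 * spx / epx else NA_real_,
      flag_empty = epx == 0))
  }
  if (any(out$flag_empty)) warning("region(s) with no epidermis pixels flagged")
  attr(out, "whole") <- whole
  out
}

#' QC overlay with spaces painted red
#'
#' @param gray 2-D raster in \[0, 1\].
#' @param space logical matrix or a `cohesion_result`.
#' @return RGB array `height x width x 3`.
#' @export
cohesion_overlay <- function(gray, space) {
  if (inherits(space, "cohesion_result")) space <- space$space_mask
  r <- gray; g <- gray; b <- gray
  r[space] <- 1; g[space] <- 0; b[space] <- 0
  array(c(r, g, b), dim = c(dim(gray), 3L))
}
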