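#' Segment nuclei and measure their orientation
#'
#' Thresholds the nuclear channel (Otsu), splits touching nuclei by a
#' distance-transform watershed, discards objects below `min_area_px`, and
#' measures each remaining nucleus by the moments of its pixel set: centroid,
#' area, the equivalent-ellipse major-axis angle (degrees from the +x axis in
#' \[0, 180), y down) and eccentricity. Each record is tagged with the
#' compartment containing its centroid. Near-circular nuclei
#' (eccentricity < `low_ecc`) carry an orientation but are flagged
#' low-confidence.
#'
#' @param nuclear 2-D numeric raster in \[0, 1\].
#' @param min_area_px minimum object area in pixels (default 40).
#' @param max_area_px maximum object area in pixels (default `Inf`); bounding
#'   the area from above discards unresolved doublets of touching nuclei,
#'   whose pooled orientation is meaningless.
#' @param masks optional [compartment_masks()] used to assign compartments.
#' @param low_ecc eccentricity below which the orientation is flagged.
#' @param watershed_tolerance minimum depth (in distance-map units) separating
#'   two catchment basins before touching nuclei are split; 0.5 splits most
#'   abutting nuclei without fragmenting single elongated ones.
#' @return a data frame of class `nucleus_records` with columns `label`, `x`,
#'   `y`, `area_px`, `major_axis_angle_deg`, `eccentricity`, `low_confidence`,
#'   `compartment`; the integer label map is attached as
#'   `attr(, "label_map")`. An empty data frame when nothing is found.
#' @export
segment_nuclei <- function(nuclear, min_area_px = 40, masks = NULL,
                           low_ecc = 0.05, watershed_tolerance = 0.5,
                           max_area_px = Inf) {
  if (!is.matrix(nuclear) || length(nuclear) == 0L)
    abort_field("nuclear", "must be a non-empty matrix")
  check_scalar(min_area_px, "min_area_px", nonneg = TRUE)
  empty <- function() {
    df <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                     area_px = integer(0), major_axis_angle_deg = numeric(0),
                     eccentricity = numeric(0), low_confidence = logical(0),
                     compartment = character(0), stringsAsFactors = FALSE)
    attr(df, "label_map") <- matrix(0L, nrow(nuclear), ncol(nuclear))
    class(df) <- c("nucleus_records", "data.frame")
    df
  }
  img <- as_ebi(nuclear)
  rng <- range(nuclear)
  if (diff(rng) < 1e-6) return(empty())
  t <- EBImage::otsu(img, range = rng)
  mask <- nuclear > t
  if (!any(mask)) return(empty())
  lbl_img <- EBImage::watershed(EBImage::distmap(as_ebi(mask)),
                                tolerance = watershed_tolerance, ext = 1)
  mom <- EBImage::computeFeatures.moment(lbl_img)
  shp <- EBImage::computeFeatures.shape(lbl_img)
  if (is.null(mom) || nrow(mom) == 0L) return(empty())
  lbl <- from_ebi(lbl_img)
  keep <- shp[, "s.area"] >= min_area_px & shp[, "s.area"] <= max_area_px
  if (!any(keep)) return(empty())
  drop_ids <- which(!keep)
  if (length(drop_ids) > 0) lbl[lbl %in% drop_ids] <- 0L
  df <- data.frame(label = which(keep),
                   x = mom[keep, "m.cx"], y = mom[keep, "m.cy"],
                   area_px = as.integer(shp[keep, "s.area"]),
                   major_axis_angle_deg = (mom[keep, "m.theta"] * 180 / pi) %% 180,
                   eccentricity = mom[keep, "m.eccentricity"],
                   stringsAsFactors = FALSE)
  df$low_confidence <- df$eccentricity < low_ecc
  df$compartment <- NA_character_
  if (!is.null(masks)) {
    rr <- pmin(pmax(round(df$y), 1L), nrow(nuclear))
    cc <- pmin(pmax(round(df$x), 1L), ncol(nuclear))
    idx <- (cc - 1L) * nrow(nuclear) + rr
    if (!is.null(masks$basal_band)) df$compartment[masks$basal_band[idx]] <- "basal"
    sel <- is.na(df$compartment) & masks$epidermis[idx]
    df$compartment[sel] <- "suprabasal"
    sel <- is.na(df$compartment) & masks$dermis[idx]
    df$compartment[sel] <- "dermis"
  }
  rownames(df) <- NULL
  attr(df, "label_map") <- lbl
  class(df) <- c("nucleus_records", "data.frame")
  df
}

# Tangent direction (degrees from +x, y down) at every vertex of a polyline.
# A pixel-traced junction is an integer staircase, so a +/-1 neighbour
# difference is dominated by quantization; instead the local tangent is the
# principal direction (undirected PCA axis) of a window of `window` vertices
# on each side (clipped at segment ends). The PCA axis averages the staircase
# out without smoothing the global curve and, unlike a y-on-x regression
# slope, is exactly equivariant under rigid rotation of the scene (vertical
# tangents included).
jde_tangents <- function(jde, window = 10L) {
  n <- nrow(jde)
  tng <- numeric(n)
  for (sg in unique(jde$segment)) {
    i <- which(jde$segment == sg)
    m <- length(i)
    if (m == 1) { tng[i] <- 0; next }
    x <- jde$x[i]; y <- jde$y[i]
    cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
    cxx <- cumsum(c(0, x * x)); cyy <- cumsum(c(0, y * y))
    cxy <- cumsum(c(0, x * y))
    lo <- pmax(seq_len(m) - window, 1L); hi <- pmin(seq_len(m) + window, m)
    k <- hi - lo + 1
    sx <- cx[hi + 1] - cx[lo]; sy <- cy[hi + 1] - cy[lo]
    sxx <- cxx[hi + 1] - cxx[lo]; syy <- cyy[hi + 1] - cyy[lo]
    sxy <- cxy[hi + 1] - cxy[lo]
    vxx <- sxx - sx * sx / k; vyy <- syy - sy * sy / k
    vxy <- sxy - sx * sy / k
    tng[i] <- 0.5 * atan2(2 * vxy, vxx - vyy) * 180 / pi
  }
  tng
}

#' Angle between nucleus axis and the local JDE tangent
#'
#' For each nucleus, finds the nearest polyline vertex, takes the local
#' tangent by a least-squares fit over `tangent_window` vertices on each side
#' (see the note in the source about staircase quantization), and returns the
#' acute angle between the nucleus major axis and that tangent, folded into
#' \[0, 90\] degrees: 90 means perpendicular to the junction.
#'
#' @param nuclei a `nucleus_records` data frame (needs `x`, `y`,
#'   `major_axis_angle_deg`), or a single-row equivalent.
#' @param jde a `jde_polyline` (or ground-truth polyline with `x_px`/`y_px`).
#' @param tangent_window half-width, in polyline vertices, of the local
#'   tangent fit (default 10).
#' @return numeric vector of angles in \[0, 90\].
#' @export
angle_to_jde <- function(nuclei, jde, tangent_window = 10L) {
  xj <- if ("x" %in% names(jde)) jde$x else jde$x_px
  yj <- if ("y" %in% names(jde)) jde$y else jde$y_px
  if (length(xj) < 2L) abort_field("jde", "polyline must have at least 2 points")
  if (is.null(jde$segment)) jde_df <- data.frame(x = xj, y = yj, segment = 1L)
  else jde_df <- data.frame(x = xj, y = yj, segment = jde$segment)
  tng <- jde_tangents(jde_df, window = tangent_window)
  n <- nrow(nuclei)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(nuclei$x[s:e], jde_df$x, "-")
    dy <- outer(nuclei$y[s:e], jde_df$y, "-")
    nearest <- max.col(-(dx * dx + dy * dy), ties.method = "first")
    out[s:e] <- fold_angle(nuclei$major_axis_angle_deg[s:e] - tng[nearest])
  }
  out
}

#' Histogram of angles in 18 five-degree bins
#'
#' Bins angles into the 18 categories `[0,5), [5,10), ..., [85,90]` (the last
#' bin is closed so 90 degrees is countable).
#'
#' @param angles numeric vector of angles in \[0, 90\].
#' @return an `angle_histogram`: list with `bin_edges` (19 values), `counts`
#'   (18 integers summing to `n`) and `n`.
#' @export
bin_angles <- function(angles) {
  if (length(angles) > 0 && (any(!is.finite(angles)) || any(angles < 0 | angles > 90)))
    abort_field("angles", "all angles must lie in [0, 90]")
  edges <- seq(0, 90, by = 5)
  idx <- pmin(findInterval(angles, edges), 18L)
  structure(list(bin_edges = edges, counts = tabulate(idx, nbins = 18L),
                 n = length(angles)), class = "angle_histogram")
}

#' @export
as.data.frame.angle_histogram <- function(x, ...) {
  data.frame(bin_low = x$bin_edges[-19], bin_high = x$bin_edges[-1],
             count = x$counts)
}

#' Classify an angle into the three polarity classes
#'
#' Nearly parallel: \[0, 30); oblique: \[30, 60); nearly perpendicular:
#' \[60, 90\]. The class boundaries are exposed for sensitivity analyses.
#'
#' @param angle_deg numeric vector of angles in \[0, 90\].
#' @param boundaries cut-points between the classes, default `c(30, 60)`.
#' @return factor with levels `nearly_parallel`, `oblique`,
#'   `nearly_perpendicular`.
#' @export
classify_polarity <- function(angle_deg, boundaries = c(30, 60)) {
  if (length(angle_deg) > 0 &&
      (any(!is.finite(angle_deg)) || any(angle_deg < 0 | angle_deg > 90)))
    abort_field("angle_deg", "all angles must lie in [0, 90]")
  lev <- c("nearly_parallel", "oblique", "nearly_perpendicular")
  cls <- ifelse(angle_deg < boundaries[1], lev[1],
                ifelse(angle_deg < boundaries[2], lev[2], lev[3]))
  factor(cls, levels = lev)
}

#' Per-ROI polarity profile
#'
#' Runs nucleus segmentation on the section's nuclear channel, measures every
#' basal nucleus's angle to the JDE, and summarises each region of interest
#' (an interval along the section axis, in micrometres) by its 18-bin angle
#' histogram, polarity-class fractions and nucleus count. ROIs with no basal
#' nuclei are returned with `n = 0` and flagged.
#'
#' @param section a [section_image()].
#' @param jde a `jde_polyline`.
#' @param masks a [compartment_masks()] with `basal_band` set.
#' @param roi_intervals_um list of `c(start, end)` in micrometres.
#' @param nuclear_channel name of the nuclear channel.
#' @param min_area_px,max_area_px passed to [segment_nuclei()].
#' @return a `polarity_profile`: list with `rois` (per-ROI list of `n`,
#'   `histogram`, `class_fractions`, `flag_empty`), `summary` (data frame) and
#'   `nuclei` (the basal records with their angles).
#' @export
polarity_profile <- function(section, jde, masks, roi_intervals_um,
                             nuclear_channel = "dapi", min_area_px = 40,
                             max_area_px = Inf) {
  px <- section$pixel_size_um
  width_um <- section_dim(section)[2] * px
  for (iv in roi_intervals_um)
    if (length(iv) != 2L || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > width_um)
      abort_field("roi_intervals_um",
                  sprintf("ROIs must be c(start, end) within [0, %g] um", width_um))
  nuc <- segment_nuclei(get_channel(section, nuclear_channel),
                        min_area_px = min_area_px, max_area_px = max_area_px,
                        masks = masks)
  nuc$angle_jde_deg <- angle_to_jde(nuc, jde)
  basal <- nuc[!is.na(nuc$compartment) & nuc$compartment == "basal", , drop = FALSE]
  x_um <- basal$x * px
  rois <- list(); summ <- NULL
  for (i in seq_along(roi_intervals_um)) {
    iv <- roi_intervals_um[[i]]
    sel <- x_um >= iv[1] & x_um < iv[2]
    ang <- basal$angle_jde_deg[sel]
    h <- bin_angles(ang)
    fr <- if (length(ang) > 0) prop.table(table(classify_polarity(ang)))
    else table(classify_polarity(numeric(0)))
    fr <- stats::setNames(as.numeric(fr), names(fr))
    flag <- length(ang) == 0
    if (flag) warning(sprintf("ROI %d contains no basal nuclei", i))
    rois[[i]] <- list(interval_um = iv, n = length(ang), histogram = h,
                      class_fractions = fr, flag_empty = flag)
    summ <- rbind(summ, data.frame(
      roi = i, start_um = iv[1], end_um = iv[2], n = length(ang),
      median_angle_deg = if (length(ang)) stats::median(ang) else NA_real_,
      nearly_parallel = fr[["nearly_parallel"]],
      oblique = fr[["oblique"]],
      nearly_perpendicular = fr[["nearly_perpendicular"]]))
  }
  structure(list(rois = rois, summary = summ, nuclei = basal),
            class = "polarity_profile")
}
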