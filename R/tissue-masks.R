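#' Compartment masks container
#'
#' Binary rasters for the epidermis, dermis, background, and optionally the
#' basal band. Masks are pairwise disjoint (checked on construction) and the
#' basal band, when present, is a subset of the epidermis.
#'
#' @param epidermis,dermis,background logical matrices of identical shape.
#' @param basal_band optional logical matrix, subset of `epidermis`.
#' @return an object of class `compartment_masks`.
#' @export
compartment_masks <- function(epidermis, dermis, background, basal_band = NULL) {
  if (!identical(dim(epidermis), dim(dermis)) ||
      !identical(dim(epidermis), dim(background)))
    abort_field("masks", "epidermis, dermis and background must share shape")
  if (any(epidermis & dermis) || any(epidermis & background) ||
      any(dermis & background))
    abort_field("masks", "compartment masks must be pairwise disjoint")
  if (!is.null(basal_band)) {
    if (!identical(dim(basal_band), dim(epidermis)))
      abort_field("basal_band", "must share shape with epidermis")
    if (any(basal_band & !epidermis))
      abort_field("basal_band", "must be a subset of the epidermis mask")
  }
  structure(list(epidermis = epidermis, dermis = dermis,
                 background = background, basal_band = basal_band),
            class = "compartment_masks")
}

#' Background intensity threshold from tissue-free regions
#'
#' Estimates the empty-space threshold as `mean + k * SD` of the pixels inside
#' user-supplied tissue-free rectangles. Pixels at or below the threshold are
#' classifiable as empty space (background or intercellular gap).
#'
#' @param gray 2-D numeric raster.
#' @param tissue_free_regions list of rectangles `c(x0, x1, y0, y1)` in pixel
#'   coordinates (1-based, inclusive).
#' @param k number of SDs above the background mean (default 3).
#' @return scalar intensity threshold.
#' @export
background_threshold <- function(gray, tissue_free_regions, k = 3) {
  if (!is.matrix(gray)) abort_field("gray", "must be a matrix")
  check_scalar(k, "k", nonneg = TRUE)
  if (!is.list(tissue_free_regions) || length(tissue_free_regions) == 0L)
    abort_field("tissue_free_regions", "must be a non-empty list of rectangles")
  px <- numeric(0)
  for (r in tissue_free_regions) {
    if (length(r) != 4L)
      abort_field("tissue_free_regions", "each rectangle must be c(x0, x1, y0, y1)")
    x0 <- r[1]; x1 <- r[2]; y0 <- r[3]; y1 <- r[4]
    if (x0 > x1 || y0 > y1)
      abort_field("tissue_free_regions", "rectangle has zero or negative area")
    if (x0 < 1 || x1 > ncol(gray) || y0 < 1 || y1 > nrow(gray))
      abort_field("tissue_free_regions", "rectangle outside image bounds")
    px <- c(px, as.vector(gray[y0:y1, x0:x1]))
  }
  if (length(px) < 100)
    warning("fewer than 100 tissue-free pixels; threshold estimate is noisy")
  s <- stats::sd(px)
  mean(px) + k * (if (is.na(s)) 0 else s)
}

#' Segment tissue compartments
#'
#' Classifies pixels above the background threshold as tissue, keeps the
#' largest connected tissue component, and splits it into epidermis and
#' dermis. In synthetic mode a ground-truth label raster can be supplied;
#' otherwise the split is intensity-based (the epidermis renders brighter than
#' the dermis in the HES-like composite): 3-class k-means on tissue
#' intensities, the brightest class seeding the epidermis, followed by
#' morphological closing and hole filling so nuclei and intercellular gaps
#' stay inside the epidermis mask.
#'
#' @param section a [section_image()].
#' @param nuclear_channel channel used when no HES composite is present.
#' @param threshold background threshold from [background_threshold()].
#' @param truth_labels optional ground-truth compartment raster
#'   (`truth$compartments`) to split epidermis/dermis exactly.
#' @return a [compartment_masks()] object (without `basal_band`).
#' @export
segment_compartments <- function(section, nuclear_channel = "dapi", threshold,
                                 truth_labels = NULL) {
  gray <- section_gray(section, nuclear_channel)
  check_scalar(threshold, "threshold")
  tissue <- gray > threshold
  if (!any(tissue)) stop("empty section: no tissue above threshold", call. = FALSE)
  tissue <- largest_component(tissue)
  filled <- from_ebi(EBImage::fillHull(as_ebi(tissue))) > 0
  if (!is.null(truth_labels)) {
    epi <- filled & (truth_labels == COMP_BASAL | truth_labels == COMP_SUPRABASAL |
                       truth_labels == COMP_GAP)
    derm <- filled & truth_labels == COMP_DERMIS
  } else {
    v <- gray[tissue]
    ctr <- unique(as.numeric(quantile(v, c(0.15, 0.5, 0.9))))
    if (length(ctr) >= 2) {
      km <- suppressWarnings(kmeans(v, centers = matrix(ctr, ncol = 1)))
      means <- as.numeric(km$centers)
      top <- which.max(means)
      cut <- (max(means[-top]) + means[top]) / 2
    } else cut <- ctr[1] - 1e-9 # flat image: everything is one class
    epi_raw <- tissue & gray > cut
    brush <- EBImage::makeBrush(7, "disc")
    epi_raw <- from_ebi(EBImage::closing(as_ebi(epi_raw), brush)) > 0
    if (!any(epi_raw)) stop("empty section: no epidermis-like tissue", call. = FALSE)
    # drop stray bright specks but keep every substantial piece of the
    # epidermal band (it may be cut into several components by dark gaps)
    lbl <- from_ebi(EBImage::bwlabel(as_ebi(epi_raw)))
    sz <- tabulate(lbl[lbl > 0L])
    small <- which(sz < 25)
    if (length(small) > 0) epi_raw[lbl %in% small] <- FALSE
    # The epidermis is a band: fill each column between the top and bottom of
    # the bright epidermal tissue so nuclei and intercellular gaps (dark, and
    # possibly connected to the outside) stay inside the epidermis mask.
    H <- nrow(gray); W <- ncol(gray)
    top_env <- rep(NA_real_, W); bot_env <- rep(NA_real_, W)
    for (cc in seq_len(W)) {
      r <- which(epi_raw[, cc])
      if (length(r) > 0) { top_env[cc] <- r[1]; bot_env[cc] <- r[length(r)] }
    }
    ok <- which(!is.na(top_env))
    if (length(ok) >= 2) {
      span <- ok[1]:ok[length(ok)]
      top_env[span] <- approx(ok, top_env[ok], xout = span)$y
      bot_env[span] <- approx(ok, bot_env[ok], xout = span)$y
      # columns occluded by a dark gap lying on the surface or the junction
      # report a shrunken envelope; a running median restores them (gaps are
      # narrow relative to the window)
      if (length(span) > 31) {
        top_env[span] <- stats::runmed(top_env[span], 31, endrule = "median")
        bot_env[span] <- stats::runmed(bot_env[span], 31, endrule = "median")
      }
    }
    rows <- matrix(seq_len(H), H, W)
    top_m <- matrix(top_env, H, W, byrow = TRUE)
    bot_m <- matrix(bot_env, H, W, byrow = TRUE)
    epi <- !is.na(top_m) & rows >= top_m & rows <= bot_m
    # dermis lies below the junction; filled pixels above the epidermal
    # surface (bright specks shaved off by the envelope smoothing) are
    # background, not dermis
    derm <- filled & !epi & (is.na(bot_m) | rows > bot_m)
  }
  compartment_masks(epidermis = epi, dermis = derm, background = !(epi | derm))
}

#' Extract the dermo-epidermal junction polyline
#'
#' Traces the epidermis-dermis interface: for each sampled column, the deepest
#' epidermis pixel 8-adjacent to the dermis. Column gaps of at most
#' `max_gap_cols` sampled columns are linearly interpolated; larger gaps split
#' the polyline into independent segments (recorded in the `segment` column).
#'
#' @param epidermis_mask,dermis_mask disjoint logical matrices.
#' @param resolution_px column sampling step in pixels.
#' @param max_gap_cols largest run of junction-free sampled columns bridged by
#'   interpolation.
#' @return a `jde_polyline`: data frame with `x`, `y` (pixel coordinates,
#'   strictly increasing x) and `segment`.
#' @export
extract_jde <- function(epidermis_mask, dermis_mask, resolution_px = 1L,
                        max_gap_cols = 5L) {
  if (any(epidermis_mask & dermis_mask))
    abort_field("masks", "epidermis and dermis masks must be disjoint")
  if (!any(epidermis_mask) || !any(dermis_mask))
    abort_field("masks", "both masks must be non-empty")
  check_scalar(resolution_px, "resolution_px", positive = TRUE, integer = TRUE)
  kern <- matrix(1, 3, 3)
  derm_grown <- from_ebi(EBImage::dilate(as_ebi(dermis_mask), kern)) > 0
  adj <- epidermis_mask & derm_grown
  if (!any(adj)) stop("no junction: epidermis and dermis are not adjacent", call. = FALSE)
  cols <- seq(1L, ncol(epidermis_mask), by = resolution_px)
  y <- vapply(cols, function(cc) {
    r <- which(adj[, cc])
    if (length(r) == 0) NA_real_ else max(r)
  }, numeric(1))
  ok <- !is.na(y)
  first <- which(ok)[1]; last <- rev(which(ok))[1]
  cols <- cols[first:last]; y <- y[first:last]; ok <- ok[first:last]
  # segment breaks at NA runs longer than max_gap_cols
  seg <- integer(length(cols)); cur <- 1L; run <- 0L
  for (i in seq_along(cols)) {
    if (is.na(y[i])) run <- run + 1L
    else {
      if (run > max_gap_cols) cur <- cur + 1L
      run <- 0L
    }
    seg[i] <- cur
  }
  out <- NULL
  for (sgi in unique(seg[ok])) {
    sel <- seg == sgi
    xi <- cols[sel]; yi <- y[sel]
    if (sum(!is.na(yi)) == 1) { # single column: keep the point
      out <- rbind(out, data.frame(x = xi[!is.na(yi)], y = yi[!is.na(yi)],
                                   segment = sgi))
      next
    }
    keep <- xi >= min(xi[!is.na(yi)]) & xi <= max(xi[!is.na(yi)])
    xi <- xi[keep]; yi <- yi[keep]
    yi <- approx(xi[!is.na(yi)], yi[!is.na(yi)], xout = xi)$y
    out <- rbind(out, data.frame(x = xi, y = yi, segment = sgi))
  }
  rownames(out) <- NULL
  structure(out, class = c("jde_polyline", "data.frame"))
}

validate_jde <- function(jde) {
  if (!inherits(jde, "data.frame") || nrow(jde) < 2L)
    abort_field("jde", "polyline must have at least 2 points")
  if (any(diff(jde$x) <= 0 & diff(c(0, jde$segment[-1] != jde$segment[-nrow(jde)])) == 0))
    abort_field("jde", "x must be strictly increasing within a segment")
  invisible(jde)
}

#' Basal-band mask around the junction
#'
#' All epidermis pixels within `band_width_um` (Euclidean distance, converted
#' through the pixel size) of the JDE polyline.
#'
#' @param epidermis_mask logical matrix.
#' @param jde a `jde_polyline` from [extract_jde()] (or the ground-truth
#'   polyline as a data frame with `x`/`y` or `x_px`/`y_px` columns).
#' @param band_width_um band width in micrometres (default 15).
#' @param pixel_size_um micrometres per pixel.
#' @return logical matrix, subset of `epidermis_mask`.
#' @export
basal_band <- function(epidermis_mask, jde, band_width_um = 15, pixel_size_um) {
  check_scalar(band_width_um, "band_width_um", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  xj <- if ("x" %in% names(jde)) jde$x else jde$x_px
  yj <- if ("y" %in% names(jde)) jde$y else jde$y_px
  H <- nrow(epidermis_mask); W <- ncol(epidermis_mask)
  ref <- matrix(1, H, W)
  cc <- pmin(pmax(round(xj), 1L), W)
  rr <- pmin(pmax(round(yj), 1L), H)
  ref[(cc - 1L) * H + rr] <- 0
  d <- from_ebi(EBImage::distmap(as_ebi(ref)))
  epidermis_mask & (d * pixel_size_um <= band_width_um)
}
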