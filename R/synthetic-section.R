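#' Specification of a synthetic marker channel
#'
#' Describes one immunofluorescence-like channel of a synthetic section.
#' `compartment_intensity` gives the mean rendered intensity per tissue
#' compartment. For `localization = "nuclear"` the map value is the intensity
#' of *positive* nuclei in that compartment; everything else (and negative
#' nuclei) sits at the `background` value, and `positive_fraction` gives the
#' per-compartment probability that a nucleus is positive. For membrane or
#' cytoplasmic markers the compartment is filled diffusely at the map value
#' (the localization is recorded but both are rendered as a diffuse fill).
#'
#' @param name channel name.
#' @param localization one of `"nuclear"`, `"membrane"`, `"cytoplasmic"`.
#' @param compartment_intensity named numeric vector over
#'   `c("basal","suprabasal","dermis","gap","background")`, values in \[0,1\].
#'   Missing compartments default to the `background` value (default 0).
#' @param positive_fraction named numeric vector in \[0,1\] over compartments
#'   (nuclear markers only).
#' @param noise_sd Gaussian pixel noise SD added to the channel.
#' @param abnormal_scale multiplier applied to tissue intensities inside
#'   abnormal intervals (e.g. 0.5 halves a basal marker inside dysplasia).
#' @param abnormal_positive_fraction optional per-compartment positivity used
#'   inside abnormal intervals instead of `positive_fraction`.
#' @return an object of class `marker_spec`.
#' @export
marker_spec <- function(name, localization = c("nuclear", "membrane", "cytoplasmic"),
                        compartment_intensity, positive_fraction = NULL,
                        noise_sd = 0.02, abnormal_scale = 1,
                        abnormal_positive_fraction = NULL) {
  localization <- match.arg(localization)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_field("name", "must be a non-empty string")
  comps <- c("basal", "suprabasal", "dermis", "gap", "background")
  ci <- rep(if ("background" %in% names(compartment_intensity))
    compartment_intensity[["background"]] else 0, length(comps))
  names(ci) <- comps
  ci[names(compartment_intensity)] <- compartment_intensity
  if (any(ci < 0 | ci > 1)) abort_field("compartment_intensity", "values must lie in [0,1]")
  pf <- stats::setNames(rep(0, length(comps)), comps)
  if (!is.null(positive_fraction)) {
    if (any(positive_fraction < 0 | positive_fraction > 1))
      abort_field("positive_fraction", "values must lie in [0,1]")
    pf[names(positive_fraction)] <- positive_fraction
  }
  apf <- NULL
  if (!is.null(abnormal_positive_fraction)) {
    apf <- pf
    if (any(abnormal_positive_fraction < 0 | abnormal_positive_fraction > 1))
      abort_field("abnormal_positive_fraction", "values must lie in [0,1]")
    apf[names(abnormal_positive_fraction)] <- abnormal_positive_fraction
  }
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(abnormal_scale, "abnormal_scale", nonneg = TRUE)
  structure(list(name = name, localization = localization,
                 compartment_intensity = ci, positive_fraction = pf,
                 noise_sd = noise_sd, abnormal_scale = abnormal_scale,
                 abnormal_positive_fraction = apf),
            class = "marker_spec")
}

#' Specification of a synthetic skin section
#'
#' Parameters of the synthetic section generator. The section emulates a
#' cross-section of regenerated skin: a sinusoidal dermo-epidermal junction
#' (JDE), a basal layer of elliptical nuclei whose major axes deviate from the
#' local JDE normal by a wrapped-normal angle with SD `1/sqrt(polarity_concentration)`
#' radians (`0` = uniform orientations), stratified suprabasal layers, a
#' sparse dermis, dark elliptical intercellular gaps, and optional marker
#' channels.
#'
#' @param width_px,height_px raster size in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param jde_amplitude_um,jde_wavelength_um sinusoid parameters of the JDE.
#' @param epidermis_thickness_um epidermis thickness (surface to JDE).
#' @param basal_nucleus_axis_ratio major/minor axis ratio of basal nuclei
#'   (major axis fixed at 10 um).
#' @param polarity_concentration angular concentration of basal nuclei about
#'   the JDE normal; 0 gives uniform orientations.
#' @param target_gap_fraction intercellular-space area fraction of the
#'   epidermis inside abnormal intervals (or everywhere when there are none).
#' @param normal_gap_fraction gap fraction outside abnormal intervals
#'   (ignored when there are no abnormal intervals).
#' @param marker_specs list of [marker_spec()] objects.
#' @param abnormal_intervals_um list of `c(start, end)` intervals (um along
#'   the section axis) inside which basal orientations are uniform on
#'   \[0, 90\] and the gap fraction is `target_gap_fraction`.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param basal_spacing_um mean spacing of basal nuclei along the JDE
#'   (default 5.5 um, about 145 basal nuclei per 800 um).
#' @param basal_depth_um depth of the basal compartment above the JDE.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(width_px = 1600L, height_px = 520L, pixel_size_um = 0.5,
                         jde_amplitude_um = 10, jde_wavelength_um = 300,
                         epidermis_thickness_um = 80,
                         basal_nucleus_axis_ratio = 2.5,
                         polarity_concentration = 8,
                         target_gap_fraction = 0.02,
                         normal_gap_fraction = 0.02,
                         marker_specs = list(),
                         abnormal_intervals_um = list(),
                         seed = 1L,
                         basal_spacing_um = 5.5,
                         basal_depth_um = 14) {
  check_scalar(width_px, "width_px", positive = TRUE, integer = TRUE)
  check_scalar(height_px, "height_px", positive = TRUE, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(jde_amplitude_um, "jde_amplitude_um", nonneg = TRUE)
  check_scalar(jde_wavelength_um, "jde_wavelength_um", positive = TRUE)
  check_scalar(epidermis_thickness_um, "epidermis_thickness_um", positive = TRUE)
  check_scalar(basal_nucleus_axis_ratio, "basal_nucleus_axis_ratio", lo = 1)
  check_scalar(polarity_concentration, "polarity_concentration", nonneg = TRUE)
  check_scalar(target_gap_fraction, "target_gap_fraction", lo = 0, hi = 1)
  check_scalar(normal_gap_fraction, "normal_gap_fraction", lo = 0, hi = 1)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(basal_spacing_um, "basal_spacing_um", positive = TRUE)
  check_scalar(basal_depth_um, "basal_depth_um", positive = TRUE)
  width_um <- width_px * pixel_size_um
  height_um <- height_px * pixel_size_um
  if (!is.list(abnormal_intervals_um))
    abort_field("abnormal_intervals_um", "must be a list of c(start, end)")
  for (iv in abnormal_intervals_um) {
    if (length(iv) != 2L || iv[1] >= iv[2])
      abort_field("abnormal_intervals_um", "each interval must be c(start, end) with start < end")
    if (iv[1] < 0 || iv[2] > width_um)
      abort_field("abnormal_intervals_um",
                  sprintf("intervals must lie within [0, %g] um", width_um))
  }
  if (!all(vapply(marker_specs, inherits, logical(1), "marker_spec")))
    abort_field("marker_specs", "must be a list of marker_spec objects")
  needed <- jde_amplitude_um * 2 + epidermis_thickness_um + 0.15 * height_um + 20
  if (needed > height_um)
    abort_field("height_px", "too small to fit epidermis, JDE relief and dermis")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 jde_amplitude_um = jde_amplitude_um,
                 jde_wavelength_um = jde_wavelength_um,
                 epidermis_thickness_um = epidermis_thickness_um,
                 basal_nucleus_axis_ratio = basal_nucleus_axis_ratio,
                 polarity_concentration = polarity_concentration,
                 target_gap_fraction = target_gap_fraction,
                 normal_gap_fraction = normal_gap_fraction,
                 marker_specs = marker_specs,
                 abnormal_intervals_um = abnormal_intervals_um,
                 seed = as.integer(seed),
                 basal_spacing_um = basal_spacing_um,
                 basal_depth_um = basal_depth_um),
            class = "section_spec")
}

# compartment codes used in the ground-truth label raster
COMP_BACKGROUND <- 0L; COMP_BASAL <- 1L; COMP_SUPRABASAL <- 2L
COMP_DERMIS <- 3L; COMP_GAP <- 4L
COMP_NAMES <- c("background", "basal", "suprabasal", "dermis", "gap")

comp_name <- function(code) COMP_NAMES[code + 1L]

in_intervals <- function(x, intervals) {
  hit <- rep(FALSE, length(x))
  for (iv in intervals) hit <- hit | (x >= iv[1] & x < iv[2])
  hit
}

#' Generate a synthetic skin section with exact ground truth
#'
#' Renders a multi-channel raster (DAPI-like nuclear channel, one channel per
#' [marker_spec()], and an HES-like RGB composite in channels `hes_r`,
#' `hes_g`, `hes_b`) together with a ground-truth object recording every
#' nucleus (centroid, true angle to the JDE in \[0, 90\] degrees, compartment,
#' per-marker positivity), the true JDE polyline, the gap mask with realized
#' gap fractions, and the abnormal intervals. Output is bit-identical for a
#' fixed `spec$seed`; nucleus and gap geometry do not change when marker
#' specs are added or edited (markers use a separate RNG sub-stream).
#'
#' @param spec a [section_spec()].
#' @return a list with elements `section` (a [section_image()]) and `truth`
#'   (class `ground_truth`).
#' @export
generate_section <- function(spec) {
  if (!inherits(spec, "section_spec")) spec <- do.call(section_spec, spec)
  W <- spec$width_px; H <- spec$height_px; px <- spec$pixel_size_um
  width_um <- W * px; height_um <- H * px
  A <- spec$jde_amplitude_um; wav <- spec$jde_wavelength_um
  thick <- spec$epidermis_thickness_um
  y0 <- A + thick + 0.15 * height_um
  jde_um <- function(x_um) y0 + A * sin(2 * pi * x_um / wav)
  jde_slope <- function(x_um) A * (2 * pi / wav) * cos(2 * pi * x_um / wav)

  xs_um <- ((1:W) - 0.5) * px
  jde_row <- jde_um(xs_um) / px + 0.5
  surface_row <- jde_row - thick / px
  basal_top_row <- jde_row - spec$basal_depth_um / px
  abn_col <- in_intervals(xs_um, spec$abnormal_intervals_um)

  rows <- matrix(seq_len(H), H, W)
  jr <- matrix(jde_row, H, W, byrow = TRUE)
  sr <- matrix(surface_row, H, W, byrow = TRUE)
  br <- matrix(basal_top_row, H, W, byrow = TRUE)
  comp <- matrix(COMP_BACKGROUND, H, W)
  comp[rows > jr] <- COMP_DERMIS
  comp[rows >= sr & rows <= jr] <- COMP_SUPRABASAL
  comp[rows > br & rows <= jr] <- COMP_BASAL

  geom <- with_seed(spec$seed, {
    sigma_deg <- if (spec$polarity_concentration > 0)
      (180 / pi) / sqrt(spec$polarity_concentration) else Inf
    # --- basal nuclei along the JDE, depth-staggered to avoid overlap
    bx <- seq(4, width_um - 4, by = spec$basal_spacing_um)
    bx <- pmin(pmax(bx + runif(length(bx), -1, 1), 4), width_um - 4)
    nb <- length(bx)
    tan_rad <- atan2(jde_slope(bx), 1)
    tan_deg <- tan_rad * 180 / pi
    off <- ifelse(seq_len(nb) %% 2L == 0L, 6, 10)
    cx_um <- bx + off * sin(tan_rad)
    cy_um <- jde_um(bx) - off * cos(tan_rad)
    abn <- in_intervals(bx, spec$abnormal_intervals_um)
    uniform <- abn | !is.finite(sigma_deg)
    u <- runif(nb, 0, 90); s <- sample(c(-1, 1), nb, replace = TRUE)
    delta <- if (is.finite(sigma_deg)) rnorm(nb, 0, sigma_deg) else rep(0, nb)
    axis_deg <- ifelse(uniform, (tan_deg + s * u) %% 180,
                       (tan_deg + 90 + delta) %% 180)
    true_angle <- ifelse(uniform, u, fold_angle(90 + delta))
    a_maj <- 5; a_min <- 5 / spec$basal_nucleus_axis_ratio
    basal <- data.frame(x_um = cx_um, y_um = cy_um, compartment = "basal",
                        axis_deg = axis_deg, angle_jde_true_deg = true_angle,
                        a_um = a_maj, b_um = a_min, stringsAsFactors = FALSE)
    # --- suprabasal nuclei: flattened, roughly parallel to the surface
    supra <- NULL
    depths <- seq(spec$basal_depth_um + 5, thick - 6, by = 7)
    for (d in depths) {
      sx <- seq(4, width_um - 4, by = 7)
      sx <- pmin(pmax(sx + runif(length(sx), -2, 2), 4), width_um - 4)
      st <- atan2(jde_slope(sx), 1) * 180 / pi
      ax <- (st + rnorm(length(sx), 0, 15)) %% 180
      supra <- rbind(supra, data.frame(
        x_um = sx, y_um = jde_um(sx) - d, compartment = "suprabasal",
        axis_deg = ax, angle_jde_true_deg = fold_angle(ax - st),
        a_um = 4, b_um = 2.5, stringsAsFactors = FALSE))
    }
    # --- sparse dermal nuclei, uniform orientation
    dermis_depth <- height_um - (y0 + A)
    nd <- max(0L, round(width_um * dermis_depth / 900))
    dx <- runif(nd, 4, width_um - 4)
    dt <- atan2(jde_slope(dx), 1) * 180 / pi
    dy <- runif(nd, jde_um(dx) + 6, height_um - 6)
    dax <- runif(nd, 0, 180)
    derm <- data.frame(x_um = dx, y_um = dy, compartment = "dermis",
                       axis_deg = dax, angle_jde_true_deg = fold_angle(dax - dt),
                       a_um = 3.5, b_um = 2.25, stringsAsFactors = FALSE)
    nuclei <- rbind(basal, supra, derm)
    nuclei$id <- seq_len(nrow(nuclei))
    nuclei$x_px <- nuclei$x_um / px + 0.5
    nuclei$y_px <- nuclei$y_um / px + 0.5

    nuc_pix <- vector("list", nrow(nuclei))
    nuc_mask <- matrix(FALSE, H, W)
    basal_mask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(nuclei))) {
      p <- ellipse_pixels(nuclei$x_px[i], nuclei$y_px[i],
                          nuclei$a_um[i] / px, nuclei$b_um[i] / px,
                          nuclei$axis_deg[i], H, W)
      nuc_pix[[i]] <- p
      nuc_mask[p] <- TRUE
      if (nuclei$compartment[i] == "basal") basal_mask[p] <- TRUE
    }

    # --- intercellular gaps: dark ellipses rejection-placed in the epidermis.
    # Gaps are intercellular, i.e. interior to the tissue: a thin compact
    # surface margin (3 um, horny-layer-like) is kept gap-free so spaces do
    # not breach the epidermal surface.
    epi_mask <- comp == COMP_BASAL | comp == COMP_SUPRABASAL
    interior <- rows >= sr + 3 / px
    gap_mask <- matrix(FALSE, H, W)
    colmat <- matrix(abn_col, H, W, byrow = TRUE)
    if (length(spec$abnormal_intervals_um) > 0)
      regions <- list(list(name = "abnormal", mask = epi_mask & colmat,
                           frac = spec$target_gap_fraction),
                      list(name = "normal", mask = epi_mask & !colmat,
                           frac = spec$normal_gap_fraction))
    else
      regions <- list(list(name = "all", mask = epi_mask,
                           frac = spec$target_gap_fraction))
    gap_tab <- NULL
    for (rg in regions) {
      area <- sum(rg$mask)
      target_px <- round(rg$frac * area)
      placed <- 0L
      if (target_px > 0 && area > 0) {
        # gaps may swallow suprabasal cells (acantholysis-like) but never the
        # basal layer, whose nuclei carry the polarity ground truth
        rg$mask <- rg$mask & interior
        elig <- which(rg$mask & !basal_mask)
        max_iter <- ceiling(target_px / 20) * 40 + 200
        it <- 0L
        while (placed < target_px && it < max_iter) {
          it <- it + 1L
          ctr <- elig[sample.int(length(elig), 1L)]
          gy <- (ctr - 1L) %% H + 1L; gx <- (ctr - 1L) %/% H + 1L
          ga <- runif(1, 2.5, 5) / px; gb <- runif(1, 1.5, 3) / px
          gth <- runif(1, 0, 180)
          p <- ellipse_pixels(gx, gy, ga, gb, gth, H, W)
          if (length(p) == 0 || !all(rg$mask[p]) || any(basal_mask[p])) next
          new <- p[!gap_mask[p]]
          if (placed + length(new) > target_px + 40) next
          gap_mask[p] <- TRUE
          placed <- placed + length(new)
        }
      }
      gap_tab <- rbind(gap_tab, data.frame(
        region = rg$name, epidermis_px = area, target = rg$frac,
        realized = if (area > 0) placed / area else NA_real_))
    }
    # drop nuclei swallowed by a gap
    hit <- vapply(nuc_pix, function(p) length(p) > 0 && any(gap_mask[p]),
                  logical(1))
    if (any(hit)) {
      nuclei <- nuclei[!hit, , drop = FALSE]
      nuclei$id <- seq_len(nrow(nuclei))
      nuc_pix <- nuc_pix[!hit]
      nuc_mask <- matrix(FALSE, H, W)
      for (p in nuc_pix) nuc_mask[p] <- TRUE
    }
    list(nuclei = nuclei, nuc_pix = nuc_pix, nuc_mask = nuc_mask,
         gap_mask = gap_mask, gap_tab = gap_tab)
  })

  comp[geom$gap_mask] <- COMP_GAP
  nuclei <- geom$nuclei
  abn_nuc <- in_intervals(nuclei$x_um, spec$abnormal_intervals_um)

  # --- DAPI-like nuclear channel and HES-like composite (geometry stream)
  chans <- with_seed(spec$seed + 1L, {
    dapi <- matrix(0.02, H, W)
    bright <- runif(nrow(nuclei), 0.7, 0.95)
    for (i in seq_len(nrow(nuclei))) dapi[geom$nuc_pix[[i]]] <- bright[i]
    dapi <- quantize16(dapi + rnorm(length(dapi), 0, 0.03))
    hes_cols <- rbind(background = c(0.04, 0.04, 0.04),
                      basal = c(0.85, 0.62, 0.66),
                      suprabasal = c(0.85, 0.62, 0.66),
                      dermis = c(0.62, 0.47, 0.52),
                      gap = c(0.04, 0.045, 0.04))
    nuc_col <- c(0.32, 0.22, 0.45)
    hes <- lapply(1:3, function(k) {
      m <- matrix(hes_cols[comp_name(comp), k], H, W)
      m[geom$nuc_mask] <- nuc_col[k]
      quantize16(m + rnorm(length(m), 0, 0.01))
    })
    list(dapi = dapi, hes = hes)
  })

  channels <- list(dapi = chans$dapi)
  marker_means <- list()
  for (mi in seq_along(spec$marker_specs)) {
    ms <- spec$marker_specs[[mi]]
    mk <- with_seed(spec$seed + 7919L * mi, {
      ci <- ms$compartment_intensity
      scale_col <- ifelse(abn_col, ms$abnormal_scale, 1)
      scmat <- matrix(scale_col, H, W, byrow = TRUE)
      if (ms$localization == "nuclear") {
        m <- matrix(ci[["background"]], H, W)
        pf <- ms$positive_fraction[nuclei$compartment]
        if (!is.null(ms$abnormal_positive_fraction))
          pf[abn_nuc] <- ms$abnormal_positive_fraction[nuclei$compartment[abn_nuc]]
        pos <- runif(nrow(nuclei)) < pf
        for (i in which(pos)) {
          val <- ci[[nuclei$compartment[i]]] * (if (abn_nuc[i]) ms$abnormal_scale else 1)
          m[geom$nuc_pix[[i]]] <- val
        }
      } else {
        m <- matrix(ci[comp_name(comp)], H, W)
        tissue <- comp != COMP_BACKGROUND
        m[tissue] <- m[tissue] * scmat[tissue]
        pos <- rep(NA, nrow(nuclei))
      }
      list(raster = quantize16(m + rnorm(length(m), 0, ms$noise_sd)), pos = pos)
    })
    channels[[ms$name]] <- mk$raster
    if (ms$localization == "nuclear") nuclei[[paste0("pos_", ms$name)]] <- mk$pos
    marker_means[[ms$name]] <- list(localization = ms$localization,
                                    compartment_intensity = ms$compartment_intensity,
                                    abnormal_scale = ms$abnormal_scale)
  }
  channels$hes_r <- chans$hes[[1]]
  channels$hes_g <- chans$hes[[2]]
  channels$hes_b <- chans$hes[[3]]

  global_gap <- sum(geom$gap_mask) / sum(comp == COMP_BASAL | comp == COMP_SUPRABASAL |
                                           comp == COMP_GAP)
  truth <- structure(list(
    nuclei = nuclei[, c("id", "x_px", "y_px", "x_um", "y_um", "compartment",
                        "axis_deg", "angle_jde_true_deg",
                        grep("^pos_", names(nuclei), value = TRUE))],
    jde = data.frame(x_px = seq_len(W), y_px = jde_row),
    compartments = comp,
    gap_mask = geom$gap_mask,
    gap_fraction = list(global = global_gap, by_region = geom$gap_tab),
    abnormal_intervals_um = spec$abnormal_intervals_um,
    marker_means = marker_means,
    spec = spec), class = "ground_truth")
  list(section = section_image(channels, px), truth = truth)
}

#' Ground-truth compartment masks
#'
#' Converts a ground-truth label raster into the [compartment_masks()]
#' container used by the measurement pipeline (synthetic mode). Gap pixels
#' belong to the epidermis mask, as they are intercellular spaces within it.
#'
#' @param truth the `truth` element returned by [generate_section()].
#' @return a `compartment_masks` object with `basal_band` filled in.
#' @export
truth_masks <- function(truth) {
  comp <- truth$compartments
  epi <- comp == COMP_BASAL | comp == COMP_SUPRABASAL | comp == COMP_GAP
  H <- nrow(comp); W <- ncol(comp)
  rows <- matrix(seq_len(H), H, W)
  jr <- matrix(truth$jde$y_px, H, W, byrow = TRUE)
  band <- epi & rows > (jr - truth$spec$basal_depth_um / truth$spec$pixel_size_um) &
    rows <= jr
  compartment_masks(epidermis = epi, dermis = comp == COMP_DERMIS,
                    background = comp == COMP_BACKGROUND, basal_band = band)
}

#' Analytic polarity distribution of the generator
#'
#' Closed-form properties of the basal-nucleus angle-to-JDE distribution
#' implied by a `polarity_concentration`: deviations from the JDE normal are
#' wrapped normal with SD `1/sqrt(concentration)` radians, so the measured
#' angle is `90 - W` where `W` is the folded deviation. Used to freeze
#' expected values for recovery tests.
#'
#' @param concentration `polarity_concentration` of the generator; 0 means
#'   uniform on \[0, 90\].
#' @return list with `median_deg`, `class_mass` (named fractions for the
#'   nearly-parallel, oblique and nearly-perpendicular classes) and `cdf`, the
#'   CDF of the angle on \[0, 90\].
#' @export
polarity_analytic <- function(concentration) {
  check_scalar(concentration, "concentration", nonneg = TRUE)
  if (concentration == 0) {
    cdf <- function(a) pmin(pmax(a / 90, 0), 1)
    return(list(median_deg = 45,
                class_mass = c(nearly_parallel = 1 / 3, oblique = 1 / 3,
                               nearly_perpendicular = 1 / 3),
                cdf = cdf))
  }
  sigma <- (180 / pi) / sqrt(concentration)
  ks <- -50:50
  cdf_w <- function(w) # P(folded deviation <= w), w in [0, 90]
    vapply(w, function(wi)
      sum(pnorm((180 * ks + wi) / sigma) - pnorm((180 * ks - wi) / sigma)),
      numeric(1))
  cdf <- function(a) 1 - cdf_w(90 - pmin(pmax(a, 0), 90))
  w50 <- uniroot(function(w) cdf_w(w) - 0.5, c(0, 90))$root
  mass <- c(nearly_parallel = 1 - cdf_w(60),
            oblique = cdf_w(60) - cdf_w(30),
            nearly_perpendicular = cdf_w(30))
  list(median_deg = 90 - w50, class_mass = mass, cdf = cdf)
}
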