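#' Multi-channel section image
#'
#' A `section_image` holds named, equally shaped 2-D rasters (values in
#' \[0, 1\]) plus the physical pixel size. The package convention throughout is
#' `matrix[row, col]` = `(y, x)`, origin at the top-left, y increasing
#' downward, with the section axis running along the columns and the epidermis
#' above the dermis.
#'
#' @param channels named list of numeric matrices of identical dimension.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @return An object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    abort_field("channels", "must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m), logical(1))))
    abort_field("channels", "every channel must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    abort_field("channels", "all channels must share the same shape")
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

section_dim <- function(section) dim(section$channels[[1]])

get_channel <- function(section, name) {
  if (!name %in% names(section$channels))
    abort_field("channel", sprintf("'%s' not present (have: %s)", name,
                                   paste(names(section$channels), collapse = ", ")))
  section$channels[[name]]
}

#' Stack the HES-like composite channels into an RGB array
#'
#' @param section a [section_image()] with `hes_r`, `hes_g`, `hes_b` channels.
#' @return numeric array `height x width x 3`.
#' @export
hes_rgb <- function(section) {
  stopifnot(all(c("hes_r", "hes_g", "hes_b") %in% names(section$channels)))
  d <- section_dim(section)
  array(c(section$channels$hes_r, section$channels$hes_g,
          section$channels$hes_b), dim = c(d, 3L))
}

# Grayscale view used for tissue segmentation: luminance of the HES composite
# when present, otherwise the named nuclear channel.
section_gray <- function(section, nuclear_channel = "dapi") {
  if (all(c("hes_r", "hes_g", "hes_b") %in% names(section$channels)))
    grayscale(hes_rgb(section))
  else get_channel(section, nuclear_channel)
}

rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE] # 90 deg clockwise
rot180_mat <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
flipv_mat <- function(m) m[nrow(m):1, , drop = FALSE]

#' Rotate a section image by a multiple of 90 degrees
#'
#' Exact (no interpolation) rotation of every channel; used to test the
#' rotation invariance of downstream angle measurements.
#'
#' @param section a [section_image()].
#' @param degrees one of 90, 180, 270 (clockwise).
#' @return the rotated `section_image`.
#' @export
rotate_section <- function(section, degrees) {
  if (!degrees %in% c(90, 180, 270)) abort_field("degrees", "must be 90, 180 or 270")
  f <- switch(as.character(degrees),
              "90" = rot90_mat,
              "180" = rot180_mat,
              "270" = function(m) rot90_mat(rot180_mat(m)))
  section_image(lapply(section$channels, f), section$pixel_size_um)
}

#' Auto-orient a section to the canonical frame
#'
#' Rotates/flips the image so the section's long axis is horizontal and the
#' epidermis (the brightest tissue class) lies above the dermis. All
#' downstream operations assume this frame.
#'
#' @param section a [section_image()].
#' @param nuclear_channel channel used when no HES composite is present.
#' @return the re-oriented `section_image`; the transform applied is recorded
#'   in `attr(, "orientation")` as a character vector of elementary steps.
#' @export
auto_orient <- function(section, nuclear_channel = "dapi") {
  steps <- character(0)
  d <- section_dim(section)
  if (d[1] > d[2]) { # portrait: make landscape
    section <- section_image(lapply(section$channels, rot90_mat),
                             section$pixel_size_um)
    steps <- c(steps, "rot90cw")
  }
  gray <- section_gray(section, nuclear_channel)
  tis <- gray > EBImage::otsu(as_ebi(gray), range = c(0, 1))
  tis <- largest_component(tis)
  if (!any(tis)) return(structure(section, orientation = steps))
  v <- gray[tis]
  bright <- tis & gray > stats::median(v)
  dark <- tis & !bright
  ybright <- mean(row(gray)[bright])
  ydark <- if (any(dark)) mean(row(gray)[dark]) else Inf
  if (ybright > ydark) { # epidermis below: flip vertically
    section <- section_image(lapply(section$channels, flipv_mat),
                             section$pixel_size_um)
    steps <- c(steps, "flipv")
  }
  structure(section, orientation = steps)
}
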