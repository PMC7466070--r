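spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$marker_specs <- lapply(spec$marker_specs, unclass)
  out
}

spec_from_list <- function(lst) {
  lst$marker_specs <- lapply(lst$marker_specs, function(m) {
    marker_spec(name = m$name, localization = m$localization,
                compartment_intensity = unlist(m$compartment_intensity),
                positive_fraction = unlist(m$positive_fraction),
                noise_sd = m$noise_sd, abnormal_scale = m$abnormal_scale,
                abnormal_positive_fraction =
                  if (is.null(m$abnormal_positive_fraction)) NULL
                  else unlist(m$abnormal_positive_fraction))
  })
  lst$abnormal_intervals_um <- lapply(lst$abnormal_intervals_um, as.numeric)
  do.call(section_spec, lst)
}

#' Write a synthetic fixture to disk
#'
#' Stores every channel as a lossless 16-bit grayscale TIFF, the HES-like
#' composite as an RGB TIFF, the ground-truth label rasters as 8-bit TIFFs,
#' the remaining ground truth as JSON, and a manifest (file list plus the
#' generating [section_spec()], from which the fixture can be regenerated
#' exactly).
#'
#' @param section a [section_image()].
#' @param truth the matching `ground_truth`.
#' @param directory existing, writable directory.
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(section, truth, directory) {
  if (!dir.exists(directory))
    stop(sprintf("directory does not exist: %s", directory), call. = FALSE)
  files <- character(0)
  for (ch in names(section$channels)) {
    f <- file.path(directory, paste0("channel_", ch, ".tif"))
    tiff::writeTIFF(section$channels[[ch]], f, bits.per.sample = 16L)
    files <- c(files, basename(f))
  }
  f <- file.path(directory, "hes_composite.tif")
  tiff::writeTIFF(hes_rgb(section), f, bits.per.sample = 16L)
  files <- c(files, basename(f))
  f <- file.path(directory, "truth_compartments.tif")
  tiff::writeTIFF(truth$compartments / 255, f, bits.per.sample = 8L)
  files <- c(files, basename(f))
  f <- file.path(directory, "truth_gap_mask.tif")
  tiff::writeTIFF(truth$gap_mask * 1, f, bits.per.sample = 8L)
  files <- c(files, basename(f))
  truth_json <- list(nuclei = truth$nuclei, jde = truth$jde,
                     gap_fraction = truth$gap_fraction,
                     abnormal_intervals_um = truth$abnormal_intervals_um,
                     marker_means = truth$marker_means)
  jsonlite::write_json(truth_json, file.path(directory, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  files <- c(files, "truth.json")
  manifest <- list(pixel_size_um = section$pixel_size_um,
                   channels = names(section$channels),
                   files = files, spec = spec_to_list(truth$spec))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return list with `section`, `truth` (rasters and tables restored; the
#'   full `ground_truth` can also be regenerated from `manifest$spec`) and
#'   `manifest`.
#' @export
read_fixture <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("no manifest.json in: %s", directory), call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  channels <- list()
  for (ch in manifest$channels)
    channels[[ch]] <- tiff::readTIFF(file.path(directory, paste0("channel_", ch, ".tif")))
  section <- section_image(channels, manifest$pixel_size_um)
  tj <- jsonlite::read_json(file.path(directory, "truth.json"), simplifyVector = TRUE)
  comp <- round(tiff::readTIFF(file.path(directory, "truth_compartments.tif")) * 255)
  storage.mode(comp) <- "integer"
  gap <- tiff::readTIFF(file.path(directory, "truth_gap_mask.tif")) > 0.5
  spec <- spec_from_list(manifest$spec)
  truth <- structure(list(nuclei = tj$nuclei, jde = tj$jde,
                          compartments = comp, gap_mask = gap,
                          gap_fraction = tj$gap_fraction,
                          abnormal_intervals_um = tj$abnormal_intervals_um,
                          marker_means = tj$marker_means, spec = spec),
                     class = "ground_truth")
  list(section = section, truth = truth, manifest = manifest)
}
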