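## On-disk formats. Scan datasets are stored as a single RDS container with
## a fixed logical layout: the counts array (integer, masked pixels = -1),
## the detector/scan metadata under the same attribute names used
## throughout (energy_keV, distance_m, pixel_size_m, beam_center,
## det_shape, mask, exposure_ms, step_y_um, step_z_um), and, for simulated
## data, the ground-truth phantom under "truth". Images go to TIFF and
## tables to CSV.

SCAN_FORMAT_VERSION <- 1L

#' Write a scan dataset to disk
#'
#' @param stack A `pattern_stack`.
#' @param path Output file path (conventionally `.scan.rds`).
#' @return `path`, invisibly.
#' @export
write_scan <- function(stack, path) {
  stopifnot(inherits(stack, "pattern_stack"))
  payload <- list(
    format_version = SCAN_FORMAT_VERSION,
    counts = stack$counts,
    energy_keV = stack$geom$energy_keV,
    distance_m = stack$geom$distance_m,
    pixel_size_m = stack$geom$pixel_size_m,
    beam_center = stack$geom$beam_center,
    det_shape = stack$geom$shape,
    mask = stack$geom$mask,
    exposure_ms = stack$exposure_ms,
    step_y_um = stack$grid$step_y_um,
    step_z_um = stack$grid$step_z_um,
    n_rows = stack$grid$n_rows,
    n_cols = stack$grid$n_cols,
    seed = stack$seed,
    truth = stack$truth)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a scan dataset from disk
#'
#' @param path File written by [write_scan()].
#' @return A `pattern_stack` (with `truth` attached when present).
#' @export
read_scan <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format_version, SCAN_FORMAT_VERSION))
    stop_invalid("unsupported scan file version")
  geom <- detector_geometry(payload$energy_keV, payload$distance_m,
                            payload$pixel_size_m, payload$beam_center,
                            payload$det_shape, payload$mask)
  grid <- scan_grid(payload$n_rows, payload$n_cols, payload$step_y_um,
                    payload$step_z_um, payload$exposure_ms)
  structure(list(counts = payload$counts, grid = grid, geom = geom,
                 exposure_ms = payload$exposure_ms, truth = payload$truth,
                 seed = payload$seed), class = "pattern_stack")
}

#' Write a float-valued map as 32-bit TIFF
#'
#' TIFF storage here is limited to the [0, 1] range, so values are
#' affinely rescaled and the mapping recorded in a plain-text `.scale`
#' sidecar (JSON: min, max). Invalid (`NA`) pixels are stored as 0 and
#' valid pixels occupy [0.1, 1]; [read_float_tiff()] reverses the mapping.
#'
#' @param x Numeric matrix (NAs allowed).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(x, path) {
  lo <- suppressWarnings(min(x, na.rm = TRUE))
  hi <- suppressWarnings(max(x, na.rm = TRUE))
  if (!is.finite(lo)) { lo <- 0; hi <- 0 }
  span <- if (hi > lo) hi - lo else 1
  enc <- pmin(pmax(0.1 + 0.9 * (x - lo) / span, 0.1), 1)
  enc[is.na(x)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(min = lo, max = hi), paste0(path, ".scale"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [write_float_tiff()]
#'
#' @param path TIFF path (a `.scale` sidecar must sit next to it).
#' @return Numeric matrix with NAs restored.
#' @export
read_float_tiff <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".scale"), simplifyVector = TRUE)
  enc <- tiff::readTIFF(path)
  span <- if (sc$max > sc$min) sc$max - sc$min else 1
  out <- sc$min + (enc - 0.1) / 0.9 * span
  out[enc == 0] <- NA_real_
  out
}

#' Write an integer label image as 16-bit TIFF
#'
#' @param x Integer matrix of labels in [0, 65535].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(x, path) {
  if (any(x < 0, na.rm = TRUE) || any(x > 65535, na.rm = TRUE))
    stop_invalid("labels must be in [0, 65535]")
  x[is.na(x)] <- 0
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a radial profile as CSV
#'
#' Columns: `q_nm_inv`, `intensity_per_ms`, `n_pixels`. The intensity
#' column carries whatever normalization the profile has (use
#' [normalize_exposure()] first for per-ms units).
#'
#' @param profile A [radial_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  df <- data.frame(q_nm_inv = profile$q, intensity_per_ms = profile$intensity,
                   n_pixels = profile$n_pixels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a radial profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @return A [radial_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  radial_profile(df$q_nm_inv, df$intensity_per_ms, df$n_pixels)
}
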