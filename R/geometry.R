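## Detector and scan geometry: energy/wavelength conversion, per-pixel
## scattering-vector magnitude q and azimuth, q <-> real-space conversion.
##
## Conventions: detector pixel (0,0) has its corner at the top-left of the
## frame; pixel centers sit at integer + 0.5 offsets; the beam center is
## given in the same fractional-pixel (row, col) frame and may lie outside
## the frame. Azimuth is measured counter-clockwise from the +column axis
## (rows increase downwards on screen, so "up" is +90 degrees). The detector
## is assumed flat and normal to the beam; no solid-angle or polarization
## correction is applied.

#' Planck constant times speed of light, in keV nm
#'
#' CODATA value used for photon energy to wavelength conversion.
#' @export
HC_KEV_NM <- 1.2398419

#' Convert photon energy to wavelength
#'
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in nm (`lambda = hc / E`).
#' @examples
#' wavelength_from_energy(13.0) # ~0.09537 nm
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (!is.numeric(energy_keV) || any(!is.finite(energy_keV)) || any(energy_keV <= 0))
    stop_invalid("photon energy must be positive and finite")
  HC_KEV_NM / energy_keV
}

#' Detector geometry
#'
#' Bundles the quantities needed to map detector pixels to scattering
#' vectors: photon energy, sample-detector distance, pixel size, beam
#' center and a pixel mask.
#'
#' @param energy_keV Photon energy (keV).
#' @param distance_m Sample-detector distance (m).
#' @param pixel_size_m Edge length of the square detector pixels (m).
#' @param beam_center Numeric length-2, beam center as (row, col) in
#'   fractional pixels (top-left corner of the frame is (0, 0)); may lie
#'   outside the frame.
#' @param shape Integer length-2, detector (rows, cols).
#' @param mask Logical matrix of the detector shape; `TRUE` marks pixels
#'   excluded from all analysis (module gaps, beamstop, hot pixels).
#'   Default: nothing masked.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(energy_keV, distance_m, pixel_size_m,
                              beam_center, shape, mask = NULL) {
  check_scalar_positive(energy_keV, "energy_keV")
  check_scalar_positive(distance_m, "distance_m")
  check_scalar_positive(pixel_size_m, "pixel_size_m")
  if (length(beam_center) != 2L || any(!is.finite(beam_center)))
    stop_invalid("`beam_center` must be two finite numbers (row, col)")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop_invalid("`shape` must be two positive integers (rows, cols)")
  if (is.null(mask)) {
    mask <- matrix(FALSE, shape[1], shape[2])
  } else {
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
    if (!identical(dim(mask), shape))
      stop_invalid("`mask` dimensions must equal the detector shape")
  }
  structure(list(
    energy_keV = energy_keV,
    distance_m = distance_m,
    pixel_size_m = pixel_size_m,
    beam_center = as.numeric(beam_center),
    shape = shape,
    mask = mask
  ), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector_geometry: %d x %d px (%.0f um), E = %.3f keV (lambda = %.5f nm), L = %.3f m\n",
    x$shape[1], x$shape[2], x$pixel_size_m * 1e6, x$energy_keV,
    wavelength_from_energy(x$energy_keV), x$distance_m))
  cat(sprintf("  beam center (row, col) = (%.2f, %.2f); %d masked px\n",
              x$beam_center[1], x$beam_center[2], sum(x$mask)))
  invisible(x)
}

#' Scan grid
#'
#' Raster-scan bookkeeping: number of scan positions along each axis, step
#' sizes and exposure per position.
#'
#' @param n_rows,n_cols Scan positions along the slow and fast axis.
#' @param step_y_um,step_z_um Step sizes in micrometres.
#' @param exposure_ms Exposure time per scan position in milliseconds.
#' @return An object of class `scan_grid`.
#' @export
scan_grid <- function(n_rows, n_cols, step_y_um = 0.5, step_z_um = 0.5,
                      exposure_ms = 1.34) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop_invalid("scan grid dimensions must be positive")
  check_scalar_positive(step_y_um, "step_y_um")
  check_scalar_positive(step_z_um, "step_z_um")
  check_scalar_positive(exposure_ms, "exposure_ms")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 step_y_um = step_y_um, step_z_um = step_z_um,
                 exposure_ms = exposure_ms), class = "scan_grid")
}

#' Total number of scan positions in a grid
#'
#' @param grid A [scan_grid()].
#' @return `n_rows * n_cols` as a double (full-window scans exceed
#'   `.Machine$integer.max / 240` pixels comfortably).
#' @export
n_positions <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  as.double(grid$n_rows) * as.double(grid$n_cols)
}

#' Per-pixel scattering vector map
#'
#' For every detector pixel, the scattering-vector magnitude
#' `q = (4*pi/lambda) * sin(theta)` with `theta` half the scattering angle,
#' `theta = arctan(r / L) / 2`, where `r` is the radial distance of the
#' pixel center from the beam center in the detector plane and `L` the
#' sample-detector distance. Azimuth is the planar angle of the pixel about
#' the beam center, counter-clockwise from the +column axis, in [0, 2*pi).
#' The mask plays no role here; it only gates downstream use of pixels.
#'
#' @param geom A [detector_geometry()].
#' @return An object of class `qmap`: list with matrices `q` (nm^-1) and
#'   `azimuth` (rad), both of the detector shape.
#' @export
build_qmap <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  lambda <- wavelength_from_energy(geom$energy_keV)
  rows <- seq_len(geom$shape[1]) - 0.5
  cols <- seq_len(geom$shape[2]) - 0.5
  dr <- rows - geom$beam_center[1]
  dc <- cols - geom$beam_center[2]
  drm <- matrix(dr, geom$shape[1], geom$shape[2])
  dcm <- matrix(dc, geom$shape[1], geom$shape[2], byrow = TRUE)
  r_m <- sqrt(drm^2 + dcm^2) * geom$pixel_size_m
  theta <- 0.5 * atan(r_m / geom$distance_m)
  q <- (4 * pi / lambda) * sin(theta)
  azimuth <- atan2(-drm, dcm) %% (2 * pi)
  structure(list(q = q, azimuth = azimuth), class = "qmap")
}

#' Radial detector distance at which a given q is observed
#'
#' Inverse of the pixel-to-q mapping of [build_qmap()]:
#' `r = L * tan(2 * asin(q * lambda / (4*pi)))`.
#'
#' @param q Scattering-vector magnitudes (nm^-1).
#' @param geom A [detector_geometry()].
#' @return Radial distances from the beam center in metres.
#' @export
q_to_radius <- function(q, geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (any(q < 0)) stop_invalid("q must be non-negative")
  lambda <- wavelength_from_energy(geom$energy_keV)
  s <- q * lambda / (4 * pi)
  if (any(s > 1)) stop_invalid("q beyond the backscattering limit for this wavelength")
  geom$distance_m * tan(2 * asin(s))
}

#' Real-space length corresponding to a scattering vector
#'
#' `d = 2*pi/q`; the mapping is an involution, so the same function converts
#' lengths back to q. The power-law fit range [0.185, 1.723] nm^-1 probes
#' real-space features between 34.0 nm and 3.6 nm.
#'
#' @param q Scattering-vector magnitude(s), nm^-1 (or a length in nm for the
#'   inverse direction).
#' @return `2*pi/q` in nm (or nm^-1).
#' @export
d_spacing <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop_invalid("q must be positive and finite")
  2 * pi / q
}
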