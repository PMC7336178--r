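## Reduction: pattern stacks -> dark-field contrast images, average
## patterns, azimuthally integrated radial profiles.

#' Radial intensity profile
#'
#' One-dimensional azimuthally integrated profile: per-bin mean counts per
#' unmasked pixel, with the number of contributing pixels per bin. Bins with
#' no contributing pixels are invalid (`NA` intensity), never zero.
#'
#' @param q Strictly increasing bin centers (nm^-1).
#' @param intensity Mean counts per pixel per bin (`NA` where invalid).
#' @param n_pixels Contributing pixels per bin.
#' @return A data frame of class `radial_profile` with columns `q`,
#'   `intensity`, `n_pixels`.
#' @export
radial_profile <- function(q, intensity, n_pixels) {
  if (length(q) < 1 || any(diff(q) <= 0))
    stop_invalid("q bin centers must be strictly increasing")
  if (length(intensity) != length(q) || length(n_pixels) != length(q))
    stop_invalid("q, intensity and n_pixels must have equal length")
  if (any(n_pixels < 0)) stop_invalid("n_pixels must be >= 0")
  intensity[n_pixels == 0] <- NA_real_
  structure(data.frame(q = q, intensity = intensity, n_pixels = n_pixels),
            class = c("radial_profile", "data.frame"))
}

## scan-point indices: accept a (row, col) 2-column matrix or linear
## (column-major) indices into the scan grid; returns a (row, col) matrix
scan_point_index <- function(indices, grid) {
  if (is.matrix(indices) && ncol(indices) == 2L) {
    out <- cbind(as.integer(indices[, 1]), as.integer(indices[, 2]))
  } else {
    idx <- as.integer(indices)
    out <- cbind(((idx - 1L) %% grid$n_rows) + 1L,
                 ((idx - 1L) %/% grid$n_rows) + 1L)
  }
  if (nrow(out) > 0 &&
      (any(out[, 1] < 1L) || any(out[, 1] > grid$n_rows) ||
       any(out[, 2] < 1L) || any(out[, 2] > grid$n_cols)))
    stop_invalid("scan indices outside the grid")
  out
}

#' Dark-field contrast image
#'
#' Per scan position, the integrated (summed) counts over all unmasked
#' detector pixels with `q <= q_max`. The default `q_max` of 2.99 nm^-1
#' matches the region of interest used for the radial profiles.
#'
#' @param stack A `pattern_stack` (see [simulate_scan()] / [read_scan()]).
#' @param q_max Upper q bound of the detector ROI (nm^-1).
#' @return An object of class `darkfield_image`: scan-grid-shaped `values`
#'   matrix plus `q_max`, `grid`, `geom`.
#' @export
darkfield <- function(stack, q_max = 2.99) {
  stopifnot(inherits(stack, "pattern_stack"))
  check_scalar_positive(q_max, "q_max")
  qmap <- build_qmap(stack$geom)
  roi <- !stack$geom$mask & qmap$q <= q_max
  if (!any(roi))
    stop(errorCondition("no unmasked detector pixel satisfies q <= q_max",
                        class = c("saxscan_empty_roi", "error")))
  ## stream over scan rows to keep memory bounded on large stacks
  n_px <- prod(stack$geom$shape)
  roi_v <- as.vector(roi)
  values <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  for (i in seq_len(stack$grid$n_rows)) {
    slab <- stack$counts[, , i, , drop = FALSE]
    dim(slab) <- c(n_px, stack$grid$n_cols)
    values[i, ] <- colSums(slab[roi_v, , drop = FALSE])
  }
  structure(list(values = values,
                 q_max = q_max, grid = stack$grid, geom = stack$geom),
            class = "darkfield_image")
}

#' @export
print.darkfield_image <- function(x, ...) {
  cat(sprintf("darkfield_image: %d x %d scan positions, q_max = %g nm^-1\n",
              nrow(x$values), ncol(x$values), x$q_max))
  invisible(x)
}

#' Average scattering pattern over a set of scan positions
#'
#' Pixel-wise arithmetic mean of the selected frames; masked pixels are
#' `NA` in the result.
#'
#' @param stack A `pattern_stack`.
#' @param indices Scan positions: a 2-column (row, col) matrix or linear
#'   column-major indices into the scan grid. Must be non-empty.
#' @return Matrix of mean counts, detector shape, `NA` on masked pixels.
#' @export
average_pattern <- function(stack, indices) {
  stopifnot(inherits(stack, "pattern_stack"))
  pts <- scan_point_index(indices, stack$grid)
  if (nrow(pts) == 0) stop_invalid("`indices` must select at least one scan position")
  n_px <- prod(stack$geom$shape)
  acc <- numeric(n_px)
  ## accumulate per scan row to keep memory bounded on large stacks
  for (i in unique(pts[, 1])) {
    cols <- pts[pts[, 1] == i, 2]
    slab <- stack$counts[, , i, cols, drop = FALSE]
    dim(slab) <- c(n_px, length(cols))
    acc <- acc + rowSums(slab)
  }
  avg <- acc / nrow(pts)
  avg[as.vector(stack$geom$mask)] <- NA_real_
  matrix(avg, stack$geom$shape[1], stack$geom$shape[2])
}

#' Azimuthal integration of a detector frame
#'
#' Bins unmasked pixels by their pixel-center q into `n_bins` linear bins
#' over `q_range` and reports the mean counts per contributing pixel in
#' each bin (mean rather than sum, so profiles from differently masked
#' regions remain comparable). No pixel splitting across bins.
#'
#' @param frame Detector frame (counts; `NA` allowed for invalid pixels).
#' @param geom A [detector_geometry()].
#' @param n_bins Number of linear q bins (>= 2). Default 300.
#' @param q_range Numeric (min, max); pixels with `min < q <= max`
#'   contribute. Default (0, 2.99].
#' @param qmap Optional precomputed [build_qmap()].
#' @return A [radial_profile()].
#' @export
azimuthal_integrate <- function(frame, geom, n_bins = 300,
                                q_range = c(0, 2.99), qmap = NULL) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  if (q_range[1] >= q_range[2]) stop_invalid("q_range must satisfy min < max")
  if (!all(dim(frame) == geom$shape)) stop_invalid("frame shape must equal the detector shape")
  if (is.null(qmap)) qmap <- build_qmap(geom)
  width <- (q_range[2] - q_range[1]) / n_bins
  qv <- as.vector(qmap$q)
  vv <- as.vector(frame)
  keep <- !as.vector(geom$mask) & !is.na(vv) & qv > q_range[1] & qv <= q_range[2]
  bin <- ceiling((qv[keep] - q_range[1]) / width)
  bin[bin > n_bins] <- n_bins  # guard the exact upper edge
  n_px <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  if (any(keep)) {
    agg <- rowsum(vv[keep], group = bin, reorder = TRUE)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  intensity <- ifelse(n_px > 0, sums / pmax(n_px, 1), NA_real_)
  centers <- q_range[1] + (seq_len(n_bins) - 0.5) * width
  radial_profile(centers, intensity, n_px)
}

#' Radial profile of the average pattern over scan positions
#'
#' Convenience composition of [average_pattern()] and
#' [azimuthal_integrate()]; with a common mask and binning this equals the
#' average of the per-frame profiles.
#'
#' @inheritParams average_pattern
#' @inheritParams azimuthal_integrate
#' @return A [radial_profile()].
#' @export
integrate_scan_points <- function(stack, indices, n_bins = 300,
                                  q_range = c(0, 2.99), qmap = NULL) {
  azimuthal_integrate(average_pattern(stack, indices), stack$geom,
                      n_bins = n_bins, q_range = q_range, qmap = qmap)
}
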