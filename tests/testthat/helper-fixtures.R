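# Shared fixtures and independent brute-force oracles.

# Binned Eiger-like detector: `det` x `det` pixels covering the same q range
# as the full-resolution detector at 13 keV / 0.9 m, with a small central
# beamstop mask.
std_geom <- function(det = 96, beamstop = TRUE) {
  mask <- matrix(FALSE, det, det)
  ctr <- c(det / 2 + 0.25, det / 2 - 0.25)
  if (beamstop)
    mask[abs(row(mask) - 0.5 - ctr[1]) <= 1.5 &
           abs(col(mask) - 0.5 - ctr[2]) <= 1.5] <- TRUE
  detector_geometry(13.0, 0.9, 75e-6 * 2070 / det, ctr, c(det, det), mask)
}

# Pattern stack assembled directly from a list of frames (row-major over the
# scan grid), for hand-built reduction tests.
manual_stack <- function(frames, geom, grid, exposure_ms = 1.34) {
  counts <- array(0L, dim = c(geom$shape[1], geom$shape[2],
                              grid$n_rows, grid$n_cols))
  k <- 0
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    k <- k + 1
    counts[, , i, j] <- frames[[k]]
  }
  structure(list(counts = counts, grid = grid, geom = geom,
                 exposure_ms = exposure_ms, truth = NULL, seed = NA_integer_),
            class = "pattern_stack")
}

# Naive sliding-window Bradley threshold (no integral image, no cleanup).
bf_bradley <- function(image, window_fraction, sensitivity) {
  nr <- nrow(image); nc <- ncol(image)
  side <- max(3L, as.integer(round(window_fraction * max(nr, nc))))
  if (side %% 2L == 0L) side <- side + 1L
  h <- side %/% 2L
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- max(1, i - h):min(nr, i + h)
    cc <- max(1, j - h):min(nc, j + h)
    out[i, j] <- image[i, j] > (1 + sensitivity) * mean(image[rr, cc])
  }
  out
}

# Naive Otsu: exhaustive between-class variance over all 256 candidates.
bf_otsu <- function(values, n_levels = 256L) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(NA_real_)
  bins <- pmin(floor((values - lo) / (hi - lo) * n_levels), n_levels - 1L)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:(n_levels - 2)) {
    g0 <- bins <= t; g1 <- !g0
    if (!any(g0) || !any(g1)) next
    w0 <- mean(g0); w1 <- mean(g1)
    v <- w0 * w1 * (mean(bins[g0]) - mean(bins[g1]))^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  lo + (best_t + 0.5) / n_levels * (hi - lo)
}

# Brute-force two-sample KS statistic: sup over all pooled breakpoints.
bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  ex <- vapply(pts, function(t) mean(x <= t), numeric(1))
  ey <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(ex - ey))
}
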