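## Forward model: elliptical cell phantoms on a scan grid with known
## power-law scattering parameters, rendered to detector frames with
## Poisson counting noise on top of a weakly anisotropic instrument
## background.

CLASS_BACKGROUND <- 0L
CLASS_CYTOPLASM <- 1L
CLASS_NUCLEUS <- 2L
CLASS_DISREGARDED <- 3L
MASK_SENTINEL <- -1L

#' Porod prefactor from electron-density contrast and interface area
#'
#' In the Porod limit (exponent -4) the power-law prefactor K is
#' proportional to the squared electron-density contrast between scatterers
#' and their surroundings and to the interface area:
#' `K = c0 * delta_rho^2 * surface_area`. Absolute intensities are not
#' calibrated here, so `c0` and the inputs are in arbitrary units; only the
#' proportionality is meaningful (and tested).
#'
#' @param delta_rho Electron-density contrast (arbitrary units, > 0).
#' @param surface_area Interface area (arbitrary units, > 0).
#' @param c0 Proportionality constant (default 1).
#' @return Prefactor K in the simulator's intensity units.
#' @export
porod_constant <- function(delta_rho, surface_area, c0 = 1) {
  if (any(delta_rho <= 0) || any(surface_area <= 0) || c0 <= 0)
    stop_invalid("delta_rho, surface_area and c0 must be positive")
  c0 * delta_rho^2 * surface_area
}

#' Phantom parameter distributions
#'
#' Defaults emulate freeze-dried fibroblast-like cells: power-law exponents
#' near -4.1 (slightly below the Porod value, as measured for freeze-dried
#' cells), a nucleus brighter than the cytoplasm (it is thicker and denser),
#' a small additive constant B, and a smooth instrument background that is
#' 10-30 percent of the cytoplasm intensity in the fit range with a weak
#' cos(2 phi) anisotropy. All anisotropy lives in the background term.
#'
#' @param cell_semiaxis_px Range of the cell-body major semi-axis (scan px).
#' @param axis_ratio Range of minor/major axis ratio.
#' @param nucleus_scale Range of nucleus/cell semi-axis ratio.
#' @param alpha_mean,alpha_sd Normal law for the power-law exponent, truncated
#'   to `alpha_bounds`.
#' @param alpha_bounds Truncation interval for alpha.
#' @param K_meanlog,K_sdlog Log-normal law for the cytoplasm prefactor K
#'   (counts nm^alpha ms^-1 per pixel; arbitrary absolute scale).
#' @param nucleus_K_factor Range of the nucleus/cytoplasm K ratio.
#' @param B_range Uniform range of the additive constant B (counts ms^-1).
#' @param bg_amplitude,bg_exponent Instrument background `b(q) = amp * q^exp`.
#' @param bg_aniso Background anisotropy amplitude `a` in [0, 1).
#' @param bg_orientation Background anisotropy orientation (rad).
#' @param min_separation Minimum gap between cell-body ellipses (px).
#' @param edge_margin Margin kept free at the grid edge (px).
#' @param K_area_coupling `"none"` (log-normal K) or `"inverse"`
#'   (K proportional to 1/area, emulating a cell-cycle-like anticorrelation).
#' @param K_area_scale Numerator for the `"inverse"` coupling.
#' @param delta_rho,surface_area Optional per-cell contrast and interface
#'   area; when `delta_rho` is given, the cytoplasm K is set through
#'   [porod_constant()] instead of the log-normal law.
#' @param max_attempts_per_cell Rejection-sampling budget for placement.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(cell_semiaxis_px = c(8, 16),
                           axis_ratio = c(0.6, 1),
                           nucleus_scale = c(0.35, 0.55),
                           alpha_mean = -4.1, alpha_sd = 0.1,
                           alpha_bounds = c(-6, -2),
                           K_meanlog = log(0.05), K_sdlog = 0.25,
                           nucleus_K_factor = c(1.5, 3),
                           B_range = c(0.001, 0.003),
                           bg_amplitude = 0.02, bg_exponent = -3,
                           bg_aniso = 0.1, bg_orientation = 21 * pi / 180,
                           min_separation = 2,
                           edge_margin = 2,
                           K_area_coupling = c("none", "inverse"),
                           K_area_scale = 20,
                           delta_rho = NULL, surface_area = NULL,
                           max_attempts_per_cell = 200) {
  params <- list(
    cell_semiaxis_px = cell_semiaxis_px, axis_ratio = axis_ratio,
    nucleus_scale = nucleus_scale,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd, alpha_bounds = alpha_bounds,
    K_meanlog = K_meanlog, K_sdlog = K_sdlog,
    nucleus_K_factor = nucleus_K_factor, B_range = B_range,
    bg_amplitude = bg_amplitude, bg_exponent = bg_exponent,
    bg_aniso = bg_aniso, bg_orientation = bg_orientation,
    min_separation = min_separation, edge_margin = edge_margin,
    K_area_coupling = match.arg(K_area_coupling),
    K_area_scale = K_area_scale,
    delta_rho = delta_rho, surface_area = surface_area,
    max_attempts_per_cell = max_attempts_per_cell)
  structure(params, class = "phantom_params")
}

rtruncnorm1 <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > bounds[1] & x < bounds[2]])
  }
  out[seq_len(n)]
}

ellipse_pixels <- function(center, a, b, angle, n_rows, n_cols) {
  rr <- floor(max(1, center[1] - a)):ceiling(min(n_rows, center[1] + a))
  cc <- floor(max(1, center[2] - a)):ceiling(min(n_cols, center[2] + a))
  g <- expand.grid(row = rr, col = cc)
  dy <- g$row - center[1]; dx <- g$col - center[2]
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  g[u^2 + v^2 <= 1, , drop = FALSE]
}

#' Generate a phantom cell field with ground-truth scattering parameters
#'
#' Places `n_cells` non-overlapping elliptical cells (rejection sampling) on
#' the scan grid, each with a concentric elliptical nucleus, and assigns
#' per-cell power-law parameters (K, alpha, B) for cytoplasm and nucleus
#' from the distributions in `params`. Reproducible for a fixed seed.
#'
#' @param n_cells Number of cells (>= 0).
#' @param grid A [scan_grid()].
#' @param seed Integer seed.
#' @param params A [phantom_params()].
#' @return An object of class `phantom`: scan-grid-shaped `class_map`
#'   (0 background, 1 cytoplasm, 2 nucleus), `cell_id_map`, `K_map`,
#'   `alpha_map`, `B_map`, background descriptor `bg`, per-cell table
#'   `cells`, the `grid`, `seed` and `params`.
#' @export
make_phantom <- function(n_cells, grid, seed = 1L, params = phantom_params()) {
  stopifnot(inherits(grid, "scan_grid"))
  if (n_cells < 0) stop_invalid("n_cells must be >= 0")
  nr <- grid$n_rows; nc <- grid$n_cols
  with_seed(seed, {
    class_map <- matrix(CLASS_BACKGROUND, nr, nc)
    cell_id_map <- matrix(0L, nr, nc)
    K_map <- matrix(0, nr, nc)
    alpha_map <- matrix(0, nr, nc)
    B_map <- matrix(0, nr, nc)

    placed <- data.frame(center_row = numeric(0), center_col = numeric(0),
                         a = numeric(0), b = numeric(0), angle = numeric(0))
    attempts <- 0L
    budget <- params$max_attempts_per_cell * max(1L, n_cells)
    while (nrow(placed) < n_cells && attempts < budget) {
      attempts <- attempts + 1L
      a <- runif(1, params$cell_semiaxis_px[1], params$cell_semiaxis_px[2])
      b <- a * runif(1, params$axis_ratio[1], params$axis_ratio[2])
      m <- a + params$edge_margin
      if (2 * m >= min(nr, nc))
        stop_invalid("scan grid too small for the requested cell sizes")
      ctr <- c(runif(1, m, nr - m), runif(1, m, nc - m))
      ok <- TRUE
      if (nrow(placed) > 0) {
        d <- sqrt((placed$center_row - ctr[1])^2 + (placed$center_col - ctr[2])^2)
        ok <- all(d > placed$a + a + params$min_separation)
      }
      if (ok) {
        placed <- rbind(placed, data.frame(center_row = ctr[1], center_col = ctr[2],
                                           a = a, b = b, angle = runif(1, 0, pi)))
      }
    }
    if (nrow(placed) < n_cells)
      stop(errorCondition(
        sprintf("could only place %d of %d cells without overlap", nrow(placed), n_cells),
        class = c("saxscan_placement_error", "error")))

    n <- nrow(placed)
    cells <- NULL
    if (n > 0) {
      nuc_scale <- runif(n, params$nucleus_scale[1], params$nucleus_scale[2])
      alpha_cyt <- rtruncnorm1(n, params$alpha_mean, params$alpha_sd, params$alpha_bounds)
      alpha_nuc <- rtruncnorm1(n, params$alpha_mean, params$alpha_sd, params$alpha_bounds)
      K_factor <- runif(n, params$nucleus_K_factor[1], params$nucleus_K_factor[2])
      B <- runif(n, params$B_range[1], params$B_range[2])
      K_cyt <- rlnorm(n, params$K_meanlog, params$K_sdlog)
      if (!is.null(params$delta_rho)) {
        drho <- rep_len(params$delta_rho, n)
        sarea <- if (is.null(params$surface_area)) {
          # Ramanujan perimeter of the cell ellipse as an interface-area proxy
          h <- ((placed$a - placed$b) / (placed$a + placed$b))^2
          pi * (placed$a + placed$b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
        } else rep_len(params$surface_area, n)
        K_cyt <- porod_constant(drho, sarea, c0 = 0.002)
      }

      area_px <- integer(n); n_nuc_px <- integer(n)
      pix_list <- vector("list", n); nuc_list <- vector("list", n)
      for (i in seq_len(n)) {
        body <- ellipse_pixels(c(placed$center_row[i], placed$center_col[i]),
                               placed$a[i], placed$b[i], placed$angle[i], nr, nc)
        nuc <- ellipse_pixels(c(placed$center_row[i], placed$center_col[i]),
                              placed$a[i] * nuc_scale[i], placed$b[i] * nuc_scale[i],
                              placed$angle[i], nr, nc)
        pix_list[[i]] <- body; nuc_list[[i]] <- nuc
        area_px[i] <- nrow(body); n_nuc_px[i] <- nrow(nuc)
      }
      if (params$K_area_coupling == "inverse")
        K_cyt <- params$K_area_scale / pmax(area_px, 1)
      K_nuc <- K_cyt * K_factor

      for (i in seq_len(n)) {
        body <- pix_list[[i]]; nuc <- nuc_list[[i]]
        bi <- cbind(body$row, body$col); ni <- cbind(nuc$row, nuc$col)
        class_map[bi] <- CLASS_CYTOPLASM
        class_map[ni] <- CLASS_NUCLEUS
        cell_id_map[bi] <- i
        K_map[bi] <- K_cyt[i]; K_map[ni] <- K_nuc[i]
        alpha_map[bi] <- alpha_cyt[i]; alpha_map[ni] <- alpha_nuc[i]
        B_map[bi] <- B[i]
      }
      cells <- data.frame(cell_id = seq_len(n), placed,
                          nucleus_scale = nuc_scale,
                          K_cyt = K_cyt, K_nuc = K_nuc,
                          alpha_cyt = alpha_cyt, alpha_nuc = alpha_nuc,
                          B = B, area_px = area_px, n_nuc_px = n_nuc_px)
    } else {
      cells <- data.frame(cell_id = integer(0), center_row = numeric(0),
                          center_col = numeric(0), a = numeric(0), b = numeric(0),
                          angle = numeric(0), nucleus_scale = numeric(0),
                          K_cyt = numeric(0), K_nuc = numeric(0),
                          alpha_cyt = numeric(0), alpha_nuc = numeric(0),
                          B = numeric(0), area_px = integer(0), n_nuc_px = integer(0))
    }

    structure(list(
      grid = grid, class_map = class_map, cell_id_map = cell_id_map,
      K_map = K_map, alpha_map = alpha_map, B_map = B_map,
      bg = list(amplitude = params$bg_amplitude, exponent = params$bg_exponent,
                aniso = params$bg_aniso, orientation = params$bg_orientation),
      cells = cells, seed = as.integer(seed), params = params), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d cells on a %d x %d scan grid (seed %d)\n",
              nrow(x$cells), x$grid$n_rows, x$grid$n_cols, x$seed))
  invisible(x)
}

## q map with the (masked) q = 0 beam-center pixel replaced by the nearest
## positive value so powers are finite.
qmap_positive <- function(qmap) {
  q <- qmap$q
  zero <- q <= 0
  if (any(zero)) q[zero] <- min(q[!zero])
  q
}

#' Noise-free expected detector pattern at one scan position
#'
#' Expectation in counts per millisecond per pixel: for positions inside a
#' cell, `K * q^alpha + B` from the phantom's ground-truth maps; for all
#' positions, an additive instrument background
#' `b(q) * (1 + a * cos(2 * (phi - phi0)))` with `b(q) = amp * q^exp`.
#'
#' @param phantom A [make_phantom()] result.
#' @param point Scan position, integer (row, col).
#' @param geom A [detector_geometry()].
#' @param qmap Optional precomputed [build_qmap()] for `geom`.
#' @return Matrix of expected counts per ms, detector shape.
#' @export
expected_pattern <- function(phantom, point, geom, qmap = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geom, "detector_geometry"))
  point <- as.integer(point)
  if (length(point) != 2L || point[1] < 1L || point[1] > phantom$grid$n_rows ||
      point[2] < 1L || point[2] > phantom$grid$n_cols)
    stop_invalid("`point` must be a (row, col) index inside the scan grid")
  if (is.null(qmap)) qmap <- build_qmap(geom)
  q <- qmap_positive(qmap)
  bg <- phantom$bg
  expect <- bg$amplitude * q^bg$exponent *
    (1 + bg$aniso * cos(2 * (qmap$azimuth - bg$orientation)))
  if (phantom$class_map[point[1], point[2]] != CLASS_BACKGROUND) {
    K <- phantom$K_map[point[1], point[2]]
    alpha <- phantom$alpha_map[point[1], point[2]]
    B <- phantom$B_map[point[1], point[2]]
    expect <- expect + K * q^alpha + B
  }
  expect
}

#' Simulate a full scanning-SAXS dataset from a phantom
#'
#' Renders one detector frame per scan position: an independent Poisson draw
#' with mean `expected_pattern * exposure * flux_scale` (optionally times a
#' per-scan-row flux factor, emulating slow drifts of the incoming beam).
#' Masked pixels carry the sentinel value -1. Bit-reproducible per seed.
#'
#' @param phantom A [make_phantom()] result.
#' @param geom A [detector_geometry()].
#' @param exposure_ms Exposure per position (ms); default from the grid.
#' @param flux_scale Overall flux multiplier (dimensionless).
#' @param seed Integer seed.
#' @param row_flux Optional numeric vector, one multiplier per scan row.
#' @return A `pattern_stack`: `counts` array with dim (det_rows, det_cols,
#'   n_rows, n_cols) of integer counts (-1 on masked pixels), plus `grid`,
#'   `geom`, `exposure_ms` and the phantom as `truth`.
#' @export
simulate_scan <- function(phantom, geom, exposure_ms = NULL, flux_scale = 1,
                          seed = 1L, row_flux = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geom, "detector_geometry"))
  if (is.null(exposure_ms)) exposure_ms <- phantom$grid$exposure_ms
  check_scalar_positive(exposure_ms, "exposure_ms")
  check_scalar_positive(flux_scale, "flux_scale")
  nr <- phantom$grid$n_rows; nc <- phantom$grid$n_cols
  if (!is.null(row_flux) && length(row_flux) != nr)
    stop_invalid("`row_flux` must have one value per scan row")
  qmap <- build_qmap(geom)
  q <- qmap_positive(qmap)
  bg <- phantom$bg
  bg_pattern <- as.vector(bg$amplitude * q^bg$exponent *
    (1 + bg$aniso * cos(2 * (qmap$azimuth - bg$orientation))))
  n_px <- prod(geom$shape)
  masked <- as.vector(geom$mask)

  ## cells have piecewise-constant parameters: cache the q-power term per
  ## unique (K, alpha, B) triple instead of recomputing per scan position
  key_map <- matrix("", nr, nc)
  inside <- phantom$class_map != CLASS_BACKGROUND
  key_map[inside] <- paste(phantom$K_map[inside], phantom$alpha_map[inside],
                           phantom$B_map[inside])
  cache <- new.env(parent = emptyenv())
  qv <- as.vector(q)

  counts <- array(MASK_SENTINEL, dim = c(geom$shape[1], geom$shape[2], nr, nc))
  with_seed(seed, {
    for (i in seq_len(nr)) {
      rf <- if (is.null(row_flux)) 1 else row_flux[i]
      for (j in seq_len(nc)) {
        mu <- bg_pattern
        if (inside[i, j]) {
          key <- key_map[i, j]
          term <- cache[[key]]
          if (is.null(term)) {
            term <- phantom$K_map[i, j] * qv^phantom$alpha_map[i, j] +
              phantom$B_map[i, j]
            cache[[key]] <- term
          }
          mu <- mu + term
        }
        frame <- rpois(n_px, mu * exposure_ms * flux_scale * rf)
        frame[masked] <- MASK_SENTINEL
        counts[, , i, j] <- frame
      }
    }
  })
  structure(list(counts = counts, grid = phantom$grid, geom = geom,
                 exposure_ms = exposure_ms, truth = phantom,
                 seed = as.integer(seed)), class = "pattern_stack")
}

#' @export
print.pattern_stack <- function(x, ...) {
  cat(sprintf("pattern_stack: %d x %d scan positions, %d x %d detector, %g ms exposure\n",
              x$grid$n_rows, x$grid$n_cols, x$geom$shape[1], x$geom$shape[2],
              x$exposure_ms))
  invisible(x)
}

#' Simulate a Poisson-noisy radial profile directly at the profile level
#'
#' Shortcut for parameter-recovery studies: given a noise-free expectation
#' I(q) in counts per pixel per ms, draws per-bin Poisson counts for
#' `n_patterns` averaged patterns with `n_pixels` contributing pixels per
#' bin, and returns the corresponding [radial_profile()] (counts per pixel
#' per pattern, i.e. not yet exposure-normalized).
#'
#' @param q Bin centers (nm^-1).
#' @param intensity_per_ms Expected intensity per pixel per ms at `q`.
#' @param exposure_ms Exposure per pattern (ms).
#' @param n_patterns Number of patterns averaged.
#' @param n_pixels Pixels per bin (scalar or per-bin vector).
#' @param seed Integer seed.
#' @return A [radial_profile()].
#' @export
simulate_radial_profile <- function(q, intensity_per_ms, exposure_ms = 1.34,
                                    n_patterns = 1, n_pixels = 50, seed = 1L) {
  if (length(q) != length(intensity_per_ms))
    stop_invalid("q and intensity_per_ms must have the same length")
  check_scalar_positive(exposure_ms, "exposure_ms")
  n_pixels <- rep_len(n_pixels, length(q))
  eff <- exposure_ms * n_patterns * n_pixels
  with_seed(seed, {
    counts <- rpois(length(q), intensity_per_ms * eff)
    radial_profile(q, counts / (n_patterns * n_pixels), n_pixels * n_patterns)
  })
}
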