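## Population-level orchestration and statistics: the three analysis levels
## (window-wide, per-cell, single-pattern), area-quartile subpopulations,
## two-sample Kolmogorov-Smirnov comparisons, and orientation/anisotropy
## of scattering patterns.

#' Empirical quartile boundaries of a cell-area distribution
#'
#' 25/50/75 percentiles with linear interpolation. Cells in the first
#' quartile of the area distribution are called "small", those in the
#' fourth quartile "large".
#'
#' @param areas Numeric vector of cell areas (pixel counts), length >= 4.
#' @return Numeric length-3: the 25, 50 and 75 percent boundaries.
#' @export
area_quartiles <- function(areas) {
  if (length(areas) < 4) stop_invalid("need at least 4 areas")
  unname(quantile(areas, c(0.25, 0.5, 0.75), type = 7))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the p-value from the asymptotic
#' Kolmogorov distribution at effective sample size
#' `n_eff = n_x * n_y / (n_x + n_y)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with elements `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_invalid("samples must be non-empty")
  ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Orientation and anisotropy of a scattering pattern
#'
#' The radial decay is first normalized out: every unmasked pixel with q
#' inside `q_range` is divided by the mean intensity of its q bin, so the
#' weights carry only the azimuthal modulation (otherwise the steep
#' radial decay couples to the coarse azimuthal sampling of the innermost
#' rings and fakes anisotropy). The normalized weights are then averaged
#' in azimuthal sectors and summarized by the second circular moment
#' `m2 = sum(w * exp(2i*phi)) / sum(w)`: anisotropy is `|m2|` (0
#' isotropic, 1 a perfect needle) and the orientation is `arg(m2)/2`
#' mapped to [0, 180) degrees. For intensity proportional to
#' `1 + a*cos(2*(phi - phi0))` the moment gives anisotropy `a/2` and
#' angle `phi0`.
#'
#' @param frame Detector frame (counts; NA = invalid).
#' @param geom A [detector_geometry()].
#' @param q_range q interval used for the azimuthal weights (nm^-1).
#' @param n_sectors Number of azimuthal sectors. Default 36.
#' @param n_qbins Radial bins used for the normalization. Default 32.
#' @param qmap Optional precomputed [build_qmap()].
#' @return List: `angle_deg` in [0, 180), `anisotropy` in [0, 1],
#'   `n_sectors_valid`.
#' @export
orientation_anisotropy <- function(frame, geom, q_range = c(0.185, 1.723),
                                   n_sectors = 36, n_qbins = 32, qmap = NULL) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (is.null(qmap)) qmap <- build_qmap(geom)
  qv <- as.vector(qmap$q); av <- as.vector(qmap$azimuth); vv <- as.vector(frame)
  keep <- !as.vector(geom$mask) & !is.na(vv) & qv >= q_range[1] & qv <= q_range[2]
  if (!any(keep)) stop_invalid("no valid pixels in q_range")
  qk <- qv[keep]; vk <- vv[keep]; ak <- av[keep]
  qb <- pmin(floor((qk - q_range[1]) / (q_range[2] - q_range[1]) * n_qbins) + 1L,
             n_qbins)
  ring_mean <- tapply(vk, qb, mean)
  denom <- ring_mean[as.character(qb)]
  w_px <- ifelse(is.finite(denom) & denom > 0, vk / denom, 1)
  sector <- pmin(floor(ak / (2 * pi) * n_sectors) + 1L, n_sectors)
  w <- tapply(w_px, sector, mean)
  phi <- (as.integer(names(w)) - 0.5) * 2 * pi / n_sectors
  if (length(w) < 2) stop_invalid("need at least 2 valid azimuthal sectors")
  if (any(w < 0)) w <- w - min(w)  # weights must be non-negative
  if (sum(w) <= 0) return(list(angle_deg = NA_real_, anisotropy = 0,
                               n_sectors_valid = length(w)))
  m2 <- sum(w * exp(2i * phi)) / sum(w)
  angle <- (Arg(m2) / 2 * 180 / pi) %% 180
  list(angle_deg = angle, anisotropy = Mod(m2), n_sectors_valid = length(w))
}

#' Compare fitted parameters of small vs large cells
#'
#' Splits retained cell records by the quartiles of the area distribution
#' ("small" = first quartile, "large" = fourth), and compares the K and
#' alpha distributions per region (nucleus, cytoplasm) between the two
#' groups with two-sample Kolmogorov-Smirnov tests. P-values are reported
#' raw (no multiple-testing correction).
#'
#' @param records Data frame with columns `area`, `K_nuc`, `K_cyt`,
#'   `alpha_nuc`, `alpha_cyt` (one row per retained cell).
#' @return An object of class `population_summary`: `quartiles`,
#'   group sizes, per-group/per-region summary statistics, a `ks` table of
#'   the four comparisons, and an `underpowered` flag (set when either
#'   group has fewer than 2 complete records).
#' @export
compare_small_vs_large <- function(records) {
  need <- c("area", "K_nuc", "K_cyt", "alpha_nuc", "alpha_cyt")
  if (!all(need %in% names(records)))
    stop_invalid("`records` must have columns ", paste(need, collapse = ", "))
  if (nrow(records) < 4) stop_invalid("need at least 4 retained cells")
  qs <- area_quartiles(records$area)
  small <- records[records$area <= qs[1], , drop = FALSE]
  large <- records[records$area >= qs[3], , drop = FALSE]
  ## degenerate when a group is tiny or the area distribution has no spread
  ## (the "small" and "large" groups then coincide)
  underpowered <- nrow(small) < 2 || nrow(large) < 2 || qs[1] >= qs[3]

  vars <- c(K_cyt = "K_cyt", K_nuc = "K_nuc",
            alpha_cyt = "alpha_cyt", alpha_nuc = "alpha_nuc")
  summarize <- function(df) {
    do.call(rbind, lapply(names(vars), function(v) {
      x <- df[[vars[v]]]; x <- x[!is.na(x)]
      data.frame(variable = v, n = length(x), mean = mean(x),
                 median = median(x), sd = sd(x))
    }))
  }
  ks <- do.call(rbind, lapply(names(vars), function(v) {
    xs <- small[[vars[v]]]; xl <- large[[vars[v]]]
    xs <- xs[!is.na(xs)]; xl <- xl[!is.na(xl)]
    if (length(xs) == 0 || length(xl) == 0)
      return(data.frame(variable = v, D = NA_real_, p_value = NA_real_))
    kt <- ks_two_sample(xs, xl)
    data.frame(variable = v, D = kt$D, p_value = kt$p_value)
  }))
  structure(list(quartiles = qs, n_small = nrow(small), n_large = nrow(large),
                 small = summarize(small), large = summarize(large),
                 ks = ks, underpowered = underpowered),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population_summary: %d small vs %d large cells%s\n",
              x$n_small, x$n_large,
              if (x$underpowered) " (UNDERPOWERED)" else ""))
  print(x$ks, row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' Key/value configuration for [run_pipeline()], mergeable with a YAML
#' file via [read_config()]. The background pixel bounds default to a wide
#' interval suited to reduced-scale scans; at full-window scale the
#' constants of [filter_criteria()] apply.
#'
#' @param ... Overrides of the defaults listed below.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    qmax_darkfield = 2.99,
    fit_qmin = 0.185,
    fit_qmax = 1.723,
    n_qbins = 300,
    bradley = list(window_fraction = 1 / 4, sensitivity = 0.5,
                   min_object_px = 20),
    filter = list(min_nucleus_pixels = 30, bg_bounds = c(100, 1e7),
                  ratio_bounds = NULL),
    surroundings = list(margin = 20),
    levels = c("window", "cell"),
    dose = list(mu_over_rho_cm2_g = MU_OVER_RHO_PROTEIN, flux_ph_s = 1.7e12),
    seed = 1L)
  over <- list(...)
  cfg <- modifyList(cfg, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of configuration keys (see [pipeline_config()]).
#' @return A [pipeline_config()] with the file's overrides applied.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, if (is.null(over)) list() else over)
}

fit_to_row <- function(fit, cell_id, region) {
  data.frame(cell_id = cell_id, region = region,
             K = fit$K, alpha = fit$alpha, B = fit$B,
             K_err = unname(fit$se["K"]), alpha_err = unname(fit$se["alpha"]),
             B_err = unname(fit$se["B"]), converged = fit$converged,
             n_bins = fit$n_bins)
}

#' Run the full scanning-SAXS analysis pipeline
#'
#' Composition of all stages on a stored scan: dark-field computation,
#' segmentation, then power-law fits at the requested analysis levels:
#' \describe{
#'   \item{window}{one average pattern per ROI class over all retained
#'     cells; the window background is the average over all surroundings;}
#'   \item{cell}{per retained cell, average nucleus and cytoplasm patterns
#'     with that cell's surroundings as background;}
#'   \item{pattern}{a fit per scan position inside retained cells, using
#'     the row-matched background (falling back to the cell background for
#'     rows without surroundings).}
#' }
#' All profiles are exposure-normalized before background subtraction and
#' fitting. Artifacts (TIFF maps, CSV tables, JSON summary) are written to
#' `output_dir` when given; outputs are fully determined by input + config.
#'
#' @param scan A `pattern_stack` or a path readable by [read_scan()].
#' @param config A [pipeline_config()].
#' @param output_dir Optional output directory (created if needed).
#' @return List of class `pipeline_result`: `darkfield`, `segmentation`,
#'   `cell_table`, `window_fits`, `cell_fits`, `pattern_fits`,
#'   `pattern_maps` (K and alpha scan-shaped matrices), `summary`
#'   (population comparison, or NULL if too few cells).
#' @export
run_pipeline <- function(scan, config = pipeline_config(), output_dir = NULL) {
  stack <- if (inherits(scan, "pattern_stack")) scan else read_scan(scan)
  qmap <- build_qmap(stack$geom)
  exposure <- stack$exposure_ms
  n_bins <- config$n_qbins
  q_range <- c(0, config$qmax_darkfield)
  fit_range <- c(config$fit_qmin, config$fit_qmax)

  df <- darkfield(stack, config$qmax_darkfield)
  seg <- segment_darkfield(
    df,
    window_fraction = config$bradley$window_fraction,
    sensitivity = config$bradley$sensitivity,
    min_object_px = config$bradley$min_object_px,
    margin = config$surroundings$margin,
    criteria = filter_criteria(config$filter$min_nucleus_pixels,
                               config$filter$bg_bounds,
                               config$filter$ratio_bounds))
  retained <- seg$cells$cell_id[seg$cells$retained]

  norm_profile <- function(indices) {
    normalize_exposure(
      integrate_scan_points(stack, indices, n_bins = n_bins,
                            q_range = q_range, qmap = qmap), exposure)
  }
  class_idx <- function(class_code, ids) {
    sel <- seg$class_map == class_code &
      array(seg$cell_id_map %in% ids, dim(seg$cell_id_map))
    which(sel, arr.ind = TRUE)
  }
  surr_idx <- function(ids) {
    sel <- array(seg$surroundings_map %in% ids, dim(seg$surroundings_map))
    which(sel, arr.ind = TRUE)
  }
  try_fit <- function(signal, background) {
    sub <- subtract_background(signal, background)
    tryCatch(fit_power_law(sub, q_range = fit_range),
             saxscan_invalid_argument = function(e) NULL)
  }

  window_fits <- NULL
  cell_fits <- NULL
  pattern_fits <- NULL
  pattern_maps <- NULL

  if (length(retained) > 0 && "window" %in% config$levels) {
    bg_prof <- norm_profile(surr_idx(retained))
    rows <- list()
    for (cls in c(nucleus = CLASS_NUCLEUS, cytoplasm = CLASS_CYTOPLASM)) {
      idx <- class_idx(cls, retained)
      if (nrow(idx) == 0) next
      fit <- try_fit(norm_profile(idx), bg_prof)
      if (!is.null(fit))
        rows[[length(rows) + 1L]] <-
          fit_to_row(fit, NA_integer_,
                     if (cls == CLASS_NUCLEUS) "nucleus" else "cytoplasm")
    }
    window_fits <- do.call(rbind, rows)
  }

  if (length(retained) > 0 && any(c("cell", "pattern") %in% config$levels)) {
    rows <- list()
    cell_bg <- list()
    for (id in retained) {
      bg_i <- surr_idx(id)
      if (nrow(bg_i) == 0) next
      bg_prof <- norm_profile(bg_i)
      cell_bg[[as.character(id)]] <- bg_prof
      for (cls in c(nucleus = CLASS_NUCLEUS, cytoplasm = CLASS_CYTOPLASM)) {
        idx <- class_idx(cls, id)
        if (nrow(idx) == 0) next
        fit <- try_fit(norm_profile(idx), bg_prof)
        if (!is.null(fit))
          rows[[length(rows) + 1L]] <-
            fit_to_row(fit, id, if (cls == CLASS_NUCLEUS) "nucleus" else "cytoplasm")
      }
    }
    if ("cell" %in% config$levels) cell_fits <- do.call(rbind, rows)

    if ("pattern" %in% config$levels) {
      K_map <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
      alpha_map <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
      prow <- list()
      for (id in retained) {
        px <- which(seg$cell_id_map == id &
                      seg$class_map %in% c(CLASS_CYTOPLASM, CLASS_NUCLEUS),
                    arr.ind = TRUE)
        if (nrow(px) == 0) next
        row_bg <- list()
        for (k in seq_len(nrow(px))) {
          pt <- px[k, ]
          key <- as.character(pt[1])
          if (is.null(row_bg[[key]])) {
            row_bg[[key]] <- tryCatch(
              normalize_exposure(
                row_matched_background(stack, seg, id, pt, n_bins = n_bins,
                                       q_range = q_range, qmap = qmap),
                exposure),
              saxscan_empty_row_background = function(e)
                cell_bg[[as.character(id)]])
          }
          bg_prof <- row_bg[[key]]
          if (is.null(bg_prof)) next
          sig <- norm_profile(matrix(pt, ncol = 2))
          fit <- try_fit(sig, bg_prof)
          if (is.null(fit)) next
          region <- if (seg$class_map[pt[1], pt[2]] == CLASS_NUCLEUS)
            "nucleus" else "cytoplasm"
          r <- fit_to_row(fit, id, region)
          r$scan_row <- pt[1]; r$scan_col <- pt[2]
          prow[[length(prow) + 1L]] <- r
          if (fit$converged) {
            K_map[pt[1], pt[2]] <- fit$K
            alpha_map[pt[1], pt[2]] <- fit$alpha
          }
        }
      }
      pattern_fits <- do.call(rbind, prow)
      pattern_maps <- list(K = K_map, alpha = alpha_map)
    }
  }

  ## population summary from converged per-cell fits
  summary <- NULL
  if (!is.null(cell_fits) && nrow(cell_fits) > 0) {
    cf <- cell_fits[cell_fits$converged, ]
    wide <- merge(
      setNames(cf[cf$region == "nucleus", c("cell_id", "K", "alpha")],
               c("cell_id", "K_nuc", "alpha_nuc")),
      setNames(cf[cf$region == "cytoplasm", c("cell_id", "K", "alpha")],
               c("cell_id", "K_cyt", "alpha_cyt")))
    wide <- merge(wide, seg$cells[, c("cell_id", "area")])
    if (nrow(wide) >= 4)
      summary <- compare_small_vs_large(wide)
  }

  result <- structure(list(
    darkfield = df, segmentation = seg, cell_table = seg$cells,
    window_fits = window_fits, cell_fits = cell_fits,
    pattern_fits = pattern_fits, pattern_maps = pattern_maps,
    summary = summary, config = config), class = "pipeline_result")

  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' Dark-field and fit maps as 32-bit float TIFF (with `.scale` sidecars),
#' class/cell-id label maps as 16-bit TIFF, tables as CSV, and the
#' population summary as JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  write_float_tiff(result$darkfield$values, p("darkfield.tif"))
  write_label_tiff(result$segmentation$class_map, p("class_map.tif"))
  write_label_tiff(result$segmentation$cell_id_map, p("cell_id_map.tif"))
  write_cell_table(result$segmentation, p("cell_table.csv"))
  for (nm in c("window_fits", "cell_fits", "pattern_fits"))
    if (!is.null(result[[nm]]))
      write.csv(result[[nm]], p(paste0(nm, ".csv")), row.names = FALSE)
  if (!is.null(result$pattern_maps)) {
    write_float_tiff(result$pattern_maps$K, p("K_map.tif"))
    write_float_tiff(result$pattern_maps$alpha, p("alpha_map.tif"))
  }
  if (!is.null(result$summary)) {
    s <- result$summary
    jsonlite::write_json(
      list(quartiles = s$quartiles, n_small = s$n_small, n_large = s$n_large,
           small = s$small, large = s$large, ks = s$ks,
           underpowered = s$underpowered),
      p("summary.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  manifest <- list.files(output_dir)
  writeLines(manifest, p("MANIFEST"))
  invisible(output_dir)
}
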