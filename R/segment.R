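## Segmentation of the dark-field image into background / cytoplasm /
## nucleus ROIs: adaptive (Bradley) thresholding separates cells from
## background, a per-cell Otsu threshold finds each nucleus, and pixel-count
## criteria filter out cell fragments. Pixels of rejected components are
## relabeled "disregarded".

#' Adaptive (Bradley) cell mask
#'
#' Local thresholding against a sliding-window mean computed via an
#' integral image: a pixel is foreground iff its value exceeds
#' `(1 + sensitivity)` times the mean of the surrounding square window
#' (side = `window_fraction` times the larger image dimension, rounded to
#' odd, clipped at the borders). Suited to bright cells on a darker
#' background, and invariant under positive rescaling of the image.
#' Cleanup fills enclosed holes and removes connected components below
#' `min_object_px`; removed pixels are recorded in the `"removed"`
#' attribute so they can be relabeled disregarded downstream.
#'
#' @param image Numeric matrix (dark-field values).
#' @param window_fraction Window side as a fraction of `max(dim(image))`,
#'   in (0, 1]. The window should comfortably exceed the typical cell
#'   diameter so the local mean reflects the background. Default 1/4.
#' @param sensitivity Relative offset above the local mean (>= 0).
#'   Default 0.5.
#' @param min_object_px Minimum component size kept by cleanup. Default 20.
#' @param fill_holes Fill enclosed background holes. Default TRUE.
#' @return Logical matrix (TRUE = cell); attribute `"removed"` marks
#'   above-threshold pixels dropped by cleanup.
#' @export
bradley_mask <- function(image, window_fraction = 1 / 4, sensitivity = 0.5,
                         min_object_px = 20, fill_holes = TRUE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_invalid("`image` must be a numeric matrix")
  if (window_fraction <= 0 || window_fraction > 1)
    stop_invalid("`window_fraction` must be in (0, 1]")
  side <- max(3L, as.integer(round(window_fraction * max(dim(image)))))
  if (side %% 2L == 0L) side <- side + 1L
  h <- side %/% 2L
  local_mean <- .window_mean(image, h)
  raw <- image > (1 + sensitivity) * local_mean
  mask <- raw
  if (fill_holes) mask <- .fill_holes(mask)
  if (min_object_px > 0) {
    lab <- label_cells(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  structure(mask, removed = raw & !mask)
}

## clipped sliding-window mean via a zero-padded summed-area table
.window_mean <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums <- sat[r2 + 1L, c2 + 1L] - sat[r1, c2 + 1L] -
    sat[r2 + 1L, c1] + sat[r1, c1]
  sums / counts
}

## connected pixel labeling; connectivity 8 (cells) or 4 (hole filling)
.label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(out)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  pos <- matrix(0L, nr, nc)  # rank of each foreground pixel
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  ## relabel so ids follow raster (row-major) order of each component's
  ## first pixel
  raster <- (rows - 1L) * nc + cols
  first <- tapply(raster, memb, min)
  rank <- match(memb, as.integer(names(sort(first))))
  out[idx] <- rank
  out
}

.fill_holes <- function(mask) {
  bg_lab <- .label_components(!mask, connectivity = 4L)
  if (max(bg_lab) == 0L) return(mask)
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                     bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  holes <- bg_lab > 0L & !(bg_lab %in% border)
  mask | holes
}

#' Label connected cells in a binary mask
#'
#' 8-connected component labeling; ids are contiguous positive integers
#' assigned in raster (row-major) order of each component's first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of cell ids (0 = background).
#' @export
label_cells <- function(mask) {
  if (!is.matrix(mask)) stop_invalid("`mask` must be a matrix")
  .label_components(mask != 0 & !is.na(mask), connectivity = 8L)
}

#' Otsu threshold of a value set
#'
#' Min-max rescales the values, builds a 256-level histogram and returns
#' the threshold maximizing the between-class variance (smallest maximizer
#' on ties), mapped back to the original scale.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param n_levels Histogram levels. Default 256.
#' @return Threshold on the original intensity scale (`NA` if the input is
#'   constant).
#' @export
otsu_threshold <- function(values, n_levels = 256L) {
  values <- values[!is.na(values)]
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(NA_real_)
  bins <- pmin(floor((values - lo) / (hi - lo) * n_levels), n_levels - 1L)
  counts <- tabulate(bins + 1L, nbins = n_levels)
  p <- counts / sum(counts)
  levels <- seq_len(n_levels) - 1
  w0 <- cumsum(p)[-n_levels]
  mu_cum <- cumsum(p * levels)
  mu_total <- mu_cum[n_levels]
  mu0 <- mu_cum[-n_levels] / w0
  w1 <- 1 - w0
  mu1 <- (mu_total - mu_cum[-n_levels]) / w1
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- which.max(sigma_b) - 1L   # smallest maximizer
  lo + (t_star + 0.5) / n_levels * (hi - lo)
}

#' Per-cell nucleus segmentation by Otsu thresholding
#'
#' Thresholds the given cell's own dark-field values with [otsu_threshold()]
#' (the nucleus is thicker and denser than the cytoplasm, hence brighter in
#' dark-field) and keeps the largest 8-connected above-threshold component.
#'
#' @param image Numeric matrix (dark-field values).
#' @param cell_pixels Two-column (row, col) matrix of the cell's pixels.
#' @return List: `pixels` (two-column matrix of nucleus pixels, possibly
#'   empty), `threshold`, and `flagged` (TRUE when no nucleus could be
#'   found, e.g. constant intensity).
#' @export
nucleus_by_otsu <- function(image, cell_pixels) {
  if (!is.matrix(cell_pixels) || ncol(cell_pixels) != 2L)
    stop_invalid("`cell_pixels` must be a two-column (row, col) matrix")
  vals <- image[cell_pixels]
  thr <- otsu_threshold(vals)
  empty <- cell_pixels[integer(0), , drop = FALSE]
  if (is.na(thr))
    return(list(pixels = empty, threshold = NA_real_, flagged = TRUE))
  above <- cell_pixels[vals > thr, , drop = FALSE]
  if (nrow(above) == 0)
    return(list(pixels = empty, threshold = thr, flagged = TRUE))
  sub <- matrix(FALSE, nrow(image), ncol(image))
  sub[above] <- TRUE
  lab <- .label_components(sub, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  largest <- which.max(sizes)         # ties: smallest raster-ordered id
  keep <- which(lab == largest, arr.ind = TRUE)
  colnames(keep) <- c("row", "col")
  list(pixels = keep, threshold = thr, flagged = FALSE)
}

#' Background surroundings of one cell
#'
#' Background-class pixels inside the cell's bounding box dilated by
#' `margin`, excluding pixels claimed by any cell body. Where dilated boxes
#' of several cells overlap, a background pixel is assigned to the nearest
#' cell only (centroid distance; smaller id on ties), so surroundings sets
#' of different cells are disjoint.
#'
#' @param labels A `segmentation` object (see [segment_darkfield()]).
#' @param cell_id Cell id.
#' @param margin Dilation margin in pixels. Default 20.
#' @return Two-column (row, col) matrix of background pixels.
#' @export
cell_surroundings <- function(labels, cell_id, margin = 20) {
  stopifnot(inherits(labels, "segmentation"))
  cells <- labels$cells
  me <- cells[cells$cell_id == cell_id, ]
  if (nrow(me) != 1) stop_invalid("unknown cell_id ", cell_id)
  nr <- nrow(labels$class_map); nc <- ncol(labels$class_map)
  box <- function(row) c(max(1, row$bbox_r1 - margin), min(nr, row$bbox_r2 + margin),
                         max(1, row$bbox_c1 - margin), min(nc, row$bbox_c2 + margin))
  b <- box(me)
  rr <- b[1]:b[2]; cc <- b[3]:b[4]
  g <- as.matrix(expand.grid(row = rr, col = cc))
  is_bg <- labels$class_map[g] == CLASS_BACKGROUND & labels$cell_id_map[g] == 0L
  g <- g[is_bg, , drop = FALSE]
  if (nrow(g) > 0 && nrow(cells) > 1) {
    d_me <- sqrt((g[, 1] - me$centroid_row)^2 + (g[, 2] - me$centroid_col)^2)
    keep <- rep(TRUE, nrow(g))
    for (k in seq_len(nrow(cells))) {
      other <- cells[k, ]
      if (other$cell_id == cell_id) next
      ob <- box(other)
      inside <- g[, 1] >= ob[1] & g[, 1] <= ob[2] & g[, 2] >= ob[3] & g[, 2] <= ob[4]
      if (!any(inside)) next
      d_other <- sqrt((g[inside, 1] - other$centroid_row)^2 +
                        (g[inside, 2] - other$centroid_col)^2)
      closer_other <- d_other < d_me[inside] |
        (d_other == d_me[inside] & other$cell_id < cell_id)
      keep[inside][closer_other] <- FALSE
    }
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) == 0)
    stop(errorCondition(
      sprintf("cell %d has no background surroundings within margin %g; increase the margin",
              cell_id, margin),
      class = c("saxscan_empty_surroundings", "error")))
  g
}

#' Cell-fragment filter criteria
#'
#' Pixel-count conditions used to drop connected components that are
#' fragments of cells rather than whole cells. The default constants
#' (nucleus >= 30 pixels, background surroundings strictly between 5000 and
#' 10000 pixels) are reconstructions at full-scan scale and should be
#' adapted to the scan size at hand; all are configurable.
#'
#' @param min_nucleus_pixels Minimum nucleus pixel count. Default 30.
#' @param background_pixel_bounds Open interval for the background
#'   (surroundings) pixel count. Default c(5000, 10000).
#' @param ratio_bounds Optional closed interval for N_cyt / N_nuc.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_nucleus_pixels = 30,
                            background_pixel_bounds = c(5000, 10000),
                            ratio_bounds = NULL) {
  if (min_nucleus_pixels < 0) stop_invalid("min_nucleus_pixels must be >= 0")
  if (length(background_pixel_bounds) != 2 ||
      background_pixel_bounds[1] > background_pixel_bounds[2])
    stop_invalid("background_pixel_bounds must be ordered")
  if (!is.null(ratio_bounds) &&
      (length(ratio_bounds) != 2 || ratio_bounds[1] > ratio_bounds[2]))
    stop_invalid("ratio_bounds must be ordered")
  structure(list(min_nucleus_pixels = min_nucleus_pixels,
                 background_pixel_bounds = background_pixel_bounds,
                 ratio_bounds = ratio_bounds), class = "filter_criteria")
}

#' Filter cell records by pixel-count criteria
#'
#' Keeps a record iff `N_nuc >= min_nucleus_pixels`, `N_bg` lies strictly
#' inside `background_pixel_bounds`, and (when configured)
#' `N_cyt / N_nuc` lies in `ratio_bounds`.
#'
#' @param records Data frame with columns `N_nuc`, `N_cyt`, `N_bg`.
#' @param criteria A [filter_criteria()].
#' @return List: `retained` (subset of `records`), `rejections` (named
#'   per-criterion rejection counts), and `keep` (logical vector).
#' @export
filter_cells <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (!all(c("N_nuc", "N_cyt", "N_bg") %in% names(records)))
    stop_invalid("`records` must have columns N_nuc, N_cyt, N_bg")
  fail_nuc <- records$N_nuc < criteria$min_nucleus_pixels
  fail_bg <- !(records$N_bg > criteria$background_pixel_bounds[1] &
                 records$N_bg < criteria$background_pixel_bounds[2])
  fail_ratio <- rep(FALSE, nrow(records))
  if (!is.null(criteria$ratio_bounds)) {
    ratio <- records$N_cyt / pmax(records$N_nuc, 1)
    fail_ratio <- ratio < criteria$ratio_bounds[1] | ratio > criteria$ratio_bounds[2]
  }
  keep <- !(fail_nuc | fail_bg | fail_ratio)
  list(retained = records[keep, , drop = FALSE],
       rejections = c(nucleus_pixels = sum(fail_nuc),
                      background_pixels = sum(fail_bg),
                      cyt_nuc_ratio = sum(fail_ratio)),
       keep = keep)
}

#' Segment a dark-field image into per-cell ROIs
#'
#' Full segmentation driver: Bradley mask, 8-connected cell labeling,
#' per-cell Otsu nucleus detection, per-cell background surroundings, and
#' fragment filtering. Pixels removed by morphological cleanup and pixels
#' of rejected cells are relabeled "disregarded" (class 3).
#'
#' @param df_image A [darkfield()] result (or a plain numeric matrix).
#' @param window_fraction,sensitivity,min_object_px Passed to
#'   [bradley_mask()].
#' @param margin Surroundings dilation margin (px). Default 20.
#' @param criteria A [filter_criteria()].
#' @return An object of class `segmentation`: `class_map` (0 background,
#'   1 cytoplasm, 2 nucleus, 3 disregarded), `cell_id_map`,
#'   `surroundings_map`, per-cell table `cells` (N_nuc, N_cyt, N_bg,
#'   bounding box, centroid, `retained`, Otsu threshold), and `rejections`.
#' @export
segment_darkfield <- function(df_image, window_fraction = 1 / 4,
                              sensitivity = 0.5, min_object_px = 20,
                              margin = 20, criteria = filter_criteria()) {
  values <- if (inherits(df_image, "darkfield_image")) df_image$values else df_image
  mask <- bradley_mask(values, window_fraction, sensitivity, min_object_px)
  removed <- attr(mask, "removed")
  cell_id_map <- label_cells(mask)
  n_cells <- max(cell_id_map)

  class_map <- matrix(CLASS_BACKGROUND, nrow(values), ncol(values))
  class_map[removed] <- CLASS_DISREGARDED
  class_map[cell_id_map > 0L] <- CLASS_CYTOPLASM

  cells <- data.frame(cell_id = integer(0), N_nuc = integer(0),
                      N_cyt = integer(0), N_bg = integer(0),
                      area = integer(0),
                      bbox_r1 = integer(0), bbox_r2 = integer(0),
                      bbox_c1 = integer(0), bbox_c2 = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      otsu_threshold = numeric(0), nucleus_flagged = logical(0))
  nucleus_px <- vector("list", n_cells)
  for (id in seq_len(n_cells)) {
    px <- which(cell_id_map == id, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    nuc <- nucleus_by_otsu(values, px)
    nucleus_px[[id]] <- nuc$pixels
    if (nrow(nuc$pixels) > 0) class_map[nuc$pixels] <- CLASS_NUCLEUS
    cells <- rbind(cells, data.frame(
      cell_id = id, N_nuc = nrow(nuc$pixels),
      N_cyt = nrow(px) - nrow(nuc$pixels), N_bg = NA_integer_,
      area = nrow(px),
      bbox_r1 = min(px[, 1]), bbox_r2 = max(px[, 1]),
      bbox_c1 = min(px[, 2]), bbox_c2 = max(px[, 2]),
      centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
      otsu_threshold = nuc$threshold, nucleus_flagged = nuc$flagged))
  }

  seg <- structure(list(class_map = class_map, cell_id_map = cell_id_map,
                        surroundings_map = matrix(0L, nrow(values), ncol(values)),
                        cells = cells, margin = margin, criteria = criteria),
                   class = "segmentation")
  for (id in seq_len(n_cells)) {
    surr <- tryCatch(cell_surroundings(seg, id, margin),
                     saxscan_empty_surroundings = function(e) NULL)
    if (is.null(surr)) {
      seg$cells$N_bg[id] <- 0L
    } else {
      seg$cells$N_bg[id] <- nrow(surr)
      seg$surroundings_map[surr] <- id
    }
  }

  flt <- filter_cells(seg$cells, criteria)
  seg$cells$retained <- flt$keep
  seg$rejections <- flt$rejections
  for (id in which(!flt$keep))
    seg$class_map[seg$cell_id_map == id] <- CLASS_DISREGARDED
  seg$nucleus_pixels <- nucleus_px
  seg
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d cells (%d retained) on %d x %d scan positions\n",
              nrow(x$cells), sum(x$cells$retained), nrow(x$class_map),
              ncol(x$class_map)))
  invisible(x)
}

#' Per-cell geometry table as CSV
#'
#' @param seg A [segment_darkfield()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  write.csv(seg$cells, path, row.names = FALSE)
  invisible(path)
}
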