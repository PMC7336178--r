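# Segmentation: Bradley mask, connected components, per-cell Otsu,
# surroundings, fragment filtering.

test_that("bradley mask matches the brute-force sliding-window oracle", {
  set.seed(101)
  for (rep in 1:3) {
    img <- matrix(runif(48 * 40), 48, 40)
    img[10:20, 8:18] <- img[10:20, 8:18] + 2
    got <- bradley_mask(img, window_fraction = 1 / 4, sensitivity = 0.3,
                        min_object_px = 0, fill_holes = FALSE)
    expect_identical(unclass(got)[, ], bf_bradley(img, 1 / 4, 0.3))
  }
})

test_that("bradley mask basic behavior and rescale invariance", {
  # constant images threshold to nothing
  expect_true(all(!bradley_mask(matrix(5, 30, 30))))
  expect_true(all(!bradley_mask(matrix(0, 30, 30))))

  # bright square on zero background is fully recovered
  img <- matrix(0, 60, 60)
  img[21:40, 21:40] <- 10
  m <- bradley_mask(img, window_fraction = 1, sensitivity = 0.5)
  expect_true(all(m[21:40, 21:40]))   # recall = 1
  # affine rescaling v -> a*v leaves the mask unchanged
  m2 <- bradley_mask(img * 37.5, window_fraction = 1, sensitivity = 0.5)
  expect_identical(unclass(m)[, ], unclass(m2)[, ])
})

test_that("cell labeling is 8-connected with raster-ordered ids", {
  expect_true(all(label_cells(matrix(FALSE, 5, 5)) == 0L))
  # two blobs touching only diagonally merge under 8-connectivity
  m <- matrix(FALSE, 6, 6)
  m[2:3, 2:3] <- TRUE
  m[4:5, 4:5] <- TRUE
  lab <- label_cells(m)
  expect_identical(max(lab), 1L)
  # separated blobs get ids in raster order of their first pixel
  m2 <- matrix(FALSE, 8, 8)
  m2[6:7, 1:2] <- TRUE   # later in raster order
  m2[1:2, 5:6] <- TRUE   # first pixel (1,5) comes first
  lab2 <- label_cells(m2)
  expect_identical(lab2[1, 5], 1L)
  expect_identical(lab2[6, 1], 2L)
})

test_that("otsu threshold maximizes between-class variance", {
  # perfectly bimodal toy cell: the two bright pixels are the nucleus
  vals <- c(0, 0, 0, 10, 10)
  thr <- otsu_threshold(vals)
  expect_identical(sum(vals > thr), 2L)
  expect_true(is.na(otsu_threshold(c(3, 3, 3))))

  # exhaustive brute-force equivalence on random samples
  set.seed(102)
  for (rep in 1:5) {
    v <- c(rnorm(60, 0, 1), rnorm(25, 5, 1))
    expect_equal(otsu_threshold(v), bf_otsu(v), tolerance = 1e-12)
  }
})

test_that("nucleus otsu picks the largest bright component and flags degenerates", {
  img <- matrix(0, 10, 10)
  cellpx <- which(img == 0, arr.ind = TRUE)
  img[2:4, 2:4] <- 10       # large bright blob
  img[8, 8] <- 10           # separate bright single pixel
  res <- nucleus_by_otsu(img, cellpx)
  expect_false(res$flagged)
  expect_identical(nrow(res$pixels), 9L)
  expect_true(all(res$pixels[, 1] %in% 2:4))
  # constant cell: empty, flagged
  res0 <- nucleus_by_otsu(matrix(1, 5, 5), which(matrix(TRUE, 5, 5), arr.ind = TRUE))
  expect_true(res0$flagged)
  expect_identical(nrow(res0$pixels), 0L)
})

# a deterministic two-cell segmentation for surroundings tests
two_cell_seg <- function() {
  img <- matrix(0, 40, 60)
  img[8:15, 8:15] <- 5;  img[10:12, 10:12] <- 9
  img[8:15, 40:47] <- 5; img[10:12, 42:44] <- 9
  seg <- segment_darkfield(img, window_fraction = 1, sensitivity = 0.5,
                           min_object_px = 5, margin = 10,
                           criteria = filter_criteria(1, c(0, Inf)))
  seg
}

test_that("cell surroundings are background-only, margin-controlled, disjoint", {
  seg <- two_cell_seg()
  expect_identical(nrow(seg$cells), 2L)

  # margin 0 on a rectangular cell: the tight box holds no background
  expect_error(cell_surroundings(seg, 1, margin = 0),
               class = "saxscan_empty_surroundings")
  # small margin: only background pixels inside the dilated box
  s0 <- cell_surroundings(seg, 1, margin = 3)
  bb <- seg$cells[1, ]
  expect_true(all(s0[, 1] >= bb$bbox_r1 - 3 & s0[, 1] <= bb$bbox_r2 + 3))
  expect_true(all(s0[, 2] >= bb$bbox_c1 - 3 & s0[, 2] <= bb$bbox_c2 + 3))
  expect_true(all(seg$class_map[s0] == 0L))

  # huge margin: all background pixels of the dilated box not claimed by
  # a nearer cell; the two surroundings sets are disjoint
  s1 <- cell_surroundings(seg, 1, margin = 100)
  s2 <- cell_surroundings(seg, 2, margin = 100)
  k1 <- paste(s1[, 1], s1[, 2]); k2 <- paste(s2[, 1], s2[, 2])
  expect_length(intersect(k1, k2), 0)
  # every background pixel belongs to the nearer centroid
  c1 <- unlist(seg$cells[1, c("centroid_row", "centroid_col")])
  c2 <- unlist(seg$cells[2, c("centroid_row", "centroid_col")])
  d1 <- sqrt((s1[, 1] - c1[1])^2 + (s1[, 2] - c1[2])^2)
  d2 <- sqrt((s1[, 1] - c2[1])^2 + (s1[, 2] - c2[2])^2)
  expect_true(all(d1 <= d2))

  expect_error(cell_surroundings(seg, 99), class = "saxscan_invalid_argument")
})

test_that("cell filtering applies the pixel-count criteria", {
  rec <- data.frame(cell_id = 1:5,
                    N_nuc = c(29, 30, 200, 45, 31),
                    N_cyt = c(400, 500, 900, 20, 600),
                    N_bg = c(7000, 7000, 4000, 7000, 12000))
  out <- filter_cells(rec, filter_criteria())
  # hand enumeration: 1 fails nucleus, 3 and 5 fail background bounds
  expect_identical(out$retained$cell_id, c(2L, 4L))
  expect_identical(unname(out$rejections["nucleus_pixels"]), 1L)
  expect_identical(unname(out$rejections["background_pixels"]), 2L)

  # unbounded criteria: identity
  all_in <- filter_cells(rec, filter_criteria(0, c(-Inf, Inf)))
  expect_identical(all_in$retained, rec)

  # ratio criterion
  # ratios: 13.8, 16.7, 4.5, 0.44, 19.4 -> only cells 1 and 3 fall in [1, 15]
  out2 <- filter_cells(rec, filter_criteria(0, c(0, Inf), ratio_bounds = c(1, 15)))
  expect_identical(out2$retained$cell_id, c(1L, 3L))
})

test_that("segmentation partitions the scan and rejects fragments as disregarded", {
  seg <- two_cell_seg()
  expect_true(all(seg$class_map %in% 0:3))
  # nucleus and cytoplasm pixels together reconstruct each retained cell body
  for (id in seg$cells$cell_id[seg$cells$retained]) {
    body <- seg$cell_id_map == id
    cls <- seg$class_map[body]
    expect_true(all(cls %in% 1:2))
    expect_identical(sum(cls == 2L), seg$cells$N_nuc[id])
    expect_identical(sum(cls == 1L), seg$cells$N_cyt[id])
  }
  # a rejecting criterion relabels the cell disregarded
  img <- matrix(0, 40, 60)
  img[8:15, 8:15] <- 5; img[10:12, 10:12] <- 9
  seg2 <- segment_darkfield(img, window_fraction = 1, sensitivity = 0.5,
                            min_object_px = 5, margin = 10,
                            criteria = filter_criteria(min_nucleus_pixels = 500))
  expect_false(any(seg2$cells$retained))
  expect_true(all(seg2$class_map[seg2$cell_id_map > 0] == 3L))
})

test_that("segmentation recovers phantom cells on a simulated dark-field", {
  grid <- scan_grid(200, 200)
  ph <- make_phantom(20, grid, seed = 42)
  geom <- std_geom(64)
  stack <- simulate_scan(ph, geom, seed = 43)
  df <- darkfield(stack, 2.99)
  seg <- segment_darkfield(df, criteria = filter_criteria(10, c(50, 1e7)))

  # cell-count error within 10%
  expect_lte(abs(nrow(seg$cells) - 20) / 20, 0.1)

  # mask overlap with the true cell support
  truth <- ph$class_map > 0
  found <- seg$cell_id_map > 0
  jaccard <- sum(truth & found) / sum(truth | found)
  expect_gte(jaccard, 0.8)

  # nucleus centroid within 2 px of the true nucleus centroid for >= 90%
  hits <- 0
  for (i in seq_len(nrow(seg$cells))) {
    np <- which(seg$cell_id_map == i & seg$class_map == 2L, arr.ind = TRUE)
    if (nrow(np) == 0) next
    owner <- ph$cell_id_map[round(seg$cells$centroid_row[i]),
                            round(seg$cells$centroid_col[i])]
    if (owner == 0) next
    tn <- which(ph$cell_id_map == owner & ph$class_map == 2L, arr.ind = TRUE)
    if (sqrt(sum((colMeans(np) - colMeans(tn))^2)) <= 2) hits <- hits + 1
  }
  expect_gte(hits / nrow(seg$cells), 0.9)
})
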