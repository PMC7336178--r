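# Modeling: normalization, background subtraction, power-law fits, dose.

test_that("exposure normalization divides intensities by the exposure", {
  p <- radial_profile(c(0.2, 0.4, 0.6), c(4, 2, 1), c(10, 10, 10))
  expect_equal(normalize_exposure(p, 1)$intensity, p$intensity)
  expect_equal(normalize_exposure(p, 2)$intensity, p$intensity / 2)
  expect_error(normalize_exposure(p, 0), class = "saxscan_invalid_argument")
})

test_that("normalized profiles from different exposure times agree", {
  # the same expectation observed at 1.34 ms and 20 ms gives compatible
  # per-ms profiles once normalized (Poisson tolerance)
  q <- seq(0.19, 1.72, length.out = 100)
  I <- 0.05 * q^-4 + 0.002
  n_px <- 40; n_pat <- 50
  p_fast <- normalize_exposure(
    simulate_radial_profile(q, I, 1.34, n_pat, n_px, seed = 61), 1.34)
  p_slow <- normalize_exposure(
    simulate_radial_profile(q, I, 20, n_pat, n_px, seed = 62), 20)
  sigma <- sqrt(I / (1.34 * n_pat * n_px) + I / (20 * n_pat * n_px))
  z <- (p_fast$intensity - p_slow$intensity) / sigma
  expect_lt(mean(abs(z) < 4), 1.001)
  expect_true(all(abs(z) < 6))
  expect_lt(abs(mean(z)), 0.5)
})

test_that("background subtraction is bin-wise and keeps negatives", {
  q <- c(0.2, 0.4, 0.6)
  s <- radial_profile(q, c(5, 5, 5), c(10, 10, 10))
  b <- radial_profile(q, c(2, 2, 7), c(10, 10, 10))
  out <- subtract_background(s, b)
  expect_equal(out$intensity, c(3, 3, -2))
  expect_equal(subtract_background(s, s)$intensity, c(0, 0, 0))

  # invalid bins propagate
  b2 <- radial_profile(q, c(2, NA, 2), c(10, 0, 10))
  expect_true(is.na(subtract_background(s, b2)$intensity[2]))

  # binning mismatch
  b3 <- radial_profile(c(0.2, 0.4, 0.61), c(1, 1, 1), c(10, 10, 10))
  expect_error(subtract_background(s, b3), class = "saxscan_invalid_argument")
})

test_that("noiseless power-law fits are exact over an (K, alpha, B) grid", {
  q <- seq(0.19, 1.72, length.out = 80)
  for (alpha in c(-5, -4.1, -3, -2.2, -1.5)) {
    for (K in c(0.02, 1)) {
      B <- 0.05 * K
      prof <- radial_profile(q, K * q^alpha + B, rep(50, length(q)))
      f <- fit_power_law(prof)
      expect_true(f$converged)
      expect_equal(f$K, K, tolerance = 1e-6)
      expect_equal(f$alpha, alpha, tolerance = 1e-6)
      expect_equal(f$B, B, tolerance = 1e-6 * K)
    }
  }
})

test_that("power-law fit is scale-equivariant and validates its inputs", {
  q <- seq(0.19, 1.72, length.out = 60)
  prof <- radial_profile(q, 0.3 * q^-3.5 + 0.01, rep(50, length(q)))
  f1 <- fit_power_law(prof)
  f2 <- fit_power_law(radial_profile(q, prof$intensity * 8, prof$n_pixels))
  expect_equal(f2$K / f1$K, 8, tolerance = 1e-6)
  expect_equal(f2$B / f1$B, 8, tolerance = 1e-4)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-8)

  expect_error(fit_power_law(radial_profile(q[1:5], prof$intensity[1:5],
                                            prof$n_pixels[1:5])),
               class = "saxscan_invalid_argument")
  expect_error(fit_power_law(prof, q_range = c(1, 0.2)),
               class = "saxscan_invalid_argument")
})

test_that("sphere profiles fit to the Porod exponent in the asymptotic regime", {
  q <- seq(2, 6, length.out = 200)
  prof <- radial_profile(q, sphere_profile(q, 4, polydispersity = 0.15),
                         rep(1, length(q)))
  f <- fit_power_law(prof, q_range = c(2, 6), fix_B = TRUE)
  expect_true(f$converged)
  expect_equal(f$alpha, -4, tolerance = 0.15 / 4)
})

test_that("alpha recovery from Poisson-noisy profiles is unbiased with calibrated CIs", {
  q <- seq(0.19, 1.72, length.out = 154)
  n <- 200
  alpha_true <- -4.1
  alpha_hat <- se_hat <- numeric(n)
  set.seed(63)
  for (i in seq_len(n)) {
    K <- rlnorm(1, log(0.05), 0.25)
    B <- runif(1, 0.001, 0.003)
    prof <- normalize_exposure(
      simulate_radial_profile(q, K * q^alpha_true + B, 1.34,
                              n_patterns = 300, n_pixels = 40,
                              seed = 64 + i), 1.34)
    f <- fit_power_law(prof, weighting = "poisson")
    alpha_hat[i] <- f$alpha
    se_hat[i] <- f$se["alpha"]
  }
  expect_lt(abs(mean(alpha_hat) - alpha_true), 0.05)
  coverage <- mean(abs(alpha_hat - alpha_true) <= se_hat)
  expect_gte(coverage, 0.58)
  expect_lte(coverage, 0.78)
})

test_that("dose follows the Howells-type expression and its scalings", {
  d0 <- dose(dose_params())
  expect_equal(d0, 4.84e6, tolerance = 0.01)
  expect_identical(floor(log10(d0)), 6)  # the ~1e6 Gy regime

  # exact linearity in exposure
  d20 <- dose(dose_params(exposure_s = 20e-3))
  expect_equal(d20 / d0, 20 / 1.34)

  # inverse proportionality to the step area
  dq <- dose(dose_params(step_y_m = 0.25e-6, step_z_m = 0.25e-6))
  expect_equal(dq / d0, 4)

  # multiplicative in flux and energy
  expect_equal(dose(dose_params(flux_ph_s = 3.4e12)) / d0, 2)
  expect_equal(dose(dose_params(energy_keV = 26)) / d0, 2)
  expect_error(dose_params(flux_ph_s = -1), class = "saxscan_invalid_argument")
})

test_that("row-matched background follows a row-dependent flux drift", {
  grid <- scan_grid(60, 60)
  ph <- make_phantom(1, grid, seed = 11,
                     params = phantom_params(cell_semiaxis_px = c(8, 10)))
  geom <- std_geom(96)
  drift <- seq(0.7, 1.3, length.out = 60)
  stack <- simulate_scan(ph, geom, seed = 12, row_flux = drift)
  seg <- segment_darkfield(darkfield(stack, 2.99), window_fraction = 0.5,
                           criteria = filter_criteria(10, c(50, 1e7)))
  expect_identical(nrow(seg$cells), 1L)

  px <- which(seg$cell_id_map == 1, arr.ind = TRUE)
  pt <- px[which.min(px[, 1]), ]          # topmost cell row
  rb <- row_matched_background(stack, seg, 1, pt)

  # single-pixel row: profile equals that frame's profile
  row1 <- which(seg$surroundings_map[pt[1], ] == 1)
  if (length(row1) == 1) {
    solo <- integrate_scan_points(stack, cbind(pt[1], row1))
    expect_equal(rb$intensity, solo$intensity)
  }

  sel <- array(seg$surroundings_map %in% 1, dim(seg$surroundings_map))
  surr <- which(sel, arr.ind = TRUE)
  wb <- integrate_scan_points(stack, surr)
  bprof <- azimuthal_integrate(expected_pattern(ph, c(1, 1), geom) *
                                 stack$exposure_ms, geom)
  ok <- !is.na(rb$intensity) & rb$q > 0.3 & rb$q < 1.5
  ratio_rb <- mean(rb$intensity[ok] / bprof$intensity[ok])
  ratio_wb <- mean(wb$intensity[ok] / bprof$intensity[ok])
  # the row-matched estimate tracks the drift at the cell's row, the
  # whole-surroundings estimate sits at the average drift and is biased
  expect_lt(abs(ratio_rb - drift[pt[1]]), 0.03)
  expect_gt(abs(ratio_wb - drift[pt[1]]), abs(ratio_rb - drift[pt[1]]))

  # errors: a scan point outside the cell; a row with no surroundings
  bgpt <- which(seg$cell_id_map == 0, arr.ind = TRUE)[1, ]
  expect_error(row_matched_background(stack, seg, 1, bgpt),
               class = "saxscan_invalid_argument")
})

test_that("subtracted phantom profiles recover the cell power law", {
  grid <- scan_grid(60, 60)
  ph <- make_phantom(1, grid, seed = 13,
                     params = phantom_params(cell_semiaxis_px = c(8, 10)))
  geom <- std_geom(96)
  stack <- simulate_scan(ph, geom, seed = 14)
  seg <- segment_darkfield(darkfield(stack, 2.99), window_fraction = 0.5,
                           criteria = filter_criteria(10, c(50, 1e7)))
  cyt <- which(seg$cell_id_map == 1 & seg$class_map == 1L, arr.ind = TRUE)
  sel <- array(seg$surroundings_map %in% 1, dim(seg$surroundings_map))
  surr <- which(sel, arr.ind = TRUE)
  sig <- normalize_exposure(integrate_scan_points(stack, cyt), stack$exposure_ms)
  bg <- normalize_exposure(integrate_scan_points(stack, surr), stack$exposure_ms)
  sub <- subtract_background(sig, bg)
  # compare against the pixel-binned noiseless cell term
  pt <- cyt[1, ]
  qdet <- build_qmap(geom)$q
  cell_term <- ph$K_map[pt[1], pt[2]] * qdet^ph$alpha_map[pt[1], pt[2]] +
    ph$B_map[pt[1], pt[2]]
  ref <- azimuthal_integrate(cell_term, geom)
  ok <- !is.na(sub$intensity) & sub$q > 0.25 & sub$q < 1.6
  rel <- abs(sub$intensity[ok] - ref$intensity[ok]) / ref$intensity[ok]
  expect_lt(median(rel), 0.1)

  # and the nucleus K ranks above the cytoplasm K (denser, thicker)
  nuc <- which(seg$cell_id_map == 1 & seg$class_map == 2L, arr.ind = TRUE)
  sig_n <- normalize_exposure(integrate_scan_points(stack, nuc), stack$exposure_ms)
  f_c <- fit_power_law(sub)
  f_n <- fit_power_law(subtract_background(sig_n, bg))
  expect_true(f_c$converged && f_n$converged)
  expect_gt(f_n$K, f_c$K)
})
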