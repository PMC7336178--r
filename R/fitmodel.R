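## Modeling: exposure normalization, background subtraction (including the
## row-matched strategy for single-pattern analysis), non-linear
## least-squares power-law fits I(q) = K * q^alpha + B, and radiation-dose
## estimation.

KEV_TO_JOULE <- 1.602176634e-16

#' Mass attenuation coefficient over density for "average protein"
#'
#' 2.55 cm^2 g^-1 for cellular material approximated by the average-protein
#' empirical formula H50 C30 N9 O10 S at 13 keV (Howells-type dose
#' estimate).
#' @export
MU_OVER_RHO_PROTEIN <- 2.55

#' Normalize a radial profile by exposure time
#'
#' @param profile A [radial_profile()] in counts per pixel per pattern.
#' @param exposure_ms Exposure per pattern (ms).
#' @return A [radial_profile()] in counts per pixel per ms.
#' @export
normalize_exposure <- function(profile, exposure_ms) {
  stopifnot(inherits(profile, "radial_profile"))
  check_scalar_positive(exposure_ms, "exposure_ms")
  radial_profile(profile$q, profile$intensity / exposure_ms, profile$n_pixels)
}

#' Subtract a background profile from a signal profile
#'
#' Bin-wise difference; requires identical q binning. Bins invalid in
#' either input are invalid in the output. Negative differences are kept
#' (clamping would bias the additive constant of a subsequent fit).
#'
#' @param signal,background [radial_profile()]s on the same bins.
#' @return A [radial_profile()]; `n_pixels` is taken from `signal`.
#' @export
subtract_background <- function(signal, background) {
  stopifnot(inherits(signal, "radial_profile"), inherits(background, "radial_profile"))
  if (length(signal$q) != length(background$q) ||
      any(abs(signal$q - background$q) > 1e-9 * pmax(abs(signal$q), 1)))
    stop_invalid("signal and background must share the same q binning")
  diff <- signal$intensity - background$intensity
  n_px <- ifelse(is.na(diff), 0L, signal$n_pixels)
  out <- radial_profile(signal$q, diff, n_px)
  out$intensity[n_px == 0 & !is.na(diff)] <- diff[n_px == 0 & !is.na(diff)]
  out
}

#' Row-matched background profile for single-pattern analysis
#'
#' For a scan position inside a cell, averages the background patterns of
#' that cell's surroundings restricted to the same scan row (patterns on
#' the same row are acquired close in time, so slow drifts of the incoming
#' beam intensity cancel), then azimuthally integrates.
#'
#' @param stack A `pattern_stack`.
#' @param labels A [segment_darkfield()] result.
#' @param cell_id Cell id owning the scan position.
#' @param scan_point Integer (row, col) scan position inside the cell.
#' @param n_bins,q_range Binning, as in [azimuthal_integrate()].
#' @param qmap Optional precomputed [build_qmap()].
#' @return A [radial_profile()] (counts per pixel, not yet normalized).
#' @export
row_matched_background <- function(stack, labels, cell_id, scan_point,
                                   n_bins = 300, q_range = c(0, 2.99),
                                   qmap = NULL) {
  stopifnot(inherits(stack, "pattern_stack"), inherits(labels, "segmentation"))
  scan_point <- as.integer(scan_point)
  if (labels$cell_id_map[scan_point[1], scan_point[2]] != cell_id)
    stop_invalid("scan_point does not belong to cell ", cell_id)
  in_row <- which(labels$surroundings_map[scan_point[1], ] == cell_id)
  if (length(in_row) == 0)
    stop(errorCondition(
      sprintf("no surroundings of cell %d on scan row %d; fall back to the per-cell background",
              cell_id, scan_point[1]),
      class = c("saxscan_empty_row_background", "error")))
  idx <- cbind(rep(scan_point[1], length(in_row)), in_row)
  integrate_scan_points(stack, idx, n_bins = n_bins, q_range = q_range, qmap = qmap)
}

#' Fit a power law I(q) = K * q^alpha + B to a radial profile
#'
#' Unweighted non-linear least squares (Levenberg-Marquardt) on linear
#' intensity over the valid bins inside `q_range`. Initial values come from
#' a log-log linear regression of `I - min(I)`; `B` starts at `min(I)/2`.
#' Bounds: `K > 0`, `alpha` in `alpha_bounds` (physical decays only),
#' `B` unbounded. Optional Poisson-motivated weights (1/max(I, eps)) via
#' `weighting = "poisson"`. Non-convergence is flagged, not an error.
#'
#' @param profile A [radial_profile()].
#' @param q_range Fit range (nm^-1). Default c(0.185, 1.723), probing
#'   real-space features between 34.0 and 3.6 nm.
#' @param fix_B Fix the additive constant instead of fitting it.
#' @param B_value Value of B when fixed. Default 0.
#' @param alpha_bounds Bounds for the exponent. Default c(-8, 0).
#' @param weighting `"none"` (default) or `"poisson"`.
#' @param min_bins Minimum number of valid bins required. Default 8.
#' @return An object of class `power_law_fit`: `K`, `alpha`, `B`, standard
#'   errors, covariance, `converged`, `resid_norm`, `n_bins`, `q_range`.
#' @export
fit_power_law <- function(profile, q_range = c(0.185, 1.723), fix_B = FALSE,
                          B_value = 0, alpha_bounds = c(-8, 0),
                          weighting = c("none", "poisson"), min_bins = 8) {
  stopifnot(inherits(profile, "radial_profile"))
  weighting <- match.arg(weighting)
  if (q_range[1] >= q_range[2]) stop_invalid("q_range must satisfy min < max")
  sel <- !is.na(profile$intensity) & profile$q >= q_range[1] & profile$q <= q_range[2]
  q <- profile$q[sel]; I <- profile$intensity[sel]
  if (length(q) < min_bins)
    stop_invalid("need at least ", min_bins, " valid bins inside q_range, got ", length(q))

  B0 <- if (fix_B) B_value else min(I) / 2
  ## with B known the power-law term is I - B; otherwise shift by min(I)
  shifted <- if (fix_B) I - B_value else I - min(I)
  pos <- shifted > 0
  if (sum(pos) >= 2) {
    ll <- lm(log(shifted[pos]) ~ log(q[pos]))
    alpha0 <- unname(coef(ll)[2]); K0 <- exp(unname(coef(ll)[1]))
  } else {
    alpha0 <- -3; K0 <- max(abs(I[1]), 1e-12) * q[1]^3
  }
  alpha0 <- min(max(alpha0, alpha_bounds[1] + 1e-3), alpha_bounds[2] - 1e-3)
  K0 <- max(K0, 1e-12)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  dat <- data.frame(q = q, I = I)
  args <- if (fix_B) {
    list(I ~ K * q^alpha + B_value, data = dat,
         start = list(K = K0, alpha = alpha0),
         lower = c(K = 1e-30, alpha = alpha_bounds[1]),
         upper = c(K = Inf, alpha = alpha_bounds[2]), control = ctrl)
  } else {
    list(I ~ K * q^alpha + B, data = dat,
         start = list(K = K0, alpha = alpha0, B = B0),
         lower = c(K = 1e-30, alpha = alpha_bounds[1], B = -Inf),
         upper = c(K = Inf, alpha = alpha_bounds[2], B = Inf), control = ctrl)
  }
  if (weighting == "poisson")
    args$weights <- 1 / pmax(abs(I), max(abs(I)) * 1e-6)
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(K = NA_real_, alpha = NA_real_, B = NA_real_,
                          se = c(K = NA_real_, alpha = NA_real_, B = NA_real_),
                          cov = NULL, converged = FALSE, resid_norm = NA_real_,
                          n_bins = length(q), q_range = q_range, fix_B = fix_B),
                     class = "power_law_fit"))
  }
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(vc)) sqrt(diag(vc)) else setNames(rep(NA_real_, length(cf)), names(cf))
  structure(list(
    K = unname(cf["K"]), alpha = unname(cf["alpha"]),
    B = if (fix_B) B_value else unname(cf["B"]),
    se = c(K = unname(se["K"]), alpha = unname(se["alpha"]),
           B = if (fix_B) 0 else unname(se["B"])),
    cov = vc, converged = isTRUE(fit$convInfo$isConv),
    resid_norm = sqrt(sum(residuals(fit)^2)),
    n_bins = length(q), q_range = q_range, fix_B = fix_B),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: K = %.4g, alpha = %.4f, B = %.4g (%s, %d bins in [%.3f, %.3f])\n",
              x$K, x$alpha, x$B, if (x$converged) "converged" else "NOT converged",
              x$n_bins, x$q_range[1], x$q_range[2]))
  invisible(x)
}

#' Radiation-dose parameters
#'
#' @param mu_over_rho_cm2_g Mass attenuation coefficient over mass density
#'   (cm^2 g^-1). Default [MU_OVER_RHO_PROTEIN].
#' @param flux_ph_s Photon flux (photons s^-1). Default 1.7e12.
#' @param energy_keV Photon energy (keV). Default 13.0.
#' @param exposure_s Exposure per scan position (s).
#' @param step_y_m,step_z_m Scan step sizes (m). Default 0.5 um.
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(mu_over_rho_cm2_g = MU_OVER_RHO_PROTEIN,
                        flux_ph_s = 1.7e12, energy_keV = 13.0,
                        exposure_s = 1.34e-3,
                        step_y_m = 0.5e-6, step_z_m = 0.5e-6) {
  for (nm in c("mu_over_rho_cm2_g", "flux_ph_s", "energy_keV", "exposure_s",
               "step_y_m", "step_z_m"))
    check_scalar_positive(get(nm), nm)
  structure(list(mu_over_rho_cm2_g = mu_over_rho_cm2_g, flux_ph_s = flux_ph_s,
                 energy_keV = energy_keV, exposure_s = exposure_s,
                 step_y_m = step_y_m, step_z_m = step_z_m),
            class = "dose_params")
}

#' Estimate the absorbed X-ray dose per scan position
#'
#' `D = (mu/rho) * Phi * E * T / (dy * dz)` in Gy (J kg^-1): every photon
#' crossing the step-size area deposits its energy weighted by the mass
#' attenuation over density of the material. Exactly linear in flux, energy
#' and exposure, and inversely proportional to the step area. With the
#' default beam parameters and T = 1.34 ms the dose is ~5e6 Gy (order of
#' magnitude 1e6).
#'
#' @param params A [dose_params()].
#' @return Dose in Gy.
#' @export
dose <- function(params = dose_params()) {
  stopifnot(inherits(params, "dose_params"))
  mu_over_rho_m2_kg <- params$mu_over_rho_cm2_g * 1e-1  # cm^2/g -> m^2/kg
  energy_J <- params$energy_keV * KEV_TO_JOULE
  mu_over_rho_m2_kg * params$flux_ph_s * energy_J * params$exposure_s /
    (params$step_y_m * params$step_z_m)
}
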