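## Analytic, orientation-averaged form factors for the simulator and for
## Porod-limit validation of the power-law fitter: homogeneous sphere,
## infinitely thin rod and infinitely thin disc. In their asymptotic
## regimes these decay as q^-4, q^-1 and q^-2 respectively, which is the
## classic morphological reading of the power-law exponent.

#' Sphere form factor, optionally size-averaged
#'
#' Orientation-averaged scattering of a homogeneous sphere of radius `R`:
#' `P(q) = [3 (sin u - u cos u) / u^3]^2` with `u = qR`, normalized so
#' `P(0) = 1`. With `polydispersity > 0` the profile is the number average
#' of `P(q; R')` over a normal size distribution with mean `radius_nm` and
#' relative standard deviation `polydispersity`, evaluated by 61-point
#' Gauss-Hermite quadrature and truncated to positive radii. Size averaging
#' damps the sharp minima and exposes the smooth Porod `q^-4` envelope.
#'
#' @param q Scattering-vector magnitudes (nm^-1), non-negative.
#' @param radius_nm Mean sphere radius (nm).
#' @param polydispersity Relative standard deviation of the radius
#'   (dimensionless, >= 0). Default 0 (monodisperse).
#' @return Intensities on the `q` grid, `P(0) = 1`.
#' @export
sphere_profile <- function(q, radius_nm, polydispersity = 0) {
  check_scalar_positive(radius_nm, "radius_nm")
  if (polydispersity < 0) stop_invalid("polydispersity must be >= 0")
  if (any(q < 0)) stop_invalid("q must be non-negative")
  if (polydispersity == 0) return(.sphere_p(q * radius_nm))
  gh <- pracma::gaussHermite(61)
  radii <- radius_nm + sqrt(2) * polydispersity * radius_nm * gh$x
  keep <- radii > 0
  w <- gh$w[keep] / sum(gh$w[keep])
  acc <- numeric(length(q))
  for (i in seq_along(w)) acc <- acc + w[i] * .sphere_p(q * radii[keep][i])
  acc
}

.sphere_p <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- 1 - u[small]^2 / 5      # series limit at u -> 0
  us <- u[!small]
  out[!small] <- (3 * (sin(us) - us * cos(us)) / us^3)^2
  out
}

#' Thin-rod form factor
#'
#' Orientation-averaged scattering of an infinitely thin rod of length `L`:
#' `P(q) = 2 Si(x)/x - 4 sin^2(x/2)/x^2`, `x = qL`, with `Si` the sine
#' integral; `P(0) = 1` and `P ~ pi/x` for `x >> 1` (power-law exponent -1).
#'
#' @param q Scattering-vector magnitudes (nm^-1), non-negative.
#' @param length_nm Rod length (nm).
#' @return Intensities on the `q` grid.
#' @export
rod_profile <- function(q, length_nm) {
  check_scalar_positive(length_nm, "length_nm")
  if (any(q < 0)) stop_invalid("q must be non-negative")
  x <- q * length_nm
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small]^2 / 36
  xs <- x[!small]
  if (length(xs))
    out[!small] <- 2 * pracma::Si(xs) / xs - 4 * sin(xs / 2)^2 / xs^2
  out
}

#' Thin-disc form factor
#'
#' Orientation-averaged scattering of an infinitely thin disc of radius `R`:
#' `P(q) = (2/x^2) * (1 - J1(2x)/x)`, `x = qR`, with `J1` the first-order
#' Bessel function; `P(0) = 1` and `P ~ 2/x^2` for `x >> 1` (exponent -2).
#'
#' @param q Scattering-vector magnitudes (nm^-1), non-negative.
#' @param radius_nm Disc radius (nm).
#' @return Intensities on the `q` grid.
#' @export
disc_profile <- function(q, radius_nm) {
  check_scalar_positive(radius_nm, "radius_nm")
  if (any(q < 0)) stop_invalid("q must be non-negative")
  x <- q * radius_nm
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- 1 - x[small]^2 / 6
  xs <- x[!small]
  out[!small] <- (2 / xs^2) * (1 - besselJ(2 * xs, 1) / xs)
  out
}
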