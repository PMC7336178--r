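# saxscan

Analysis of high-throughput **scanning small-angle X-ray scattering
(scanning SAXS)** experiments on adherent cells, together with a forward
simulator so the whole pipeline can be exercised and validated without
beamline data.

In a scanning-SAXS experiment a focused X-ray beam is raster-scanned across
a sample (here: freeze-dried cells on a Si₃N₄ membrane, 0.5 µm steps,
millisecond exposures) and one 2D scattering pattern is recorded per scan
position. A full window scan of 2974 × 2991 positions yields 8,895,234
patterns covering hundreds of cells — far too many for manual region
selection. `saxscan` implements the reduction and analysis chain such
experiments need:

1. **Dark-field contrast** — per scan position, the summed scattered
   intensity over the detector region of interest with
   q ≤ 2.99 nm⁻¹, where q = (4π/λ) sin θ and θ is half the scattering
   angle. Plotted on the scan grid this gives a label-free image of the
   cells.
2. **Segmentation** — adaptive (Bradley) local thresholding separates cells
   from background; a per-cell Otsu threshold separates each nucleus from
   its cytoplasm (the nucleus is thicker and denser, hence brighter in
   dark-field); pixel-count criteria discard cell fragments.
3. **Radial profiles and power-law fits** — azimuthal integration gives
   I(q) per region of interest; after exposure normalization and
   background subtraction, profiles are fitted over
   q ∈ [0.185, 1.723] nm⁻¹ (real-space features between 34.0 and 3.6 nm) by
   non-linear least squares to

   I(q) = K · q^α + B

   where the exponent α encodes the scatterer morphology (−4 for
   monodisperse spheres — Porod's law, −2 for platelets, −1 for rods) and,
   in the Porod limit, K is proportional to the squared electron-density
   contrast times the interface area. B absorbs density fluctuations and
   incoherent scattering.
4. **Three analysis levels** — window-wide (one average pattern per ROI
   class), per-cell, and single-pattern (one fit per scan position, with
   the background taken from the cell's surroundings *on the same scan
   row*, so slow drifts of the incoming beam intensity cancel).
5. **Population statistics** — cell-area quartiles ("small" = first
   quartile, "large" = fourth), two-sample Kolmogorov–Smirnov comparisons
   of K and α distributions, orientation/anisotropy maps via the second
   circular moment of the azimuthal intensity.
6. **Dose estimation** — D = (μ/ρ) · Φ E T / (Δy Δz), giving ~5 × 10⁶ Gy
   for the default beam parameters at 1.34 ms exposure.

The **simulator** generates elliptical cell phantoms with known per-region
(K, α, B), renders Poisson-noisy detector frames on top of a weakly
anisotropic instrument background, and provides analytic sphere / rod /
disc form factors, so every stage above is testable against ground truth.

## Worked example

```r
library(saxscan)

# a phantom field of 12 cells on a 150 x 150 raster (0.5 um, 1.34 ms)
grid    <- scan_grid(150, 150)
phantom <- make_phantom(12, grid, seed = 1,
                        params = phantom_params(cell_semiaxis_px = c(6, 10)))

# binned Eiger-like detector: 96 x 96 px covering the same q range
det  <- 96
mask <- matrix(FALSE, det, det)
ctr  <- c(det / 2 + 0.25, det / 2 - 0.25)
mask[abs(row(mask) - 0.5 - ctr[1]) <= 1.5 &
     abs(col(mask) - 0.5 - ctr[2]) <= 1.5] <- TRUE   # beamstop
geom  <- detector_geometry(13.0, 0.9, 75e-6 * 2070 / det, ctr, c(det, det), mask)
stack <- simulate_scan(phantom, geom, seed = 2)

cfg <- pipeline_config(levels = c("window", "cell"),
                       filter = list(min_nucleus_pixels = 10,
                                     bg_bounds = c(50, 1e7),
                                     ratio_bounds = NULL))
res <- run_pipeline(stack, cfg)
res$segmentation
#> segmentation: 12 cells (12 retained) on 150 x 150 scan positions
res$window_fits[, c("region", "K", "alpha", "B", "converged")]
#>      region          K     alpha           B converged
#> 1   nucleus 0.14545555 -3.891705 -0.05807432      TRUE
#> 2 cytoplasm 0.06832964 -3.894203 -0.02531464      TRUE
```

All 12 phantom cells are found and retained. The window-level fits recover
exponents near the generator's α ≈ −4.1 (the small upward shift is the
low-q bin-discretization bias of the reduced-size detector, discussed in
the vignette) and a nuclear K about twice the cytoplasmic K — the phantom
draws the nucleus prefactor 1.5–3× above the cytoplasm, mirroring the
denser nucleus seen in real dark-field images. The default-parameter dose:

```r
dose(dose_params())
#> [1] 4839580     # Gy, i.e. ~5e6 Gy per 1.34 ms scan position
```

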