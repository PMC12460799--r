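# smlm3d

Simulation and analysis of volumetric astigmatism-based single-molecule
localization microscopy (SMLM).

Deep-volume SMLM — imaging whole suspended cells rather than the first
few hundred nanometres above a coverslip — has to solve three coupled
problems at once: optical aberrations that grow with imaging depth and
destroy the astigmatic PSF used for 3D localization, mechanical drift
over hours-long acquisitions that must be corrected in all three axes in
real time, and the registration of many sequentially acquired focal
planes into one coherent nanoscale volume. `smlm3d` implements the full
computational chain of such an experiment as a tested R package, and
pairs it with a physical forward simulator so that every algorithm runs
against known ground truth. It is aimed at microscopy method developers
and analysts who want a reference implementation of these algorithms, or
a sandbox in which to study their failure modes.

## What is inside

* **Forward model** — scalar Fourier-optics PSFs with Zernike aberrations
  (unit-RMS normalization, amplitudes in nm RMS, phase via 2π/λ), a
  depth-proportional first-order spherical term (0.031 rad/µm), induced
  60 nm RMS astigmatism for 3D encoding, DNA-PAINT two-state blinking,
  Poisson-placed fiducial beads (4.5·10⁻³ µm⁻³), 3-axis drift, and an
  sCMOS camera (baseline 100 ADU, 0.46 e⁻/ADU, QE 0.82).
* **Sensorless adaptive optics** — the 3N search: each Zernike mode is
  probed at (+α, 0, −α) with α = 60 nm RMS, a parabola is fitted to the
  merit factor 1/max(intensity), and the correction jumps to its vertex;
  two to three passes over 7 (or 9) modes.
* **Localization** — à-trous B3-spline wavelet detection, anisotropic 2D
  Gaussian fitting, astigmatic calibration σx(z)/σy(z) with symmetry
  scoring, least-squares z assignment, and quality filters
  (χ² ∈ [0.6, 1], z ∈ [−0.5, 0.5] µm).
* **Real-time drift correction** — automatic per-plane fiducial selection
  (130 ≤ σx,y ≤ 300 nm, χ² > 0.65, outside the well), the drift metric
  dᵢ = √((xᵢ−x₀)² + (yᵢ−y₀)² + (zᵢ−z₀)²) with W-frame temporal averaging
  (W = 10), threshold-triggered stage corrections, and automatic
  multi-plane sequencing.
* **Reconstruction** — offline residual drift correction from the bead
  tracks, plane-to-plane registration from shared fiducials, assembly
  with (i−1)·Δz offsets, axial-homogeneity coefficient of variation,
  Gaussian rendering (10 nm pixels, 10/50 nm blur), and a Fourier filter
  that removes camera-pixel grid artifacts at f = 1/(Δ·z_sr).
* **Resolution** — Fourier ring correlation on even/odd localization
  splits with the 1/7 criterion, and fiducial-cluster FWHM via
  2.35 × the SD of principal-axis projections.
* **Cluster analysis** — exact 3D Voronoi local densities (C++ clipping
  kernel), density-threshold + 50 nm single-linkage clustering
  (≥ 10 localizations), per-cluster FWHM/volume descriptors, best-fit
  sphere of a cell membrane, spherical Voronoi surface-density maps, and
  property-vs-z homogeneity regressions.

## Worked example

Correct an aberrated system, then run the full demo pipeline (simulate →
AO → calibrate → acquire two planes with feedback drift correction →
localize → register → assemble → render → estimate resolution):

```r
library(smlm3d)
set.seed(1)
cfg <- optical_config()

# a system carrying 60 nm astigmatism and 25 nm coma
coeffs <- zernike_coeffs(astig_v = 60, coma_h = 25)
st <- run_3n(make_bead_system(coeffs, cfg, camera = NULL),
             zernike_modes(7), alpha_nm = 60, iterations = 2)
print(st)
#> 3N correction: 7 modes, 2 iterations (alpha = 60 nm RMS)
#>   merit 0.008613 -> 0.005783
#> Zernike coefficients (nm RMS):
#>   astig_v      -61.73
#>   coma_h       -24.66
#>   spherical     -0.00
#>   trefoil_h     -0.01

res <- run_pipeline(default_config(), out_dir = "demo_out")
nrow(res$volume)                 # localizations kept after filtering
#> [1] 731
round(100 * as.numeric(res$axial_cv))   # axial homogeneity (CV, %)
#> [1] 81
print(res$frc)
#> FRC resolution: 35.4 +/- 3.2 nm (mean +/- s.e.m., n = 3 planes)
```

The 3N loop finds a correction within a few nm RMS of the injected
aberration (the sign is opposite because the correction cancels it; the
merit factor — inverse of the PSF maximum — drops by a third). The demo
pipeline acquires 2 planes of 300 frames of a membrane-like shell of
docking sites, keeps 731 filtered 3D localizations, reports the axial
spread of localizations across the volume (coefficient of variation of
the per-slab counts), and estimates a ~35 nm lateral FRC resolution for
the reconstruction. `demo_out/` contains per-plane localization tables
(ThunderSTORM-compatible CSV), bead tracks, the assembled volume, the
rendered TIFF stack, the AO log and a JSON manifest.

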