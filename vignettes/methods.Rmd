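---
title: "Models and methods behind smlm3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smlm3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlm3d)
```

smlm3d is a simulation and analysis toolkit for volumetric single-molecule
localization microscopy (SMLM) with astigmatism-based 3D localization. It
covers the computational chain of an in-depth light-sheet SMLM experiment:
a physical forward model of the acquisition, sensorless adaptive-optics
(AO) correction, spot detection and astigmatic z assignment, real-time
fiducial-based drift correction with automatic multi-plane sequencing,
offline reconstruction of the full volume, resolution estimation, and
tessellation-based cluster analysis. Everything runs on synthetic data
produced by the package's own generators, so every algorithm can be tested
against a known ground truth.

## The optical forward model

PSFs are computed with a scalar Fourier-optics pupil model: the intensity
image of a point source is $|\mathcal{F}\{P(\rho)e^{i\phi(\rho)}\}|^2$,
where $P$ is the aperture indicator (NA 1.27 water immersion by default)
and $\phi$ the wavefront phase. Aberrations are expressed on unit-RMS
(Noll-normalized) Zernike polynomials; amplitudes are stored in nm RMS of
wavefront error and converted to phase through $2\pi/\lambda$. The
correctable mode set excludes piston, tip, tilt and defocus; the default
7-mode correction set is vertical/oblique astigmatism, vertical/horizontal
coma, first-order spherical, and vertical/horizontal trefoil, with
secondary astigmatism available as modes 8 and 9.

Two terms are added to the user-specified wavefront:

* **Depth-dependent spherical aberration.** Refractive-index mismatch
  makes the first-order spherical term grow linearly with imaging depth;
  the default slope is 0.031 rad RMS per micrometre of depth, converted to
  nm RMS via $\lambda/2\pi$.
* **Defocus** for the emitter's axial offset, through the angular-spectrum
  propagation phase $2\pi z\sqrt{(n/\lambda)^2 - k_r^2}$.

For 3D localization, 60 nm RMS of vertical astigmatism is induced: the
PSF's width anisotropy $\sigma_x-\sigma_y$ then encodes the axial position
monotonically over roughly $\pm 0.4\,\mu m$.

The bare scalar model produces a diffraction-limited PSF
($\sigma_0 \approx 95$ nm at $\lambda$ = 580 nm). Real instruments are
blurrier: the fiducial markers have a physical size of 0.1 µm, the camera
pixels integrate, and small uncorrected aberrations remain. These effects
are lumped into a single Gaussian blur of the intensity PSF
(`extra_blur_nm`, default 100 nm). The default was chosen so that
near-focus astigmatic PSF widths fall in the 130–300 nm band used by the
fiducial selection filter, which is where experimental calibration curves
live; setting it to 0 recovers the ideal diffraction model (the package's
own Airy-pattern test does exactly that). This choice matters: with the
bare model, no simulated bead would ever satisfy the width-based selection
filter, because the filter's constants describe real, blurred PSFs.

The camera model is an sCMOS with baseline 100 counts, conversion gain
0.46 e⁻/count and quantum efficiency 0.82 (defaults). Expected photons are
thinned by the QE, shot-noised, read noise (1.4 e⁻ RMS by default) is
added, and the result is offset, rounded and clipped to 16 bits. A
"signal of 3500 counts" therefore corresponds to
$3500 \times 0.46 / 0.82 \approx 1963$ expected photons per frame.

DNA-PAINT blinking is a two-state discrete-time Markov chain per docking
site: OFF→ON with probability `on_rate_per_frame` (proportional to imager
concentration) and ON→OFF with probability `1/mean_on_frames`. Partial
frames are ignored; the steady-state ON fraction is
`on_rate / (on_rate + 1/mean_on_frames)`. Defaults (`on_rate` 0.002,
3-frame mean bright time at the base constructor; the demo configuration
uses 0.01 to populate its small scene) emulate the slow binding kinetics
of conventional imager strands at sub-nanomolar concentrations.

Fiducial beads are placed as a Poisson process of intensity
4.5·10⁻³ µm⁻³ in the polymer volume outside the sample well. Drift is
applied to the emitters in the sample frame (opposite sign to stage
corrections); linear rates and random-walk components can be combined.

## Sensorless AO: the 3N search

The merit factor is the inverse of the maximum pixel intensity of a point
source, computed after subtracting the camera baseline so that it reflects
signal rather than offset (a raw-maximum variant is available through the
`baseline` argument). Each mode is probed at $(+\alpha, 0, -\alpha)$
(default $\alpha = 60$ nm RMS) around the current correction, a parabola
is fitted through the three merits, and the correction jumps to the vertex
clamped to $[-\alpha, \alpha]$. Non-convex triplets (possible on noisy
merits) fall back to the best sampled point with a warning, which keeps a
practical loop robust. Two to three passes over the 7-mode set reduce
single-mode injections of up to 60 nm RMS to below 5 nm residual; the test
suite verifies this against an exhaustive 1-D merit grid. Noisy systems
can average several frames per merit evaluation (`n_average`).

## Localization

Spot detection uses the à-trous B3-spline wavelet transform (3 levels,
detection on the second detail plane) with a threshold of 1.5 times a
MAD-based noise scale, connected-component labelling, and non-maximum
suppression so that the side lobes of bright PSFs do not spawn duplicate
candidates. Candidates are fitted with an anisotropic 2D Gaussian
(Levenberg–Marquardt). The goodness of fit is reported as the coefficient
of determination $1 - SS_{res}/SS_{tot}$ clamped to $[0, 1]$ — a
convention chosen because the quality filters expect a statistic in
$[0, 1]$ with 1 meaning a perfect fit; it is *not* the classical
chi-square, and no equivalence with any specific tracking software's
normalization is claimed.

The astigmatism calibration fits a bead z-stack (±0.8 µm or more, 25 nm
steps), builds spline interpolants $\sigma_x(z), \sigma_y(z)$, defines the
focus as the width crossing, enforces strict monotonicity of
$\sigma_x-\sigma_y$ over ±0.4 µm (otherwise the calibration is rejected),
and scores symmetry as the normalized L2 distance between $\sigma_x(z)$
and $\sigma_y(-z)$; spherical aberration degrades that score, which is the
practical signal to re-run AO. z assignment minimizes
$(\sigma_x-\sigma_x^{cal}(z))^2 + (\sigma_y-\sigma_y^{cal}(z))^2$ over a
1 nm grid restricted to ±0.5 µm — least squares in $\sigma$ space rather
than inverting $\sigma_x-\sigma_y$, for robustness to correlated width
errors. Minima on the range boundary are flagged out of range. Quality
filters keep localizations with chi2 in [0.6, 1] and z in [−0.5, 0.5] µm,
bounds inclusive.

## Real-time drift correction and plane sequencing

The reference fiducial of each plane must have both widths in
[130, 300] nm (axially close to the plane) and chi2 > 0.65, and must lie
outside the well; among candidates, the bead with minimal
$|\sigma_x-\sigma_y|$ wins, ties broken by chi2. The drift metric is the
3D Euclidean distance between the current position estimate (sliding mean
of the last ≤ W localizations, W = 10 by default) and the reference; a
correction of $-(\hat{p}-p_0)$ is issued whenever it exceeds the threshold
(default 0). Two implementation details matter for stability and accuracy:

* When a correction is applied, the stored measurement window is
  translated by it. Without this re-referencing the averaged feedback acts
  on stale coordinates and the loop diverges for W > 1.
* The reference is re-measured as the average of W fresh frames after
  selection. The selected bead won the minimal-anisotropy contest partly
  by noise, so its fitted z in the selection frame is biased toward focus
  (a winner's curse); a fresh average removes the bias, which would
  otherwise become a constant axial stage offset.

The loop tolerates lost beads for up to 50 consecutive frames before
aborting a plane. The stage model is an ideal actuator with optional
one-frame latency and Gaussian positioning noise (2 nm RMS default in the
localization-level loop). For drift ≤ 1 nm/frame and ≤ 10 nm localization
noise the closed loop is stable over 10⁴ frames, with residual RMS near
the analytic floor $2\sigma/\sqrt{W}$ plus the tracking lag of about half
an averaging window times the drift rate.

Multi-plane acquisition advances imaging and excitation planes together by
the plane step after each plane; planes without an eligible bead are
skipped and logged; sequencing aborts only if no plane has a bead. Optical
sectioning is emulated with a hard axial excitation window (±0.6 µm
default) around the current plane — only its extent, not the light-sheet
thickness profile, is modelled. Without it, molecules a micrometre out of
focus would spread blurred tails into the tracking window and bias the
bead's axial fit, a situation the real light-sheet excitation never
creates.

## Reconstruction

Offline, the residual drift (what the finite feedback precision left) is
removed by subtracting the smoothed bead trajectory (moving average of
window W, centred on its own mean) interpolated at each localization's
frame. Adjacent planes are registered by matching fiducials laterally
(nearest neighbour within 500 nm, using per-plane mean bead positions) and
translating plane $i{+}1$ by the mean shift; at least two shared beads are
required. Assembly adds $(i-1)\Delta z$ to each plane's localizations and
renumbers ids sequentially. Axial homogeneity is summarized by the
coefficient of variation (population SD over mean) of localization counts
in z bins of the rendering plane spacing.

Rendering deposits one unit-integral separable 3D Gaussian per
localization (σ = 10 nm lateral, 50 nm axial) on a 10 nm × 10 nm ×
200 nm grid, so integrated intensity equals the localization count. The
grid-artifact filter zeroes whole DFT frequency lines at the non-zero
integer multiples of $N/z_{sr}$ (the camera-pixel frequency $1/\Delta$ and
harmonics) along both axes, preserving DC, and returns the real part of
the inverse transform. Zeroing single lines rather than notch
neighbourhoods keeps the filter maximally transparent: an image with no
energy at the targeted bins passes through to within numerical precision.

## Resolution estimation

FRC: localizations are split by the parity of their ids (a balanced,
unbiased split), both halves rendered identically, and the ring
correlation computed per lateral plane over single-bin rings. The curve is
smoothed with a 3-bin moving average; the resolution is the inverse of the
first frequency where the smoothed curve drops below 1/7, linearly
interpolated. A curve must hold above the criterion for at least three
consecutive rings to count as resolved — an isolated spike in a sparse
low-frequency ring is noise, not structure. Curves that never drop below
the criterion report the Nyquist floor of two super-resolution pixels;
curves never above it are excluded as unresolved. On simulated filaments
with localization noise σ and 10 nm rendering blur, the measured FRC
resolution tracks $2.35\sqrt{\sigma^2 + blur^2}$ within 30 %.

Bead-cluster FWHM: localizations of each physical bead are grouped
(single linkage at 150 nm, then a second-level density split for merged
beads), the principal axes of each cloud of ≥ 30 localizations are fitted,
and the FWHM along each axis is 2.35 times the SD of the projections. The
two short axes are lateral and the long axis axial, because astigmatic
localization is least precise along z; beads whose long axis tilts more
than 30° from z are flagged rather than silently accepted.

## Cluster analysis

The local density of each localization is computed from the exact 3D
Voronoi tessellation, clipped to a padded bounding box (the half-space
clipping kernel is implemented in C++; cells are proven complete by the
rule that a point farther than twice the maximal vertex distance cannot
cut). The first-rank density is
$(1 + |N_1|)/(V_i + \sum_{j \in N_1} V_j)$ over the point and its Voronoi
neighbours. Cells that touch the bounding box are excluded from pooled
sums and inherit the mean density of their interior neighbours, which
removes the truncation artifact of hull cells; with this rule the mean
density of a uniform cloud matches $n/V$ within a few percent and interior
lattice cells are exact to machine precision.

Clusters are localizations whose density exceeds the cloud's average
density — defined as the localization count divided by the total
tessellated volume, not the mean of the heavy-tailed per-point densities,
which a few dense clusters would dominate — linked by single linkage with
a 50 nm cutting distance; components under 10 localizations are dropped.
Per cluster, principal-axis FWHMs give $d_z$ (long axis) and $d_r$ (mean
of the two short axes — the choice for how to reduce two lateral axes to
one number), and the volume is the FWHM ellipsoid
$V = \frac{4}{3}\pi (d_r/2)^2 (d_z/2)$.

For membrane receptors, the sphere best fitting the cluster centroids is
found by a linear algebraic fit refined by Gauss–Newton on the geometric
residuals; centroids are projected radially onto it, the spherical Voronoi
diagram (computed via the convex hull of the projections, cell vertices =
facet circumcenters, areas by spherical excess) partitions the surface,
and the local surface cluster density is one over the cell area. Cell
areas sum to $4\pi R^2$ exactly. Ordinary least squares of each cluster
property against centroid z quantifies axial homogeneity; on synthetic
homogeneous maps all $R^2$ stay below the 0.03 criterion.

## What the synthetic data does and does not capture

The generators reproduce: Zernike-aberrated astigmatic PSFs with
depth-proportional spherical error, two-state blinking, Poisson-placed
photostable fiducials, three-axis drift, sCMOS statistics, flat (optionally
linearly graded) background, and — for the receptor-map analysis — distinct
nanoclusters (centroids kept 300 nm apart, a hard-core process, since
physical nanoclusters are distinct objects) over a volumetric nonspecific
background of about 30 localizations/µm³. That background is not
decoration: without it, cluster-rim Voronoi cells extend into vacuum and
whole cluster shells fall below the average-density threshold, a regime
real DNA-PAINT data never reaches. Not modelled: vectorial/high-NA PSF
effects, supercritical-angle fluorescence, sample-induced (non-depth)
aberrations, the light-sheet thickness profile, structured backgrounds,
and high-density overlapping emitters (the localizer assumes the sparse
regime). Passing tests therefore demonstrate the correctness of the
algorithms under these stated conditions, not the performance of any
instrument on real specimens.

## Numerical choices and problem sizes

Tolerances and tie-breaks that matter: parabola vertices are clamped to
±α and non-convex triplets fall back to the best sample; calibration
rejects non-monotone width differences outright; z lookups are on a 1 nm
grid; Voronoi clipping uses a relative tolerance of 1e-9 with exact
early stopping; registration needs ≥ 2 shared beads; coincident sphere
projections are jittered by 1 nm with a warning. Degenerate inputs
(coplanar point sets, all-zero images, empty frames) raise errors rather
than returning silently wrong numbers.

The shipped demonstration configuration acquires 2 planes of 300 frames on
a 48-pixel field with 150 docking sites and 4 beads, which completes the
full pipeline in well under a minute; the acceptance analyses use 1000
feedback frames, 100 registration repeats, 25 axial accuracy probes and a
500-cluster receptor map of 20 000 cluster localizations plus background.
These sizes were chosen so the whole verification suite runs comfortably
on a single CPU while keeping every statistical check far from its
tolerance floor. Scaling any of them up is a matter of configuration, not
code.

## Known limitations

The chi-square surrogate is a convention, not an equivalence with any
published fitting stack. The FWHM recovered for receptor clusters is
biased a few percent low because density thresholding and finite linkage
truncate cluster rims — an intrinsic property of tessellation clustering,
visible in the acceptance numbers ($d_z$ about 7 % below $2.35\sigma_z$).
The feedback reference convention keeps corrections absolute against the
initial reference; re-zeroing after each correction would accumulate
reference noise instead. Whether the temporal averaging window should
slide or tumble is unspecified in common practice; it slides here.
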