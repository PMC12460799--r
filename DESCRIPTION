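Package: smlm3d
Title: Simulation and Analysis of Volumetric Astigmatism-Based
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward simulator and analysis toolkit for in-depth volumetric
    single-molecule localization microscopy (SMLM) with astigmatism-based 3D
    localization. Simulates Zernike-aberrated point spread functions through a
    scalar Fourier-optics pupil model with a depth-proportional spherical
    term, DNA-PAINT two-state blinking, embedded fiducial beads, three-axis
    mechanical drift and an sCMOS camera model. Provides sensorless modal
    adaptive-optics correction (the 3N parabolic search on an image-quality
    merit factor), wavelet-based spot detection with anisotropic Gaussian
    fitting and astigmatic z assignment, real-time fiducial feedback-loop
    drift correction with automatic multi-plane sequencing, offline residual
    drift correction, plane registration and volume assembly, Gaussian
    volume rendering with Fourier grid-artifact removal, resolution
    estimation by Fourier ring correlation and fiducial-cluster FWHM, and
    Voronoi-density cluster analysis of 3D point clouds with best-fit-sphere
    surface mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    igraph,
    RANN,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
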