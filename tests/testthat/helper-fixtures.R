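# Shared fixtures: a compact optical model and one astigmatism calibration
# reused across test files (noiseless, so it is deterministic).

fix_cfg <- optical_config()
fix_cfg0 <- optical_config(extra_blur_nm = 0)   # bare diffraction model
fix_cam <- camera_model(read_noise_e = 0)
fix_astig <- zernike_coeffs(astig_v = 60)
fix_photons_3500adu <- 3500 * fix_cam$electrons_per_adu /
  fix_cam$quantum_efficiency

fix_calibration <- local({
  zs <- seq(-0.8, 0.8, by = 0.025)
  stk <- simulate_bead_zstack(zs, fix_astig, fix_cam, photons = 20000,
                              cfg = fix_cfg, seed = 1, shot_noise = FALSE)
  calibrate_astigmatism(stk, zs, fix_cam, fix_cfg)
})

# moment-based marginal widths of a PSF image (pixels)
moment_sigmas <- function(p) {
  n <- nrow(p); c0 <- (n + 1) / 2
  xs <- seq_len(n) - c0
  mx <- colSums(p) / sum(p); my <- rowSums(p) / sum(p)
  c(sx = sqrt(sum(mx * xs^2) - sum(mx * xs)^2),
    sy = sqrt(sum(my * xs^2) - sum(my * xs)^2))
}
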