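# Analytic profiles ---------------------------------------------------------

test_that("donut profile has an exact zero, unit integral and the expected peak", {
  expect_identical(eval_donut2d(c(0, 0), sigma = 150), 0)
  # integral over the plane equals the amplitude
  igr <- integrate(function(r) eval_donut2d(cbind(r, 0), 150, amplitude = 2) * 2 * pi * r,
                   0, Inf)
  expect_equal(igr$value, 2, tolerance = 1e-6)
  # radial maximum at sqrt(2) sigma (stationary point of r^2 exp(-r^2/2s^2))
  rr <- seq(150, 300, by = 0.01)
  vv <- eval_donut2d(cbind(rr, 0), 150)
  expect_equal(rr[which.max(vv)], sqrt(2) * 150, tolerance = 1e-3)
  # point symmetry
  set.seed(1)
  x <- matrix(rnorm(20, sd = 100), ncol = 2)
  expect_equal(eval_donut2d(x, 150), eval_donut2d(-x, 150))
})

test_that("gaussian profile is monotone with the right scale", {
  s <- 120
  expect_equal(eval_gauss2d(c(0, 0), s, amplitude = 3), 3)
  expect_equal(eval_gauss2d(c(s, 0), s) / eval_gauss2d(c(0, 0), s), exp(-0.5))
  r <- seq(0, 500, by = 10)
  expect_true(all(diff(eval_gauss2d(cbind(r, 0), s)) < 0))
})

test_that("quadratic model approximates the donut near the zero", {
  s <- 150
  expect_identical(eval_quadratic(c(0, 0), s), 0)
  # second-degree homogeneity
  x <- c(30, -20)
  expect_equal(eval_quadratic(2 * x, s), 4 * eval_quadratic(x, s))
  # agreement with the exact donut: 0.2% at |x| = 0.05 sigma, 1% to 0.3 sigma
  expect_equal(eval_quadratic(c(0.05 * s, 0), s) / eval_donut2d(c(0.05 * s, 0), s),
               1, tolerance = 2e-3)
  for (f in c(0.1, 0.2, 0.3)) {
    ratio <- eval_quadratic(c(f * s, 0), s) / eval_donut2d(c(f * s, 0), s)
    expect_lt(abs(ratio - 1), 0.05)
  }
})

test_that("non-positive sigma is rejected", {
  expect_error(eval_donut2d(c(1, 1), sigma = 0), "sigma")
  expect_error(psf_gauss2d(sigma = -1), "sigma")
})

# Vectorial model ------------------------------------------------------------

test_that("vortex mask yields a rotationally symmetric donut with a deep null", {
  p <- get_vec_psf("vortex20", phase_mask = "vortex", grid_pitch = 20, pupil_n = 64)
  expect_lte(psf_eval(p, c(0, 0, 0)) / max(p$excitation), 1e-4)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- psf_eval(p, cbind(120 * cos(th), 120 * sin(th), 0))
  expect_lt((max(ring) - min(ring)) / mean(ring), 0.02)
})

test_that("flat mask focuses on the axis; aberrations reduce the peak", {
  p <- get_vec_psf("flat20", phase_mask = "flat", grid_pitch = 20, pupil_n = 64)
  expect_equal(as.numeric(psf_eval(p, c(0, 0, 0))), max(p$excitation),
               tolerance = 1e-9)
  p0 <- psf_vectorial(optics_config(phase_mask = "flat", grid_pitch = 25, pupil_n = 48))
  pa <- psf_vectorial(optics_config(phase_mask = "flat", grid_pitch = 25, pupil_n = 48,
                                    zernike_terms = list(c(3, 1, 0.3))))  # coma
  # Strehl ratio below 1: the recorded peak intensity A drops
  expect_lt(pa$A, 0.95 * p0$A)
})

test_that("half-moon mask carries a nodal line, exact in the scalar limit", {
  # low NA: depolarization negligible, the pi-step antisymmetry null is strict
  plo <- psf_vectorial(optics_config(numerical_aperture = 0.5, phase_mask = "halfmoon_x",
                                     grid_pitch = 30, pupil_n = 64,
                                     polarization = c(0, 1)))
  nodal <- psf_eval(plo, cbind(0, seq(-300, 300, 20), 0))
  expect_lte(max(nodal) / max(plo$excitation), 1e-4)
  # high NA: the (cos(theta) - 1) cross term limits the contrast to ~1e-2
  phi <- get_vec_psf("halfmoon20", phase_mask = "halfmoon_x", grid_pitch = 20,
                     pupil_n = 64, polarization = c(0, 1))
  nodal_hi <- psf_eval(phi, cbind(0, seq(-300, 300, 20), 0))
  expect_lte(max(nodal_hi) / max(phi$excitation), 2e-2)
  # the two lobes straddle the node along x
  expect_gt(psf_eval(phi, c(150, 0, 0)), 0.2 * max(phi$excitation))
})

test_that("grid refinement leaves probed intensity ratios unchanged within 1%", {
  p20 <- get_vec_psf("vortex20", phase_mask = "vortex", grid_pitch = 20, pupil_n = 64)
  p10 <- psf_vectorial(optics_config(phase_mask = "vortex", grid_pitch = 10, pupil_n = 64))
  r20 <- psf_eval(p20, c(100, 0, 0)) / psf_eval(p20, c(50, 0, 0))
  r10 <- psf_eval(p10, c(100, 0, 0)) / psf_eval(p10, c(50, 0, 0))
  expect_equal(r20, r10, tolerance = 0.01)
})

test_that("undersampled grids and bad configurations are rejected", {
  expect_error(psf_vectorial(optics_config(grid_pitch = 200)), "sampling bound")
  expect_error(psf_vectorial(optics_config(grid_extent = 500)), "1000 nm")
  expect_error(optics_config(numerical_aperture = 1.6), "immersion")
  expect_error(optics_config(pinhole_diameter = 0), "pinhole")
})

# Detection ------------------------------------------------------------------

test_that("pinhole detection reduces efficiency when misaligned, with negligible bias", {
  oc_al <- optics_config(phase_mask = "vortex", grid_pitch = 25, pupil_n = 48,
                         pinhole_diameter = 1)
  p_al <- psf_vectorial(oc_al)
  oc_sh <- optics_config(phase_mask = "vortex", grid_pitch = 25, pupil_n = 48,
                         pinhole_diameter = 1, pinhole_shift = c(150, 0))
  p_sh <- psf_vectorial(oc_sh)
  det_al <- p_al$detection[, , 1]
  det_sh <- p_sh$detection[, , 1]
  i0 <- which(p_al$grid$x == 0)
  expect_lt(det_sh[i0, i0], det_al[i0, i0])        # efficiency drops at center
  expect_lte(max(det_al), 1)
  # localization bias of a centered emitter changes < 0.5 nm
  pat <- pat_orbit(L = 75, K_o = 4)
  bias_of <- function(psf) {
    p <- model_p(pat, psf, c(0, 0, 0))
    est_iterative_lsq(p, pat$offsets, list(model = "donut", L = 75, sigma = 150))$x_est
  }
  expect_lt(sqrt(sum((bias_of(p_sh) - bias_of(p_al))[1:2]^2)), 0.5)
})

test_that("gaussian detection attachment modulates the effective field", {
  psf <- psf_attach_detection(psf_donut2d(150), sigma_det = 200,
                              pinhole_shift = c(0, 0), efficiency = 0.8)
  expect_equal(minfluxsim:::.psf_det_eval(psf, matrix(c(0, 0, 0), 1)), 0.8)
  far <- minfluxsim:::.psf_det_eval(psf, matrix(c(400, 0, 0), 1))
  expect_lt(far, 0.2)
})

# Bead convolution -----------------------------------------------------------

test_that("bead convolution lifts the donut zero and conserves the integral", {
  p <- get_vec_psf("vortex20", phase_mask = "vortex", grid_pitch = 20, pupil_n = 64)
  expect_identical(psf_convolve_bead(p, 0)$excitation, p$excitation)
  pb <- psf_convolve_bead(p, 100)
  expect_gt(psf_eval(pb, c(0, 0, 0)), 0)
  expect_equal(sum(pb$excitation), sum(p$excitation), tolerance = 1e-3)
  expect_warning(psf_convolve_bead(p, 5), "grid pitch")
  expect_error(psf_convolve_bead(p, 1e5), "extent")
})

# Calibrated stacks ----------------------------------------------------------

test_that("calibrated stacks load, interpolate linearly and vanish outside", {
  tmp <- tempfile(fileext = ".tif")
  nx <- 21
  ramp <- outer(seq(0, 1, length.out = nx), rep(1, nx))   # linear in row index
  pages <- list(ramp * 0.5, ramp, ramp * 0.5)
  tiff::writeTIFF(pages, tmp, bits.per.sample = 32L, reduce = FALSE)
  psf <- psf_load_calibrated(tmp, pixelsize_xy_nm = 10, pixelsize_z_nm = 100)
  # node reproduction: row index maps to y (page rows), center voxel (11,11,2)
  expect_equal(as.numeric(psf_eval(psf, c(0, 0, 0))), ramp[11, 11], tolerance = 1e-6)
  expect_equal(as.numeric(psf_eval(psf, c(0, 10, 0))), ramp[12, 11], tolerance = 1e-6)
  # midway on a linear ramp -> arithmetic mean of neighbors
  expect_equal(as.numeric(psf_eval(psf, c(0, 5, 0))),
               (ramp[11, 11] + ramp[12, 11]) / 2, tolerance = 1e-6)
  # outside the support: 0 with flag
  v <- psf_eval(psf, c(0, 1e4, 0))
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "out_of_range"))
  # missing spacing metadata
  expect_error(psf_load_calibrated(tmp), "spacing")
})
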