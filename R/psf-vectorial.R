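#' Optical configuration for the vectorial PSF model
#'
#' Collects the parameters of the focusing model: objective, wavelengths,
#' refractive indices, pupil phase mask, aberrations and detection pinhole.
#' Defaults describe a typical oil-immersion MINFLUX setup (1.4 NA, 640 nm
#' excitation). The pupil-plane mask shift is given in mm at the
#' pupil-conjugate plane and converted to a pupil fraction via
#' `pupil_radius_mm`.
#'
#' @param numerical_aperture objective NA (must be `< refractive_index_immersion`).
#' @param wavelength excitation wavelength (nm).
#' @param wavelength_det detection wavelength (nm).
#' @param refractive_index_immersion,refractive_index_sample refractive indices.
#' @param phase_mask one of `"flat"`, `"vortex"`, `"tophat"`, `"halfmoon_x"`,
#'   `"halfmoon_y"`.
#' @param mask_shift 2-vector, lateral shift of the phase mask at the
#'   pupil-conjugate plane (mm).
#' @param pupil_radius_mm radius of the pupil at that plane (mm).
#' @param zernike_terms list of `c(n, m, amplitude_waves)` Zernike terms.
#' @param pinhole_diameter pinhole diameter in Airy units (`NA` for none).
#' @param pinhole_shift 2-vector pinhole misalignment in sample space (nm).
#' @param bead_diameter diameter of a calibration bead to convolve (nm).
#' @param grid_pitch sampling pitch of the computed field (nm).
#' @param grid_extent lateral half-extent of the computed field (nm).
#' @param z_extent axial half-extent (nm); `0` computes a single focal plane.
#' @param z_pitch axial plane spacing (nm).
#' @param polarization input Jones vector; default circular, matched in
#'   handedness to the vortex mask so the focal zero is complete.
#' @param pupil_n pupil sampling (points per axis).
#' @return an `optics_config` list.
#' @export
optics_config <- function(numerical_aperture = 1.4,
                          wavelength = 640,
                          wavelength_det = 680,
                          refractive_index_immersion = 1.518,
                          refractive_index_sample = 1.33,
                          phase_mask = c("flat", "vortex", "tophat",
                                         "halfmoon_x", "halfmoon_y"),
                          mask_shift = c(0, 0),
                          pupil_radius_mm = 2.5,
                          zernike_terms = list(),
                          pinhole_diameter = NA,
                          pinhole_shift = c(0, 0),
                          bead_diameter = 0,
                          grid_pitch = 10,
                          grid_extent = 1000,
                          z_extent = 0,
                          z_pitch = 100,
                          polarization = c(1, 1i) / sqrt(2),
                          pupil_n = 64) {
  phase_mask <- match.arg(phase_mask)
  if (numerical_aperture >= refractive_index_immersion)
    stop("numerical_aperture must be smaller than the immersion index", call. = FALSE)
  if (!is.na(pinhole_diameter) && pinhole_diameter <= 0)
    stop("pinhole_diameter must be > 0 (or NA for no pinhole)", call. = FALSE)
  cfg <- list(numerical_aperture = numerical_aperture,
              wavelength = wavelength, wavelength_det = wavelength_det,
              refractive_index_immersion = refractive_index_immersion,
              refractive_index_sample = refractive_index_sample,
              phase_mask = phase_mask, mask_shift = mask_shift,
              pupil_radius_mm = pupil_radius_mm,
              zernike_terms = zernike_terms,
              pinhole_diameter = pinhole_diameter,
              pinhole_shift = pinhole_shift,
              bead_diameter = bead_diameter,
              grid_pitch = grid_pitch, grid_extent = grid_extent,
              z_extent = z_extent, z_pitch = z_pitch,
              polarization = polarization, pupil_n = pupil_n)
  class(cfg) <- "optics_config"
  cfg
}

# Zernike radial polynomial R_n^m(rho), |m| <= n, n - |m| even.
.zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

# Phase (radians) of the configured mask at shifted pupil coordinates.
.mask_phase <- function(cfg, px, py) {
  # px, py in pupil-fraction units; mask shifted by mask_shift (mm)
  sx <- cfg$mask_shift[1L] / cfg$pupil_radius_mm
  sy <- cfg$mask_shift[2L] / cfg$pupil_radius_mm
  mx <- px - sx
  my <- py - sy
  switch(cfg$phase_mask,
    flat = 0 * px,
    vortex = atan2(my, mx),
    tophat = {
      # pi phase disk sized for equal inner/outer pupil energy (r = 1/sqrt(2))
      ifelse(sqrt(mx^2 + my^2) <= 1 / sqrt(2), pi, 0)
    },
    halfmoon_x = ifelse(mx >= 0, pi, 0),
    halfmoon_y = ifelse(my >= 0, pi, 0))
}

#' Vectorial focal field via the Debye diffraction integral
#'
#' Computes the focused excitation intensity of a high-NA objective by
#' evaluating the vectorial Debye integral as a discrete sum over a
#' uniformly sampled pupil (a semi-analytic DFT, exact on the requested
#' sample grid). The pupil function carries the configured phase mask,
#' Zernike aberrations and mask shift; an aplanatic (sqrt(cos theta))
#' apodization is used. The intensity is the sum of the squared moduli of
#' the three focal field components.
#'
#' The sample grid must satisfy `grid_pitch <= wavelength / (4 NA)` and
#' extend at least +-1000 nm laterally.
#'
#' @param optics an [optics_config()].
#' @return a `psf` object of kind `"vectorial"` with fields `grid`
#'   (axis vectors, nm), `excitation` (3D array, max normalized to 1) and
#'   the recorded normalization constant `A`.
#' @export
psf_vectorial <- function(optics = optics_config()) {
  cfg <- optics
  nyq <- cfg$wavelength / (4 * cfg$numerical_aperture)
  if (cfg$grid_pitch > nyq)
    stop(sprintf("grid_pitch (%g nm) exceeds the sampling bound wavelength/(4 NA) = %.2f nm",
                 cfg$grid_pitch, nyq), call. = FALSE)
  if (cfg$grid_extent < 1000)
    stop("grid_extent must cover at least +-1000 nm laterally", call. = FALSE)
  xs <- seq(-cfg$grid_extent, cfg$grid_extent, by = cfg$grid_pitch)
  zs <- if (cfg$z_extent > 0) seq(-cfg$z_extent, cfg$z_extent, by = cfg$z_pitch) else 0
  exc <- .debye_field(cfg, xs, xs, zs, cfg$wavelength, cfg$phase_mask,
                      list(cfg$polarization))
  A <- max(exc)
  exc <- exc / A
  psf <- structure(list(kind = "vectorial", grid = list(x = xs, y = xs, z = zs),
                        excitation = exc, A = A, optics = cfg,
                        zero_offset = c(0, 0, 0), detection = NULL),
                   class = c("psf_sampled", "psf"))
  if (cfg$bead_diameter > 0) psf <- psf_convolve_bead(psf, cfg$bead_diameter)
  if (!is.na(cfg$pinhole_diameter)) psf <- psf_apply_detection(psf, cfg)
  psf
}

# Intensity |E|^2 of the focal field on the grid; incoherent sum over the
# input polarizations in `pols` (list of Jones vectors).
.debye_field <- function(cfg, xs, ys, zs, wavelength, phase_mask, pols) {
  n_imm <- cfg$refractive_index_immersion
  k0 <- 2 * pi / wavelength
  smax <- cfg$numerical_aperture / n_imm
  np <- cfg$pupil_n
  u <- seq(-1, 1, length.out = np)            # pupil fraction
  PX <- matrix(u, np, np)
  PY <- matrix(u, np, np, byrow = TRUE)
  rho <- sqrt(PX^2 + PY^2)
  inside <- rho <= 1
  sinth <- pmin(rho * smax, smax)
  costh <- sqrt(pmax(1 - sinth^2, 0))
  phi <- atan2(PY, PX)
  # pupil phase: mask + Zernike aberrations (waves -> radians)
  cfg2 <- cfg; cfg2$phase_mask <- phase_mask
  ph <- .mask_phase(cfg2, PX, PY)
  if (length(cfg$zernike_terms)) {
    for (zt in cfg$zernike_terms) {
      n <- zt[1L]; m <- zt[2L]; amp <- zt[3L]
      ang <- if (m >= 0) cos(m * phi) else sin(-m * phi)
      ph <- ph + 2 * pi * amp * .zernike_radial(n, m, pmin(rho, 1)) * ang
    }
  }
  apod <- ifelse(inside, 1 / sqrt(pmax(costh, 1e-6)), 0)
  base <- apod * exp(1i * ph)
  base[!inside] <- 0
  # vectorial polarization conversion factors
  c2 <- cos(phi)^2; s2 <- sin(phi)^2; cs <- cos(phi) * sin(phi)
  fac <- list(
    xx = costh * c2 + s2,  xy = (costh - 1) * cs,
    yx = (costh - 1) * cs, yy = costh * s2 + c2,
    zx = -sinth * cos(phi), zy = -sinth * sin(phi))
  kt <- k0 * n_imm * smax        # max transverse wavenumber
  kxv <- kt * u
  Ax <- exp(1i * outer(xs, kxv)) # nx x np
  Ay <- exp(1i * outer(ys, kxv))
  kz <- k0 * n_imm * costh
  out <- array(0, c(length(xs), length(ys), length(zs)))
  for (iz in seq_along(zs)) {
    defoc <- exp(1i * kz * zs[iz])
    for (pol in pols) {
      ex_in <- pol[1L]; ey_in <- pol[2L]
      Px <- base * defoc * (ex_in * fac$xx + ey_in * fac$xy)
      Py <- base * defoc * (ex_in * fac$yx + ey_in * fac$yy)
      Pz <- base * defoc * (ex_in * fac$zx + ey_in * fac$zy)
      Ex <- Ax %*% Px %*% t(Ay)
      Ey <- Ax %*% Py %*% t(Ay)
      Ez <- Ax %*% Pz %*% t(Ay)
      out[, , iz] <- out[, , iz] + Mod(Ex)^2 + Mod(Ey)^2 + Mod(Ez)^2
    }
  }
  out / length(pols)
}

#' Pinhole detection for a sampled PSF
#'
#' Builds the detection efficiency field: a flat-phase vectorial PSF at the
#' detection wavelength (unpolarized: incoherent average over two input
#' polarizations), convolved laterally with the pinhole disk and shifted by
#' the configured pinhole misalignment. The detection field is normalized
#' to a maximum of 1 for an aligned pinhole; it stays referenced to the
#' pattern center during measurements because the fast scanner is not
#' descanned.
#'
#' @param psf a sampled `psf` (from [psf_vectorial()] or
#'   [psf_load_calibrated()]).
#' @param optics an [optics_config()] with `pinhole_diameter` set (Airy
#'   units); `NA` leaves the PSF unchanged with a notice.
#' @param fast_gauss if `TRUE`, substitute a Gaussian of matched FWHM for
#'   the vectorial detection field (documented fast mode).
#' @return the PSF with a `$detection` array over the same grid.
#' @export
psf_apply_detection <- function(psf, optics, fast_gauss = FALSE) {
  stopifnot(inherits(psf, "psf_sampled"))
  cfg <- optics
  if (is.na(cfg$pinhole_diameter)) {
    message("no pinhole configured; excitation returned unchanged")
    return(psf)
  }
  xs <- psf$grid$x; ys <- psf$grid$y; zs <- psf$grid$z
  if (fast_gauss) {
    fwhm <- 0.514 * cfg$wavelength_det / cfg$numerical_aperture
    sg <- fwhm / (2 * sqrt(2 * log(2)))
    det3 <- array(0, c(length(xs), length(ys), length(zs)))
    g2 <- outer(exp(-xs^2 / (2 * sg^2)), exp(-ys^2 / (2 * sg^2)))
    for (iz in seq_along(zs)) det3[, , iz] <- g2
  } else {
    det3 <- .debye_field(cfg, xs, ys, zs, cfg$wavelength_det, "flat",
                         list(c(1, 0), c(0, 1)))
  }
  # pinhole disk in sample space; 1 AU = 1.22 lambda_det / NA
  au_nm <- 1.22 * cfg$wavelength_det / cfg$numerical_aperture
  rad <- cfg$pinhole_diameter * au_nm / 2
  pitch <- xs[2L] - xs[1L]
  nk <- max(1L, ceiling((rad + max(abs(cfg$pinhole_shift))) / pitch))
  kx <- seq(-nk, nk) * pitch
  K <- outer(kx - cfg$pinhole_shift[1L], kx - cfg$pinhole_shift[2L],
             function(a, b) as.numeric(a^2 + b^2 <= rad^2))
  if (sum(K) == 0) K[nk + 1L, nk + 1L] <- 1   # sub-pixel pinhole -> delta
  K <- K / sum(K)
  for (iz in seq_along(zs)) det3[, , iz] <- .conv2_same(det3[, , iz], K)
  det3 <- pmax(det3, 0)
  # normalize against the aligned-pinhole maximum so misalignment shows up
  # as reduced efficiency, not as a rescaled field
  if (any(cfg$pinhole_shift != 0)) {
    Ka <- outer(kx, kx, function(a, b) as.numeric(a^2 + b^2 <= rad^2))
    Ka <- Ka / sum(Ka)
    ref <- .debye_field(cfg, xs, ys, 0, cfg$wavelength_det, "flat",
                        list(c(1, 0), c(0, 1)))[, , 1L]
    mx <- max(.conv2_same(ref, Ka))
  } else {
    mx <- max(det3)
  }
  psf$detection <- det3 / mx
  psf$detection[psf$detection > 1] <- 1
  psf
}

#' Convolve a sampled PSF with a calibration bead
#'
#' Convolves the excitation field with a uniform solid sphere of the given
#' diameter (voxel-center inclusion kernel, normalized to unit sum). Large
#' beads average out the donut zero and so introduce an apparent background
#' into the PSF shape. Diameters below one grid pitch are treated as 0 with
#' a warning.
#'
#' @param psf a sampled `psf`.
#' @param bead_diameter sphere diameter (nm).
#' @return the convolved PSF.
#' @export
psf_convolve_bead <- function(psf, bead_diameter) {
  stopifnot(inherits(psf, "psf_sampled"))
  .assert_scalar_pos(bead_diameter, "bead_diameter", allow_zero = TRUE)
  if (bead_diameter == 0) return(psf)
  pitch <- psf$grid$x[2L] - psf$grid$x[1L]
  zpitch <- if (length(psf$grid$z) > 1L) psf$grid$z[2L] - psf$grid$z[1L] else pitch
  if (bead_diameter < pitch) {
    warning("bead smaller than one grid pitch; treated as 0")
    return(psf)
  }
  if (bead_diameter > 2 * max(abs(psf$grid$x)))
    stop("bead larger than the grid extent", call. = FALSE)
  r <- bead_diameter / 2
  nx <- ceiling(r / pitch); nzk <- ceiling(r / zpitch)
  ox <- seq(-nx, nx) * pitch
  oz <- if (length(psf$grid$z) > 1L) seq(-nzk, nzk) * zpitch else 0
  field <- psf$excitation
  dm <- dim(field)
  acc <- array(0, dm)
  wsum <- 0
  for (iz in seq_along(oz)) for (iy in seq_along(ox)) for (ix in seq_along(ox)) {
    if (ox[ix]^2 + ox[iy]^2 + oz[iz]^2 > r^2) next
    sh <- .shift_array(field, c(ix - nx - 1L, iy - nx - 1L,
                                if (length(oz) > 1L) iz - nzk - 1L else 0L))
    acc <- acc + sh
    wsum <- wsum + 1
  }
  psf$excitation <- acc / wsum
  psf
}

# Shift a 3D array by integer voxels, replicating edges (keeps the total
# integral approximately conserved for fields that decay to a plateau).
.shift_array <- function(a, s) {
  dm <- dim(a)
  idx <- lapply(1:3, function(d) {
    i <- seq_len(dm[d]) - s[d]
    pmin(pmax(i, 1L), dm[d])
  })
  a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

#' Load an experimentally calibrated PSF stack
#'
#' Reads a 3D intensity stack from a multi-page TIFF (pages = z planes,
#' ZYX order) and wraps it as an interpolating PSF. Grid spacing comes
#' from the arguments or, if missing, from a JSON sidecar `<path>.json`
#' with fields `pixelsize_xy_nm` and `pixelsize_z_nm`. Negative stack
#' values are clipped to 0 with a warning. Evaluation reproduces stored
#' voxel values exactly at the nodes, interpolates with separable cubics
#' inside the support and returns 0 outside (flagged `out_of_range`).
#'
#' @param path TIFF file path.
#' @param pixelsize_xy_nm,pixelsize_z_nm voxel spacing (nm).
#' @param center voxel index (x, y, z; 1-based, fractional allowed) mapped
#'   to offset 0; defaults to the stack center.
#' @return a sampled `psf` of kind `"calibrated"`.
#' @export
psf_load_calibrated <- function(path, pixelsize_xy_nm = NULL,
                                pixelsize_z_nm = NULL, center = NULL) {
  if (is.null(pixelsize_xy_nm) || is.null(pixelsize_z_nm)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("missing grid spacing: pass pixelsize_xy_nm/pixelsize_z_nm or provide a JSON sidecar",
           call. = FALSE)
    meta <- jsonlite::read_json(side)
    pixelsize_xy_nm <- pixelsize_xy_nm %||% meta$pixelsize_xy_nm
    pixelsize_z_nm <- pixelsize_z_nm %||% meta$pixelsize_z_nm
    if (is.null(pixelsize_xy_nm) || is.null(pixelsize_z_nm))
      stop("sidecar lacks pixelsize_xy_nm / pixelsize_z_nm", call. = FALSE)
  }
  # float stacks are returned natively; integer stacks come scaled to [0, 1],
  # which is immaterial for a PSF (only relative intensities matter)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  field <- array(0, c(nx, ny, nz))
  for (iz in seq_len(nz)) field[, , iz] <- t(pages[[iz]])  # page rows = y
  if (any(field < 0)) {
    warning("negative stack values clipped to 0")
    field[field < 0] <- 0
  }
  if (is.null(center)) center <- (c(nx, ny, nz) + 1) / 2
  xs <- (seq_len(nx) - center[1L]) * pixelsize_xy_nm
  ys <- (seq_len(ny) - center[2L]) * pixelsize_xy_nm
  zs <- (seq_len(nz) - center[3L]) * pixelsize_z_nm
  structure(list(kind = "calibrated", grid = list(x = xs, y = ys, z = zs),
                 excitation = field, A = max(field),
                 zero_offset = c(0, 0, 0), detection = NULL),
            class = c("psf_sampled", "psf"))
}

#' @export
psf_eval.psf_sampled <- function(psf, offset) {
  v <- .interp_cubic3(psf$excitation, psf$grid, offset)
  oor <- attr(v, "out_of_range")
  v <- pmax(v, 0)           # cubic overshoot below 0 is clipped
  attr(v, "out_of_range") <- oor
  v
}
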