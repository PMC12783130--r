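#' Analytic MINFLUX excitation profiles
#'
#' Closed-form approximations of the focal intensity profiles used in
#' MINFLUX: the vortex "donut" with a central zero, its small-offset
#' quadratic approximation, and a Gaussian (used e.g. for scouting and for
#' conventional beam localization). All profiles are radially symmetric in
#' the offset `x` from the beam position and are parameterized by a length
#' scale `sigma` (nm) and an amplitude `A` (the donut and quadratic forms
#' integrate to `A` over the plane / are normalized consistently with it).
#'
#' `eval_donut2d()` returns `A |x|^2 / (4 pi sigma^4) exp(-|x|^2 / (2 sigma^2))`,
#' `eval_quadratic()` its first-order (in `|x|^2`) expansion
#' `A |x|^2 / (4 pi sigma^4)`, and `eval_gauss2d()` returns
#' `A exp(-|x|^2 / (2 sigma^2))`.
#'
#' @param offset numeric 2- or 3-vector, or an n x 2/3 matrix of offsets (nm).
#'   The third coordinate is ignored by these 2D profiles.
#' @param sigma length scale of the profile (nm), `> 0`.
#' @param amplitude amplitude constant `A` (arbitrary units).
#' @return intensity value(s), same length as the number of offset rows.
#' @examples
#' eval_donut2d(c(0, 0), sigma = 150)            # exact zero at the minimum
#' eval_gauss2d(c(0, 0), sigma = 150)            # maximum A at the center
#' @export
eval_donut2d <- function(offset, sigma, amplitude = 1) {
  .assert_scalar_pos(sigma, "sigma")
  x <- .as_pos3_mat(offset)
  r2 <- x[, 1L]^2 + x[, 2L]^2
  amplitude * r2 / (4 * pi * sigma^4) * exp(-r2 / (2 * sigma^2))
}

#' @rdname eval_donut2d
#' @export
eval_gauss2d <- function(offset, sigma, amplitude = 1) {
  .assert_scalar_pos(sigma, "sigma")
  x <- .as_pos3_mat(offset)
  r2 <- x[, 1L]^2 + x[, 2L]^2
  amplitude * exp(-r2 / (2 * sigma^2))
}

#' @rdname eval_donut2d
#' @export
eval_quadratic <- function(offset, sigma, amplitude = 1) {
  .assert_scalar_pos(sigma, "sigma")
  x <- .as_pos3_mat(offset)
  r2 <- x[, 1L]^2 + x[, 2L]^2
  amplitude * r2 / (4 * pi * sigma^4)
}

# Analytic lateral gradients (n x 2 matrices), used by the iterative
# estimator Jacobian and by analytic CRB cross-checks.
.grad_donut2d <- function(offset, sigma, amplitude = 1) {
  x <- .as_pos3_mat(offset)
  r2 <- x[, 1L]^2 + x[, 2L]^2
  g <- amplitude / (4 * pi * sigma^4) * (2 - r2 / sigma^2) * exp(-r2 / (2 * sigma^2))
  cbind(g * x[, 1L], g * x[, 2L])
}

.grad_gauss2d <- function(offset, sigma, amplitude = 1) {
  x <- .as_pos3_mat(offset)
  r2 <- x[, 1L]^2 + x[, 2L]^2
  g <- -amplitude / sigma^2 * exp(-r2 / (2 * sigma^2))
  cbind(g * x[, 1L], g * x[, 2L])
}

.grad_quadratic <- function(offset, sigma, amplitude = 1) {
  x <- .as_pos3_mat(offset)
  g <- amplitude / (2 * pi * sigma^4)
  cbind(g * x[, 1L], g * x[, 2L])
}

#' Analytic PSF objects
#'
#' Constructors for analytic PSF models usable anywhere the simulator takes
#' a PSF: pattern measurements, estimators, CRB computation. The default
#' `sigma` of 150 nm corresponds approximately to the donut of a 1.4 NA
#' objective at 640 nm excitation (first intensity maximum near
#' `sqrt(2) * sigma` = 212 nm from the zero).
#'
#' @param sigma profile length scale (nm).
#' @param amplitude normalization constant `A`.
#' @return an object of class `psf` with kind `analytic_donut`,
#'   `analytic_gauss` or `analytic_quadratic`.
#' @seealso [psf_eval()], [psf_vectorial()]
#' @export
psf_donut2d <- function(sigma = 150, amplitude = 1) {
  .new_analytic_psf("analytic_donut", sigma, amplitude)
}

#' @rdname psf_donut2d
#' @export
psf_gauss2d <- function(sigma = 150, amplitude = 1) {
  .new_analytic_psf("analytic_gauss", sigma, amplitude)
}

#' @rdname psf_donut2d
#' @export
psf_quadratic2d <- function(sigma = 150, amplitude = 1) {
  .new_analytic_psf("analytic_quadratic", sigma, amplitude)
}

.new_analytic_psf <- function(kind, sigma, amplitude) {
  .assert_scalar_pos(sigma, "sigma")
  structure(list(kind = kind, sigma = sigma, A = amplitude,
                 zero_offset = c(0, 0, 0), detection = NULL),
            class = c(kind, "psf_analytic", "psf"))
}

#' Evaluate a PSF at sample offsets
#'
#' Returns the excitation intensity of a PSF at offsets from the beam
#' position. For sampled PSFs (vectorial, calibrated) evaluation uses
#' separable cubic interpolation on the stored grid, returning 0 outside
#' the support (with an `out_of_range` attribute).
#'
#' @param psf a `psf` object.
#' @param offset n x 2/3 matrix or single offset (nm).
#' @return numeric vector of intensities.
#' @export
psf_eval <- function(psf, offset) UseMethod("psf_eval")

#' @export
psf_eval.psf_analytic <- function(psf, offset) {
  switch(psf$kind,
    analytic_donut     = eval_donut2d(offset, psf$sigma, psf$A),
    analytic_gauss     = eval_gauss2d(offset, psf$sigma, psf$A),
    analytic_quadratic = eval_quadratic(offset, psf$sigma, psf$A))
}

# Gradient dispatch (lateral only, n x 2)
.psf_grad <- function(psf, offset) {
  if (inherits(psf, "psf_analytic")) {
    switch(psf$kind,
      analytic_donut     = .grad_donut2d(offset, psf$sigma, psf$A),
      analytic_quadratic = .grad_quadratic(offset, psf$sigma, psf$A),
      analytic_gauss     = .grad_gauss2d(offset, psf$sigma, psf$A))
  } else {
    # numeric central differences, 0.01 nm step
    h <- 0.01
    x <- .as_pos3_mat(offset)
    gx <- (psf_eval(psf, sweep(x, 2, c(h / 2, 0, 0), "+")) -
           psf_eval(psf, sweep(x, 2, c(h / 2, 0, 0), "-"))) / h
    gy <- (psf_eval(psf, sweep(x, 2, c(0, h / 2, 0), "+")) -
           psf_eval(psf, sweep(x, 2, c(0, h / 2, 0), "-"))) / h
    cbind(gx, gy)
  }
}

#' Attach a detection model to a PSF
#'
#' Photon collection in a MINFLUX microscope is the product of the
#' excitation intensity at the (fast-scanned) beam position and the
#' detection efficiency through a pinhole that stays fixed at the pattern
#' center, because the fast scanner is not descanned in the detection path.
#' This helper attaches a simple Gaussian detection efficiency profile
#' (max 1 when aligned) to any PSF; the vectorial module offers a full
#' vectorial detection PSF via [psf_apply_detection()].
#'
#' @param psf a `psf` object.
#' @param sigma_det lateral sigma of the detection profile (nm).
#' @param pinhole_shift 2-vector lateral misalignment of the pinhole (nm).
#' @param efficiency peak detection efficiency in `[0, 1]`.
#' @return the PSF with a `$detection` function of sample offsets.
#' @export
psf_attach_detection <- function(psf, sigma_det = 250, pinhole_shift = c(0, 0),
                                 efficiency = 1) {
  stopifnot(inherits(psf, "psf"), efficiency >= 0, efficiency <= 1)
  shift <- c(pinhole_shift[1:2], 0)
  psf$detection <- function(offset) {
    x <- .as_pos3_mat(offset)
    r2 <- (x[, 1L] - shift[1L])^2 + (x[, 2L] - shift[2L])^2
    efficiency * exp(-r2 / (2 * sigma_det^2))
  }
  psf
}

# Detection efficiency at sample offsets relative to the pattern center;
# 1 when no detection model is attached.
.psf_det_eval <- function(psf, offset) {
  if (is.null(psf$detection)) return(rep(1, nrow(.as_pos3_mat(offset))))
  if (is.function(psf$detection)) return(psf$detection(offset))
  .interp_cubic3(psf$detection, psf$grid, offset)
}

# Maximum of the excitation profile over the probed region (disk of radius
# `radius` nm), used to normalize count models so that I0 means "photons
# per unit dwell at PSF max over the probed region". Any consistent
# normalization cancels in the probability model. Memoized: the radial
# scan is much more expensive than the lookups in tight scan loops.
.norm_cache <- new.env(parent = emptyenv())

.psf_norm_scale <- function(psf, radius) {
  fp <- if (!is.null(psf$excitation)) {
    n <- length(psf$excitation)
    signif(psf$excitation[1L] + 3 * psf$excitation[(n + 1L) %/% 2L] +
             7 * psf$excitation[n] + psf$excitation[(n + 3L) %/% 4L], 10)
  } else 0
  key <- paste(psf$kind, psf$sigma %||% "", signif(psf$A, 8), radius, fp,
               sep = "|")
  hit <- get0(key, envir = .norm_cache)
  if (!is.null(hit)) return(hit)
  r <- seq(0, radius, length.out = 201L)
  th <- seq(0, 2 * pi, length.out = 13L)[-13L]
  pts <- cbind(as.vector(outer(r, cos(th))), as.vector(outer(r, sin(th))), 0)
  mx <- max(psf_eval(psf, pts))
  if (mx <= 0) stop("degenerate PSF: zero intensity over the probed region", call. = FALSE)
  assign(key, mx, envir = .norm_cache)
  mx
}
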