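#' Define a MINFLUX probing pattern
#'
#' A pattern is an ordered set of probe offsets `b_i` (nm, relative to the
#' pattern center) with per-point dwell times. Supported geometries:
#' \describe{
#'   \item{`orbit`}{`K_o` points equally spaced on a circle of diameter `L`.}
#'   \item{`line_1d`}{two points at `-L/2, +L/2` along x.}
#'   \item{`zline`}{two points at `-L/2, +L/2` along z (3D probing).}
#' }
#' With `center_probed = TRUE` the pattern center is appended as a final
#' probe point; its dwell is `ctr_dwell_factor` times the per-point dwell.
#' The whole pattern can be repeated `r` times within one pattern scan
#' (repetitions are summed per point and mitigate fluorophore flickering).
#'
#' @param geometry `"orbit"`, `"line_1d"` or `"zline"`.
#' @param L orbit diameter / probe separation (nm), `> 0`.
#' @param K_o number of orbit points (`>= 2` for orbits).
#' @param dwell per-point dwell time (us).
#' @param r pattern repetitions within one scan.
#' @param center_probed append a center probe point?
#' @param ctr_dwell_factor dwell fraction for the center point.
#' @param phase angular offset of the first orbit point (radians).
#' @return an object of class `mfx_pattern` with fields `offsets` (K x 3),
#'   `dwell` (per point, us), `L`, `K`, `K_o`, `center_probed`, `r`.
#' @examples
#' p <- define_pattern("orbit", L = 75, K_o = 4, dwell = 100, center_probed = TRUE)
#' p$K  # 5
#' @export
define_pattern <- function(geometry = c("orbit", "line_1d", "zline"),
                           L, K_o = 4, dwell = 100, r = 1,
                           center_probed = FALSE, ctr_dwell_factor = 1,
                           phase = 0) {
  geometry <- match.arg(geometry)
  .assert_scalar_pos(L, "L")
  .assert_scalar_pos(dwell, "dwell")
  off <- switch(geometry,
    orbit = {
      if (K_o < 2) stop("K_o must be >= 2 for an orbit", call. = FALSE)
      ang <- phase + 2 * pi * (seq_len(K_o) - 1L) / K_o
      cbind(L / 2 * cos(ang), L / 2 * sin(ang), 0)
    },
    line_1d = { K_o <- 2L; cbind(c(-L / 2, L / 2), 0, 0) },
    zline = { K_o <- 2L; cbind(0, 0, c(-L / 2, L / 2)) })
  dw <- rep(dwell, nrow(off))
  if (center_probed) {
    off <- rbind(off, c(0, 0, 0))
    dw <- c(dw, ctr_dwell_factor * dwell)
  }
  structure(list(geometry = geometry, offsets = off, dwell = dw, L = L,
                 K = nrow(off), K_o = K_o, center_probed = center_probed,
                 r = r, center_index = if (center_probed) nrow(off) else NA_integer_),
            class = "mfx_pattern")
}

#' @export
print.mfx_pattern <- function(x, ...) {
  cat(sprintf("<mfx_pattern> %s L=%g nm K=%d (K_o=%d%s) dwell=%g us r=%d\n",
              x$geometry, x$L, x$K, x$K_o,
              if (x$center_probed) " + center" else "", x$dwell[1L], x$r))
  invisible(x)
}

#' Expected photon counts for a pattern scan
#'
#' Evaluates the count model `I_i = I0 (f(x - b_i) + bg)` with `f` the
#' effective (excitation times detection) PSF, scaled so its maximum over
#' the probed region (disk of radius `L`) is 1, and the measurement
#' probabilities `p_i = I_i / sum_j I_j`. The PSF normalization and `I0`
#' cancel in `p_i`.
#'
#' @param pattern an [define_pattern()] object.
#' @param psf a `psf` object (effective field; detection, if attached, is
#'   evaluated at the sample position relative to the pattern center).
#' @param x fluorophore position in the pattern-center frame (nm).
#' @param I0 brightness-times-dwell scale (expected photons per point at
#'   PSF max, before the `bg` term).
#' @param bg dimensionless background relative to the PSF maximum.
#' @return list with `I` (expected counts), `p` (probabilities, sum 1),
#'   `f` (normalized PSF values) and `degenerate` (all-zero model flag).
#' @export
expected_counts <- function(pattern, psf, x, I0 = 1, bg = 0) {
  stopifnot(inherits(pattern, "mfx_pattern"), inherits(psf, "psf"))
  x <- .as_pos3(x)
  rel <- sweep(-pattern$offsets, 2L, x, "+")     # x - b_i
  f <- psf_eval(psf, rel) * .psf_det_eval(psf, matrix(x, 1L))[1L]
  f <- f / .psf_norm_scale(psf, pattern$L)
  I <- I0 * (f + bg)
  s <- sum(I)
  degenerate <- s <= 0
  p <- if (degenerate) rep(NA_real_, length(I)) else I / s
  list(I = I, p = p, f = f, degenerate = degenerate)
}
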