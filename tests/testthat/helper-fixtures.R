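# Shared fixtures: small patterns and PSFs used across test files.

pat_orbit <- function(L = 75, K_o = 4, dwell = 100, r = 1, center = FALSE) {
  define_pattern("orbit", L = L, K_o = K_o, dwell = dwell, r = r,
                 center_probed = center)
}

donut150 <- psf_donut2d(sigma = 150)

# Noiseless model probabilities for an emitter at x under a pattern/psf.
model_p <- function(pattern, psf, x, bg = 0) {
  expected_counts(pattern, psf, x, bg = bg)$p
}

# Small vectorial PSFs are expensive enough to share across tests.
vec_psf_cache <- new.env()

get_vec_psf <- function(key, ...) {
  hit <- get0(key, envir = vec_psf_cache)
  if (!is.null(hit)) return(hit)
  val <- psf_vectorial(optics_config(...))
  assign(key, val, envir = vec_psf_cache)
  val
}
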