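#' Single fluorophore with motion and photophysics
#'
#' Creates a mutable fluorophore object (an environment, so that photon
#' budgets and positions update as the simulation consumes them). The
#' fluorophore combines:
#' \itemize{
#'   \item motion: a static position, a sampled [make_diffusion_track()] /
#'     [make_stepping_track()] track (frozen-position lookup per point
#'     measurement), a `function(t_us)` returning a position, or live
#'     Brownian motion via `diffusion_D` (exact incremental sampling);
#'   \item brightness: expected detected photons per us at unit normalized
#'     excitation intensity;
#'   \item bleaching: an emitted-photon budget drawn from an exponential
#'     distribution with mean `budget_mean` (photons are debited before
#'     detection losses, i.e. the pinhole does not protect the budget);
#'   \item blinking: an exponential on/off switching trace with means
#'     `t_on` / `t_off` and a reactivation limit (see
#'     [sample_switching_trace()]).
#' }
#'
#' @param position 2/3-vector (nm), `fl_track`, or `function(t_us)`.
#' @param brightness expected photons per us at unit intensity.
#' @param budget_mean mean emitted-photon budget (`Inf` disables bleaching).
#' @param t_on,t_off mean blinking dwells (us); `NULL` disables blinking.
#' @param reactivations allowed returns from the dark state.
#' @param trace_duration horizon for the pre-computed switching trace (us).
#' @param blink_start initial blinking state: `"on"`, `"off"` or
#'   `"stationary"` (see [sample_switching_trace()]).
#' @param diffusion_D live diffusion coefficient (um^2/s), alternative to a
#'   pre-sampled track.
#' @param id optional identifier (e.g. ground-truth structure id).
#' @param seed optional RNG seed for budget and trace initialization.
#' @return an object of class `fluorophore`.
#' @export
fluorophore <- function(position = c(0, 0, 0), brightness = 100,
                        budget_mean = Inf, t_on = NULL, t_off = NULL,
                        reactivations = Inf, trace_duration = 1e7,
                        blink_start = "on",
                        diffusion_D = NULL, id = NA, seed = NULL) {
  fl <- new.env(parent = emptyenv())
  fl$brightness <- brightness
  fl$id <- id
  fl$mode <- "static"
  fl$pos <- c(0, 0, 0)
  if (is.function(position)) {
    fl$mode <- "function"
    fl$pos_fn <- position
    fl$pos <- .as_pos3(position(0))
  } else if (inherits(position, "fl_track")) {
    fl$mode <- "track"
    fl$track <- position
    fl$pos <- .as_pos3(unlist(position[1L, c("x", "y", "z")]))
  } else {
    fl$pos <- .as_pos3(position)
  }
  if (!is.null(diffusion_D)) {
    if (diffusion_D < 0) stop("diffusion_D must be >= 0", call. = FALSE)
    fl$mode <- "diffusing"
    fl$D <- diffusion_D
    fl$last_t <- 0
  }
  .with_seed(seed, {
    fl$budget_remaining <- if (is.finite(budget_mean)) rexp(1, 1 / budget_mean) else Inf
    fl$trace <- if (!is.null(t_on) && !is.null(t_off)) {
      sample_switching_trace(t_on, t_off, trace_duration, reactivations,
                             start = blink_start)
    } else NULL
  })
  fl$bleached <- fl$budget_remaining <= 0
  class(fl) <- "fluorophore"
  fl
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore> mode=%s pos=(%.1f, %.1f, %.1f) nm brightness=%g/us budget=%s%s\n",
              x$mode, x$pos[1], x$pos[2], x$pos[3], x$brightness,
              if (is.finite(x$budget_remaining)) sprintf("%.0f", x$budget_remaining) else "Inf",
              if (!is.null(x$trace)) " blinking" else ""))
  invisible(x)
}

#' Fluorophore position at a time point
#'
#' For diffusing fluorophores this advances the internal Brownian state to
#' `t_us` (exact sampling of the increment); for tracks and position
#' functions it is a pure lookup. Each point measurement should call this
#' once at the point start so the position is frozen during the dwell.
#'
#' @param fl a [fluorophore()].
#' @param t_us time (us).
#' @return 3-vector position (nm).
#' @export
fl_position <- function(fl, t_us) {
  switch(fl$mode,
    static = fl$pos,
    "function" = .as_pos3(fl$pos_fn(t_us)),
    track = as.numeric(.track_position(fl$track, t_us)),
    diffusing = {
      dt <- t_us - fl$last_t
      if (dt > 0) {
        fl$pos[1:2] <- fl$pos[1:2] + rnorm(2L, sd = sqrt(2 * fl$D * dt))
        fl$last_t <- t_us
      }
      fl$pos
    })
}

#' Is the fluorophore active (not bleached)?
#' @param fl a [fluorophore()].
#' @return logical.
#' @export
fl_active <- function(fl) !fl$bleached

#' Photon emission during one point measurement
#'
#' The expected number of emitted photons is
#' `brightness x intensity x dwell x on_fraction(window)`; the realized
#' emitted count is Poisson around that mean, truncated at the remaining
#' photon budget (which is then debited by the emitted count). The detected
#' count is a binomial thinning of the emitted photons by the detection
#' efficiency, so photons blocked by the pinhole still consume budget.
#'
#' @param fl a [fluorophore()].
#' @param normalized_intensity excitation intensity (normalized units).
#' @param dwell dwell time (us), `> 0`.
#' @param t_start start time of the dwell window (us).
#' @param detection_efficiency probability that an emitted photon is
#'   detected, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return detected photon count (integer), with attribute `emitted`.
#' @export
emit_photons <- function(fl, normalized_intensity, dwell, t_start = 0,
                         detection_efficiency = 1, seed = NULL) {
  .assert_scalar_pos(dwell, "dwell")
  .with_seed(seed, {
    if (fl$bleached || fl$budget_remaining <= 0) {
      fl$bleached <- TRUE
      out <- 0L
      attr(out, "emitted") <- 0L
      return(out)
    }
    frac <- .on_fraction_vec(fl$trace, t_start, t_start + dwell)
    mu <- fl$brightness * normalized_intensity * dwell * frac
    emitted <- rpois(1L, mu)
    if (emitted > fl$budget_remaining) emitted <- floor(fl$budget_remaining)
    fl$budget_remaining <- fl$budget_remaining - emitted
    if (fl$budget_remaining < 1) fl$bleached <- TRUE   # no whole photon left
    detected <- if (detection_efficiency >= 1) emitted
                else rbinom(1L, emitted, detection_efficiency)
    out <- as.integer(detected)
    attr(out, "emitted") <- as.integer(emitted)
    out
  })
}

#' Sinusoidal vibration trajectory
#'
#' System vibrations are modeled as a moving fluorophore on a sinusoidal
#' path; pass the returned function as `position` to [fluorophore()].
#'
#' @param amplitude_nm vibration amplitude (nm).
#' @param frequency_hz vibration frequency (Hz).
#' @param phase phase offset (radians).
#' @param axis unit direction of motion (2/3-vector).
#' @param center rest position (nm).
#' @return `function(t_us)` returning a 3-vector (nm).
#' @export
make_vibration_fn <- function(amplitude_nm, frequency_hz, phase = 0,
                              axis = c(1, 0, 0), center = c(0, 0, 0)) {
  axis <- .as_pos3(axis); axis <- axis / sqrt(sum(axis^2))
  center <- .as_pos3(center)
  w <- 2 * pi * frequency_hz * 1e-6   # rad per us
  function(t_us) center + axis * amplitude_nm * sin(w * t_us + phase)
}

#' Collection of fluorophores
#'
#' A scene is a list of [fluorophore()] objects; the photon response of the
#' collection is the sum of independent member responses.
#'
#' @param ... fluorophores, or a single list of them.
#' @return an object of class `fl_collection`.
#' @export
fl_collection <- function(...) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1L]]) &&
      !inherits(members[[1L]], "fluorophore")) {
    members <- members[[1L]]
  }
  stopifnot(all(vapply(members, inherits, logical(1), "fluorophore")))
  structure(list(members = members), class = "fl_collection")
}

#' @export
length.fl_collection <- function(x) length(x$members)

#' @export
print.fl_collection <- function(x, ...) {
  cat(sprintf("<fl_collection> %d fluorophore(s), %d active\n",
              length(x$members), sum(vapply(x$members, fl_active, logical(1)))))
  invisible(x)
}

#' Photon response of a collection at one pattern position
#'
#' Freezes every member at `t_start`, evaluates the effective field at the
#' member positions and draws independent detected counts per member.
#'
#' @param col an [fl_collection()].
#' @param field_fn `function(pos_matrix)` returning the normalized effective
#'   excitation-times-detection intensity at sample positions (nm).
#' @param dwell dwell time (us).
#' @param t_start window start (us).
#' @param detection_efficiency see [emit_photons()].
#' @param seed optional RNG seed.
#' @return list with `per_member` (integer vector) and `total`.
#' @export
collection_response <- function(col, field_fn, dwell, t_start = 0,
                                detection_efficiency = 1, seed = NULL) {
  stopifnot(inherits(col, "fl_collection"))
  .with_seed(seed, {
    n <- length(col$members)
    counts <- integer(n)
    if (n > 0L) {
      for (i in seq_len(n)) {
        fl <- col$members[[i]]
        pos <- fl_position(fl, t_start)
        inten <- field_fn(matrix(pos, 1L))
        counts[i] <- emit_photons(fl, inten, dwell, t_start, detection_efficiency)
      }
    }
    list(per_member = counts, total = sum(counts))
  })
}

#' Photophysics presets for common switching modalities
#'
#' Order-of-magnitude defaults distinguishing the main single-molecule
#' switching modalities by photon budget, blinking dwells and reactivation
#' statistics: DNA-PAINT probes rebind indefinitely (infinite
#' reactivations, high photon budget per binding event), dyes in a
#' dSTORM-type blinking buffer return from the dark state about twice on
#' average (geometrically distributed), and PALM-type photoconvertible
#' fluorescent proteins bleach after a single activation with a markedly
#' smaller photon budget. Budgets are generic defaults, not calibrated to a
#' specific dye.
#'
#' @param name `"PAINT"`, `"dSTORM"` or `"PALM"`.
#' @param seed optional RNG seed (used to draw the dSTORM reactivation count).
#' @return list with `budget_mean`, `t_on`, `t_off`, `reactivations`.
#' @export
photophysics_preset <- function(name = c("PAINT", "dSTORM", "PALM"), seed = NULL) {
  name <- match.arg(name)
  switch(name,
    PAINT = list(budget_mean = 3e5, t_on = 5e5, t_off = 5e6, reactivations = Inf),
    dSTORM = {
      re <- .with_seed(seed, rgeom_mean2())
      list(budget_mean = 1e5, t_on = 2e4, t_off = 1e6, reactivations = re)
    },
    PALM = list(budget_mean = 1e4, t_on = 5e4, t_off = 1e6, reactivations = 0))
}

# Geometric reactivation count with mean 2 (support 0, 1, 2, ...).
rgeom_mean2 <- function() stats::rgeom(1L, prob = 1 / 3)

#' Nuclear-pore-complex test scene
#'
#' Generates a ground-truth benchmark scene of 8-fold symmetric rings
#' mimicking labeled nucleoporins: `n_pores` ring centers placed uniformly
#' in a square field of view, each with `corners` binding sites equally
#' spaced on a circle of radius `ring_radius` at a random global rotation,
#' each site carrying a fluorophore with probability
#' `labeling_efficiency`.
#'
#' @param n_pores number of rings.
#' @param ring_radius ring radius (nm); 50 nm approximates the Nup96 ring.
#' @param corners binding sites per ring (`>= 3`).
#' @param labeling_efficiency per-site labeling probability in `[0, 1]`.
#' @param fov side length of the square field of view (nm).
#' @param brightness,budget_mean,t_on,t_off,reactivations,blink_start
#'   photophysics passed to [fluorophore()] (e.g. from
#'   [photophysics_preset()]).
#' @param seed optional RNG seed.
#' @return an [fl_collection()]; each member's `id` is its pore index.
#' @export
make_npc_fixture <- function(n_pores = 10, ring_radius = 50, corners = 8,
                             labeling_efficiency = 1, fov = 2000,
                             brightness = 100, budget_mean = Inf,
                             t_on = NULL, t_off = NULL, reactivations = Inf,
                             blink_start = "on", seed = NULL) {
  if (corners < 3) stop("corners must be >= 3", call. = FALSE)
  stopifnot(labeling_efficiency >= 0, labeling_efficiency <= 1)
  .with_seed(seed, {
    centers <- cbind(runif(n_pores, 0, fov), runif(n_pores, 0, fov))
    if (n_pores > 1L) {
      nn <- min(stats::dist(centers))
      if (nn < 2 * ring_radius)
        warning("pore density implies overlapping rings (nearest neighbor < 2 x ring_radius)")
    }
    members <- list()
    for (p in seq_len(n_pores)) {
      rot <- runif(1, 0, 2 * pi)
      ang <- rot + 2 * pi * (seq_len(corners) - 1L) / corners
      lab <- runif(corners) < labeling_efficiency
      for (k in which(lab)) {
        members[[length(members) + 1L]] <- fluorophore(
          position = c(centers[p, 1L] + ring_radius * cos(ang[k]),
                       centers[p, 2L] + ring_radius * sin(ang[k]), 0),
          brightness = brightness, budget_mean = budget_mean,
          t_on = t_on, t_off = t_off, reactivations = reactivations,
          blink_start = blink_start, id = p)
      }
    }
    fl_collection(members)
  })
}

#' Read a scene from a CSV file
#'
#' Scene files carry columns `id`, `x_nm`, `y_nm`, `z_nm` and optionally
#' `structure_id`; photophysics are applied uniformly from a preset name or
#' explicit arguments.
#'
#' @param path CSV path.
#' @param preset optional [photophysics_preset()] name.
#' @param brightness photons per us at unit intensity.
#' @param seed optional RNG seed for photophysics initialization.
#' @return an [fl_collection()].
#' @export
read_scene_csv <- function(path, preset = NULL, brightness = 100, seed = NULL) {
  df <- read.csv(path)
  need <- c("x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    stop("scene CSV must have columns x_nm, y_nm, z_nm", call. = FALSE)
  ph <- if (!is.null(preset)) photophysics_preset(preset, seed = seed)
        else list(budget_mean = Inf, t_on = NULL, t_off = NULL, reactivations = Inf)
  members <- lapply(seq_len(nrow(df)), function(i) {
    fluorophore(position = c(df$x_nm[i], df$y_nm[i], df$z_nm[i]),
                brightness = brightness, budget_mean = ph$budget_mean,
                t_on = ph$t_on, t_off = ph$t_off,
                reactivations = ph$reactivations,
                id = if ("structure_id" %in% names(df)) df$structure_id[i]
                     else if ("id" %in% names(df)) df$id[i] else i,
                seed = .child_seed(seed, i))
  })
  fl_collection(members)
}
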