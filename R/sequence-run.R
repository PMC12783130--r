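# Execution of full Abberior-style experiments: scouting for candidates,
# the per-candidate iteration ladder with photon and CFR quality checks,
# stickiness bookkeeping, and the tracking protocol used to determine the
# maximal trackable diffusion coefficient.

#' Scout a scene for candidate fluorophores
#'
#' Probes each scouting-grid center with a Gaussian excitation beam; any
#' center whose detected count exceeds the threshold becomes a candidate.
#' Scouting excitation consumes fluorophore photon budgets (which makes
#' low-budget emitters bleach before they are ever localized); note that
#' bleaching by the excitation donut outside the detection volume is not
#' modeled, so scouting-phase bleaching is an underestimate.
#'
#' @param scene an [fl_collection()].
#' @param centers probe centers (n x 2 matrix, nm), e.g. from
#'   [make_scouting_pattern()].
#' @param threshold candidate threshold (detected counts per probe).
#' @param dwell probe dwell (us).
#' @param psf_scout Gaussian scouting PSF.
#' @param t_start clock at the start of scouting (us).
#' @param detection_efficiency see [emit_photons()].
#' @param seed optional RNG seed.
#' @return list with `candidates` (m x 2 matrix), `counts` (per center),
#'   `t_end` (clock after scouting, us).
#' @export
scout_scene <- function(scene, centers, threshold, dwell = 10,
                        psf_scout = psf_gauss2d(sigma = 150),
                        t_start = 0, detection_efficiency = 1, seed = NULL) {
  stopifnot(inherits(scene, "fl_collection"))
  .with_seed(seed, {
    n <- nrow(centers)
    counts <- integer(n)
    t <- t_start
    for (i in seq_len(n)) {
      for (fl in scene$members) {
        if (!fl_active(fl)) next
        pos <- fl_position(fl, t)
        inten <- eval_gauss2d(matrix(pos[1:2] - centers[i, ], 1L), psf_scout$sigma)
        counts[i] <- counts[i] + emit_photons(fl, inten, dwell, t,
                                              detection_efficiency)
      }
      t <- t + dwell
    }
    keep <- counts > threshold
    list(candidates = centers[keep, , drop = FALSE], counts = counts, t_end = t)
  })
}

#' Localize one candidate through the sequence iteration ladder
#'
#' Runs the configured iterations on a candidate position: each iteration
#' shrinks the pattern, applies its power factor, repetitions and
#' estimator, and recenters with the configured damping. Pattern scans
#' accumulate until the iteration photon limit is reached; a localization
#' then passes the photon-rate check (total rate above `bgcThreshold`) and,
#' past the `headstart` localizations, the CFR check (`cfr <= ccrLimit`
#' when enabled). Each failed check decrements the stickiness budget;
#' a valid localization resets it. The candidate is abandoned when the
#' budget reaches 0, after `loclimit` localizations, when the emitter
#' stays dark longer than `maxOffTime`, or when `max_time_us` elapses.
#' After the final ladder step the last iteration repeats (tracking-style).
#'
#' @param candidate starting position (nm).
#' @param scene an [fl_collection()].
#' @param config a [parse_sequence()] configuration.
#' @param psf excitation PSF used by the iteration patterns.
#' @param scanner optional [scanner_state()]; by default built from the
#'   config dead times with the slow scanner on the candidate.
#' @param bg_rate background photons per us per pattern point.
#' @param detection_efficiency see [emit_photons()].
#' @param max_time_us wall-clock budget for this candidate (us).
#' @param track_id identifier stored in the output rows.
#' @param seed optional RNG seed.
#' @return data.frame of localization records: `time_us`, pattern center,
#'   estimate and truth coordinates, `N_photons`, `cfr`, `valid`,
#'   `fail_reason` (`none`, `photon`, `cfr`, `lost`), `iteration_id`,
#'   `track_id`.
#' @export
localize_candidate <- function(candidate, scene, config, psf,
                               scanner = NULL, bg_rate = 0,
                               detection_efficiency = 1,
                               max_time_us = Inf, track_id = 1L, seed = NULL) {
  stopifnot(inherits(config, "sequence_config"))
  if (inherits(scene, "fluorophore")) scene <- fl_collection(list(scene))
  g <- config$globals
  dtm <- config$dead_times
  if (is.null(scanner)) {
    scanner <- scanner_state(pos_slow = .as_pos3(c(candidate[1:2], 0)),
                             dead_time_fast = dtm$fast_us,
                             dead_time_estimator = dtm$estimator_us,
                             dead_time_slow = dtm$slow_us)
  }
  .with_seed(seed, {
    n_itr <- length(config$iterations)
    patterns <- lapply(config$iterations, .itr_pattern, ctr_dwell_factor = g$ctrDwellFactor)
    estimators <- lapply(config$iterations, function(it)
      select_estimator(it$estimator, list(L = it$L, sigma = psf$sigma %||% 150)))
    loclimit <- if (g$loclimit > 0) g$loclimit else Inf
    stick <- g$stickiness
    rows <- vector("list", 64L)
    n_loc <- 0L
    it_i <- 1L
    dark_us <- 0
    while (n_loc < loclimit && scanner$clock < max_time_us) {
      it <- config$iterations[[it_i]]
      pat <- patterns[[it_i]]
      counts <- integer(pat$K)
      Nacc <- 0
      scan_time_ms <- sum(pat$dwell) / 1000 +
        pat$K * pat$r * dtm$fast_us / 1000
      abandoned_dark <- FALSE
      photon_fail <- FALSE
      repeat {
        mr <- measure_pattern(pat, scene, scanner, psf, bg_rate,
                              detection_efficiency, power = it$pwrFactor)
        scanner <- mr$scanner
        counts <- counts + mr$record$counts
        Nacc <- Nacc + mr$record$N
        rate <- mr$record$N / scan_time_ms
        if (rate < g$bgcThreshold) {
          # brightness check failed: the attempt ends here; darkness
          # accumulates toward maxOffTime abandonment
          photon_fail <- TRUE
          dark_us <- dark_us + scan_time_ms * 1000
          if (dark_us > it$maxOffTime * 1000) abandoned_dark <- TRUE
          break
        }
        dark_us <- 0
        if (Nacc >= it$phtLimit) break
        if (scanner$clock >= max_time_us) break
      }
      truth <- mr$record$truth
      tru <- if (!is.null(truth)) truth[which.max(rowSums(!is.na(truth))), ]
             else c(NA_real_, NA_real_, NA_real_)
      center <- scanner$pos_slow + scanner$pos_fast
      cfr <- .cfr_or_na(counts, pat)
      fail <- "none"
      if (abandoned_dark || photon_fail || Nacc < it$phtLimit) {
        fail <- if (abandoned_dark) "lost" else "photon"
      } else if (it$ccrLimit > 0 && n_loc >= g$headstart &&
                 is.finite(cfr) && cfr > it$ccrLimit) {
        fail <- "cfr"
      } else if (it$ccrLimit > 0 && n_loc >= g$headstart && !is.finite(cfr)) {
        fail <- "cfr"
      }
      est <- c(NA_real_, NA_real_, NA_real_)
      if (Nacc > 0) {
        e <- estimators[[it_i]](counts, pat)
        est <- .as_pos3(e$x_est)
        if (!all(is.finite(est))) { est <- c(NA_real_, NA_real_, NA_real_)
                                    if (fail == "none") fail <- "photon" }
      }
      valid <- fail == "none"
      n_loc <- n_loc + 1L
      if (n_loc > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[n_loc]] <- data.frame(
        time_us = scanner$clock,
        center_x_nm = center[1L], center_y_nm = center[2L], center_z_nm = center[3L],
        est_x_nm = center[1L] + est[1L], est_y_nm = center[2L] + est[2L],
        est_z_nm = center[3L] + est[3L],
        true_x_nm = tru[1L], true_y_nm = tru[2L], true_z_nm = tru[3L],
        N_photons = Nacc, cfr = cfr, valid = valid, fail_reason = fail,
        iteration_id = it_i, track_id = track_id)
      if (valid) {
        stick <- g$stickiness                     # reset on success
        scanner <- recenter_scanner(scanner, est, g$damping)
        if (it_i < n_itr) it_i <- it_i + 1L
      } else {
        stick <- stick - 1L
        if (stick <= 0L || abandoned_dark) break
        if (all(is.finite(est))) scanner <- recenter_scanner(scanner, est, g$damping)
      }
    }
    do.call(rbind, rows[seq_len(n_loc)])
  })
}

#' Run a full MINFLUX imaging experiment
#'
#' Alternates scouting rounds and candidate localization until the time
#' budget is exhausted or no active fluorophore remains. Candidates within
#' one scouting pitch of an already-processed candidate are merged.
#'
#' @param scene an [fl_collection()].
#' @param config a [parse_sequence()] configuration.
#' @param fov field of view (nm, scalar or 2-vector); scaled by the
#'   config's `fieldGeoFactor`.
#' @param time_budget_us total experiment time (us).
#' @param psf excitation PSF for the iteration patterns.
#' @param scout_pitch scouting lattice constant (nm).
#' @param scout_dwell scouting probe dwell (us).
#' @param bg_rate,detection_efficiency as in [localize_candidate()].
#' @param seed optional RNG seed.
#' @return list with `localizations` (all records), `summary` (valid /
#'   invalid counts, localization cadence, effective labeling efficiency:
#'   the fraction of ground-truth fluorophores with at least one valid
#'   localization within `match_radius`), and `n_scout_rounds`.
#' @param match_radius truth-matching radius (nm) for the labeling
#'   efficiency summary.
#' @export
run_imaging <- function(scene, config, fov = 1000, time_budget_us = 2e6,
                        psf = psf_donut2d(), scout_pitch = 150,
                        scout_dwell = 20, bg_rate = 0,
                        detection_efficiency = 1, match_radius = 100,
                        seed = NULL) {
  stopifnot(inherits(scene, "fl_collection"), inherits(config, "sequence_config"))
  g <- config$globals
  fov <- rep(as.numeric(fov), length.out = 2L) * g$fieldGeoFactor
  centers <- make_scouting_pattern(fov, scout_pitch)
  threshold <- g$bgcThreshold * scout_dwell / 1000   # counts/ms -> per dwell
  .with_seed(seed, {
    clock <- 0
    all_locs <- list()
    processed <- matrix(numeric(0), 0L, 2L)
    rounds <- 0L
    track_id <- 0L
    while (clock < time_budget_us) {
      sc <- scout_scene(scene, centers, threshold, scout_dwell, t_start = clock,
                        detection_efficiency = detection_efficiency)
      clock <- sc$t_end
      rounds <- rounds + 1L
      cand <- sc$candidates
      if (nrow(cand)) {
        keep <- rep(TRUE, nrow(cand))
        for (i in seq_len(nrow(cand))) {
          if (nrow(processed) &&
              min(sqrt(rowSums(sweep(processed, 2L, cand[i, ])^2))) < scout_pitch)
            keep[i] <- FALSE
          if (keep[i] && i > 1L) {
            prev <- cand[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], , drop = FALSE]
            if (nrow(prev) &&
                min(sqrt(rowSums(sweep(prev, 2L, cand[i, ])^2))) < scout_pitch)
              keep[i] <- FALSE
          }
        }
        cand <- cand[keep, , drop = FALSE]
      }
      if (!nrow(cand)) {
        if (!any(vapply(scene$members, fl_active, logical(1)))) break
        # nothing found this round: scouting consumed its time; try again
        if (clock >= time_budget_us) break
        next
      }
      for (i in seq_len(nrow(cand))) {
        track_id <- track_id + 1L
        sc_state <- scanner_state(pos_slow = c(cand[i, ], 0),
                                  dead_time_fast = config$dead_times$fast_us,
                                  dead_time_estimator = config$dead_times$estimator_us,
                                  dead_time_slow = config$dead_times$slow_us)
        sc_state$clock <- clock
        locs <- localize_candidate(cand[i, ], scene, config, psf,
                                   scanner = sc_state, bg_rate = bg_rate,
                                   detection_efficiency = detection_efficiency,
                                   max_time_us = time_budget_us,
                                   track_id = track_id)
        if (!is.null(locs)) {
          clock <- max(clock, max(locs$time_us))
          all_locs[[length(all_locs) + 1L]] <- locs
        }
        processed <- rbind(processed, cand[i, , drop = FALSE])
        if (clock >= time_budget_us) break
      }
    }
    locs <- if (length(all_locs)) do.call(rbind, all_locs) else NULL
    truth_xy <- t(vapply(scene$members, function(fl) fl$pos[1:2], numeric(2)))
    labeled <- rep(FALSE, nrow(truth_xy))
    if (!is.null(locs)) {
      vl <- locs[locs$valid & is.finite(locs$est_x_nm), , drop = FALSE]
      for (j in seq_len(nrow(vl))) {
        d <- sqrt((truth_xy[, 1L] - vl$est_x_nm[j])^2 +
                  (truth_xy[, 2L] - vl$est_y_nm[j])^2)
        labeled[which.min(d)] <- labeled[which.min(d)] || min(d) < match_radius
      }
    }
    summary <- list(
      n_valid = if (is.null(locs)) 0L else sum(locs$valid),
      n_invalid = if (is.null(locs)) 0L else sum(!locs$valid),
      cadence_hz = if (is.null(locs)) 0 else sum(locs$valid) / (clock * 1e-6),
      effective_labeling_efficiency = mean(labeled),
      n_fluorophores = nrow(truth_xy),
      time_used_us = clock)
    list(localizations = locs, summary = summary, n_scout_rounds = rounds)
  })
}

#' Track diffusing emitters and score track success
#'
#' Runs the tracking protocol: for each attempt a fresh emitter diffusing
#' with coefficient `D` is placed at the origin, the pattern starts
#' centered on it, and the sequence's (last-iteration) feedback loop
#' follows it. A track is successful when it reaches at least 90
#' consecutive valid localizations before the candidate is lost.
#'
#' @param config a [parse_sequence()] configuration.
#' @param D diffusion coefficient (um^2/s).
#' @param n_tracks number of independent tracks.
#' @param psf excitation PSF.
#' @param brightness emitter brightness (photons per us at PSF max). The
#'   default of 2 corresponds to a bright organic dye at tracking laser
#'   powers: the standard sequence then reaches its 500-photon limit within
#'   one or two pattern scans, i.e. a localization cadence near 1 kHz.
#' @param budget_mean emitted-photon budget mean (`Inf` for none).
#' @param bg_rate,detection_efficiency as in [localize_candidate()].
#' @param consecutive_needed consecutive valid localizations defining
#'   success (90 by convention).
#' @param max_time_us per-track time budget (us).
#' @param seed optional RNG seed.
#' @return list with `success` (logical per track), `success_rate`,
#'   `tracks` (list of localization data.frames) and `cadence_hz` (mean
#'   valid-localization rate).
#' @export
run_tracking <- function(config, D, n_tracks = 50, psf = psf_donut2d(),
                         brightness = 2, budget_mean = Inf, bg_rate = 0,
                         detection_efficiency = 1, consecutive_needed = 90,
                         max_time_us = 5e6, seed = NULL) {
  stopifnot(inherits(config, "sequence_config"))
  .with_seed(seed, {
    success <- logical(n_tracks)
    tracks <- vector("list", n_tracks)
    cad <- numeric(n_tracks)
    for (k in seq_len(n_tracks)) {
      fl <- fluorophore(position = c(0, 0, 0), brightness = brightness,
                        budget_mean = budget_mean, diffusion_D = D)
      locs <- localize_candidate(c(0, 0), fl_collection(list(fl)), config, psf,
                                 bg_rate = bg_rate,
                                 detection_efficiency = detection_efficiency,
                                 max_time_us = max_time_us, track_id = k)
      tracks[[k]] <- locs
      if (!is.null(locs)) {
        runs <- rle(locs$valid)
        success[k] <- any(runs$values & runs$lengths >= consecutive_needed)
        cad[k] <- sum(locs$valid) / (max(locs$time_us) * 1e-6)
      }
    }
    list(success = success, success_rate = mean(success), tracks = tracks,
         cadence_hz = mean(cad))
  })
}

#' Maximal trackable diffusion coefficient
#'
#' Sweeps a grid of diffusion coefficients, measures the track success
#' rate at each (via [run_tracking()]) and returns `D_max`: the diffusion
#' coefficient at which half of the tracks are successful, found by linear
#' interpolation of the success-versus-D curve. If the success rate never
#' drops below 0.5 on the grid, the grid maximum is returned with
#' `open_ended = TRUE`.
#'
#' @param config a [parse_sequence()] configuration.
#' @param D_grid increasing diffusion coefficients (um^2/s).
#' @param n_tracks tracks per grid point.
#' @param seed optional RNG seed (per-D child seeds are derived from it).
#' @param ... passed to [run_tracking()].
#' @return list with `D_max`, `open_ended`, `curve` (data.frame `D`,
#'   `success_rate`).
#' @export
estimate_dmax <- function(config, D_grid, n_tracks = 50, seed = NULL, ...) {
  stopifnot(all(diff(D_grid) > 0))
  rates <- numeric(length(D_grid))
  for (i in seq_along(D_grid)) {
    rates[i] <- run_tracking(config, D_grid[i], n_tracks = n_tracks,
                             seed = .child_seed(seed, i), ...)$success_rate
  }
  c(.dmax_from_curve(D_grid, rates),
    list(curve = data.frame(D = D_grid, success_rate = rates)))
}

# Interpolate the 50 % crossing of a success-versus-D curve.
.dmax_from_curve <- function(D_grid, rates) {
  below <- which(rates < 0.5)
  if (!length(below)) return(list(D_max = max(D_grid), open_ended = TRUE))
  j <- below[1L]
  if (j == 1L) return(list(D_max = D_grid[1L], open_ended = FALSE))
  d0 <- D_grid[j - 1L]; d1 <- D_grid[j]
  r0 <- rates[j - 1L]; r1 <- rates[j]
  list(D_max = d0 + (r0 - 0.5) / (r0 - r1) * (d1 - d0), open_ended = FALSE)
}
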