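#' Scanner state of the MINFLUX feedback loop
#'
#' Tracks the positions of the slow (descanned, e.g. galvo) and fast
#' (non-descanned, e.g. EOD) scanners, the simulation clock and the dead
#' times consumed by repositioning and on-board estimation. The pattern
#' center is always `pos_slow + pos_fast`; detection through the pinhole is
#' referenced to `pos_slow` only, because the fast scanner is not descanned
#' in the detection path.
#'
#' Default dead times correspond to current-generation instrument firmware:
#' 11 us per fast-scanner move, 15 us per estimator calculation, 40 us per
#' slow-scanner move.
#'
#' @param pos_slow,pos_fast initial scanner positions (nm).
#' @param dead_time_fast,dead_time_estimator,dead_time_slow dead times (us).
#' @param fast_range maximum fast-scanner excursion per axis (nm); larger
#'   accumulated offsets are handed off to the slow scanner.
#' @return an object of class `scanner_state`.
#' @export
scanner_state <- function(pos_slow = c(0, 0, 0), pos_fast = c(0, 0, 0),
                          dead_time_fast = 11, dead_time_estimator = 15,
                          dead_time_slow = 40, fast_range = 200) {
  structure(list(pos_slow = .as_pos3(pos_slow), pos_fast = .as_pos3(pos_fast),
                 clock = 0, dead_time_fast = dead_time_fast,
                 dead_time_estimator = dead_time_estimator,
                 dead_time_slow = dead_time_slow, fast_range = fast_range),
            class = "scanner_state")
}

#' @export
print.scanner_state <- function(x, ...) {
  cat(sprintf("<scanner_state> slow=(%.1f, %.1f, %.1f) fast=(%.1f, %.1f, %.1f) t=%.1f us\n",
              x$pos_slow[1], x$pos_slow[2], x$pos_slow[3],
              x$pos_fast[1], x$pos_fast[2], x$pos_fast[3], x$clock))
  invisible(x)
}

#' Execute one pattern scan and collect photon counts
#'
#' Probes every pattern point (repeated `r` times; counts are summed per
#' point across repetitions). At the start of each point measurement the
#' fluorophore positions are frozen; detected counts are drawn via
#' [emit_photons()] plus Poisson background. The clock advances by the
#' dwell plus one fast-scanner dead time per point reposition.
#'
#' @param pattern an [define_pattern()] pattern.
#' @param scene an [fl_collection()] (or single [fluorophore()]).
#' @param scanner a [scanner_state()].
#' @param psf a `psf` object.
#' @param bg_rate expected background photons per us per point.
#' @param detection_efficiency binomial thinning applied to emitted photons.
#' @param power excitation power factor multiplying the intensity (the
#'   per-iteration `pwrFactor` of sequence files).
#' @param seed optional RNG seed.
#' @return list with `record` (class `measurement_record`: `counts`, `N`,
#'   `p`, `timestamps`, `pattern_center`, `truth`, `bg_expected`,
#'   `emitted`) and the advanced `scanner`.
#' @export
measure_pattern <- function(pattern, scene, scanner, psf, bg_rate = 0,
                            detection_efficiency = 1, power = 1, seed = NULL) {
  stopifnot(inherits(pattern, "mfx_pattern"), inherits(scanner, "scanner_state"))
  if (inherits(scene, "fluorophore")) scene <- fl_collection(list(scene))
  .with_seed(seed, {
    K <- pattern$K
    r <- pattern$r
    center <- scanner$pos_slow + scanner$pos_fast
    norm <- .psf_norm_scale(psf, pattern$L)
    counts <- integer(K)
    emitted_total <- 0L
    timestamps <- numeric(K)
    truth <- NULL
    mid_i <- if (pattern$center_probed) pattern$center_index else ceiling(K / 2)
    dwell_eff <- pattern$dwell / r
    for (rep_k in seq_len(r)) {
      for (i in seq_len(K)) {
        t0 <- scanner$clock
        if (rep_k == 1L) timestamps[i] <- t0
        b <- center + pattern$offsets[i, ]
        for (m in seq_along(scene$members)) {
          fl <- scene$members[[m]]
          pos <- fl_position(fl, t0)
          exc <- psf_eval(psf, matrix(pos - b, 1L))[1L] / norm
          det <- .psf_det_eval(psf, matrix(pos - scanner$pos_slow, 1L))[1L]
          got <- emit_photons(fl, power * exc * det, dwell_eff[i], t0,
                              detection_efficiency)
          counts[i] <- counts[i] + got
          emitted_total <- emitted_total + attr(got, "emitted")
          if (rep_k == 1L && i == mid_i) {
            if (is.null(truth)) truth <- matrix(NA_real_, length(scene$members), 3L)
            truth[m, ] <- pos
          }
        }
        if (bg_rate > 0) counts[i] <- counts[i] + rpois(1L, bg_rate * dwell_eff[i])
        scanner$clock <- scanner$clock + dwell_eff[i] + scanner$dead_time_fast
      }
    }
    N <- sum(counts)
    record <- structure(list(
      counts = counts, N = N,
      p = if (N > 0) counts / N else rep(NA_real_, K),
      timestamps = timestamps, pattern_center = center,
      pos_slow = scanner$pos_slow,
      emitted = emitted_total,
      truth = truth, bg_expected = bg_rate * dwell_eff,
      dwell = pattern$dwell, center_index = pattern$center_index),
      class = "measurement_record")
    list(record = record, scanner = scanner)
  })
}

#' Recenter the scan pattern on a position estimate
#'
#' Moves the pattern center toward `center + estimate` by the damped step
#' `2^(-damping)` (damping 0 moves by the full estimate, 1 by half). The
#' fast scanner absorbs the move; when its accumulated excursion exceeds
#' its configured range -- or when `use_slow` is set -- the slow scanner
#' absorbs the accumulated fast offset (galvo-following hand-off), which
#' costs one slow-scanner dead time. The clock always advances by the
#' estimator dead time plus the fast-scanner dead time.
#'
#' @param scanner a [scanner_state()].
#' @param estimate position estimate in the pattern-center frame (nm).
#' @param damping exponential damping parameter (`>= 0`).
#' @param use_slow force a slow-scanner hand-off.
#' @return the advanced `scanner_state`; attribute `clipped` flags an
#'   estimate beyond the fast-scanner range.
#' @export
recenter_scanner <- function(scanner, estimate, damping = 0, use_slow = FALSE) {
  stopifnot(inherits(scanner, "scanner_state"))
  estimate <- .as_pos3(estimate)
  if (any(!is.finite(estimate))) stop("estimate must be finite", call. = FALSE)
  step <- estimate * 2^(-damping)
  clipped <- FALSE
  newfast <- scanner$pos_fast + step
  over <- abs(newfast) > 4 * scanner$fast_range
  if (any(over)) {     # gross outlier estimate: clip the commanded move
    newfast[over] <- sign(newfast[over]) * 4 * scanner$fast_range
    clipped <- TRUE
  }
  scanner$pos_fast <- newfast
  scanner$clock <- scanner$clock + scanner$dead_time_estimator + scanner$dead_time_fast
  if (use_slow || any(abs(scanner$pos_fast) > scanner$fast_range)) {
    scanner$pos_slow <- scanner$pos_slow + scanner$pos_fast
    scanner$pos_fast <- c(0, 0, 0)
    scanner$clock <- scanner$clock + scanner$dead_time_slow
  }
  attr(scanner, "clipped") <- clipped
  scanner
}

#' Run a simple measure-estimate-recenter sequence
#'
#' Executes an ordered list of components (each a pattern, an estimator and
#' a recentering policy) repeatedly until a stop condition is met. This is
#' the programmatic counterpart of the sequence-file runner in
#' [run_imaging()] / [run_tracking()] and is convenient for estimator and
#' precision studies on a static scene.
#'
#' @param components list of lists with elements `pattern`
#'   ([define_pattern()]), `estimator` (`function(counts, pattern)` as
#'   returned by [select_estimator()]), optional `recenter` (logical,
#'   default TRUE) and `damping`.
#' @param scene an [fl_collection()] or [fluorophore()].
#' @param psf a `psf` object.
#' @param stop list with any of `max_localizations`, `max_time_us`,
#'   `pht_limit` (per-localization photon accumulation target).
#' @param scanner a [scanner_state()].
#' @param bg_rate background photons per us per point.
#' @param detection_efficiency see [measure_pattern()].
#' @param seed optional RNG seed.
#' @return list with `localizations` (data.frame: time_us, center/est/true
#'   coordinates, N_photons, cfr, valid) and `records`.
#' @export
run_sequence <- function(components, scene, psf,
                         stop = list(max_localizations = 100),
                         scanner = scanner_state(), bg_rate = 0,
                         detection_efficiency = 1, seed = NULL) {
  if (inherits(scene, "fluorophore")) scene <- fl_collection(list(scene))
  stopifnot(length(components) >= 1L)
  .with_seed(seed, {
    locs <- list()
    records <- list()
    n_loc <- 0L
    repeat {
      for (comp in components) {
        pat <- comp$pattern
        counts <- integer(pat$K)
        Nacc <- 0L
        first_rec <- NULL
        repeat {
          mr <- measure_pattern(pat, scene, scanner, psf, bg_rate,
                                detection_efficiency)
          scanner <- mr$scanner
          if (is.null(first_rec)) first_rec <- mr$record
          counts <- counts + mr$record$counts
          Nacc <- Nacc + mr$record$N
          records[[length(records) + 1L]] <- mr$record
          pht <- stop$pht_limit %||% 0
          if (Nacc >= pht || pht == 0) break
          if (!is.null(stop$max_time_us) && scanner$clock > stop$max_time_us) break
        }
        valid <- Nacc > 0L
        est <- c(NA_real_, NA_real_, NA_real_)
        if (valid && !is.null(comp$estimator)) {
          e <- comp$estimator(counts, pat)
          est <- .as_pos3(e$x_est)
          valid <- all(is.finite(est))
        }
        center <- scanner$pos_slow + scanner$pos_fast
        tru <- if (!is.null(first_rec$truth)) first_rec$truth[1L, ] else c(NA, NA, NA)
        n_loc <- n_loc + 1L
        locs[[n_loc]] <- data.frame(
          time_us = scanner$clock,
          center_x_nm = center[1L], center_y_nm = center[2L], center_z_nm = center[3L],
          est_x_nm = center[1L] + est[1L], est_y_nm = center[2L] + est[2L],
          est_z_nm = center[3L] + est[3L],
          true_x_nm = tru[1L], true_y_nm = tru[2L], true_z_nm = tru[3L],
          N_photons = Nacc, cfr = .cfr_or_na(counts, pat), valid = valid)
        if (valid && isTRUE(comp$recenter %||% TRUE)) {
          scanner <- recenter_scanner(scanner, est, comp$damping %||% 0)
        }
        done <- (!is.null(stop$max_localizations) && n_loc >= stop$max_localizations) ||
                (!is.null(stop$max_time_us) && scanner$clock >= stop$max_time_us)
        if (done) {
          return(list(localizations = do.call(rbind, locs), records = records,
                      scanner = scanner))
        }
      }
    }
  })
}

.cfr_or_na <- function(counts, pattern) {
  if (!pattern$center_probed) return(NA_real_)
  orbit <- counts[-pattern$center_index]
  if (mean(orbit) == 0) return(Inf)
  counts[pattern$center_index] / mean(orbit)
}

#' Monte-Carlo localization experiment for a static emitter
#'
#' Fast, vectorized engine for precision studies: simulates `n_loc`
#' independent localizations of a static (optionally blinking) fluorophore
#' probed with one pattern scan per localization, and applies an estimator
#' to each. The brightness scale is calibrated so that the mean total
#' detected photon count equals `photons_per_loc` (duty cycle of the
#' blinking trace accounted for). Pattern repetitions `r` subdivide each
#' point dwell, summing counts per point, which is the flicker-mitigation
#' mechanism studied with [flicker_excess()].
#'
#' @param pattern an [define_pattern()] pattern.
#' @param psf a `psf` object.
#' @param n_loc number of localizations.
#' @param photons_per_loc target mean detected photons per localization.
#' @param x_true true fluorophore position, pattern frame (nm).
#' @param bg dimensionless background (relative to PSF max, as in
#'   [expected_counts()]).
#' @param t_on,t_off blinking dwells (us); `NULL` for a steady emitter.
#' @param dead_time_fast inter-point dead time (us) entering the blinking
#'   time base.
#' @param estimator `function(counts, pattern)`; default iterative donut LSQ.
#' @param seed optional RNG seed.
#' @return list with `est` (n x 3 estimates, NA where the localization was
#'   degenerate), `N` (per-localization photon totals), `mean_N`,
#'   `p_model` (model probabilities) and `pattern`.
#' @export
simulate_localizations <- function(pattern, psf, n_loc = 1000,
                                   photons_per_loc = 500,
                                   x_true = c(0, 0, 0), bg = 0,
                                   t_on = NULL, t_off = NULL,
                                   dead_time_fast = 0,
                                   estimator = NULL, seed = NULL) {
  stopifnot(inherits(pattern, "mfx_pattern"))
  if (is.null(estimator))
    estimator <- select_estimator("lsq_donut",
                                  list(L = pattern$L, sigma = psf$sigma %||% 150))
  ec <- expected_counts(pattern, psf, x_true, I0 = 1, bg = bg)
  if (ec$degenerate) stop("degenerate count model at x_true", call. = FALSE)
  K <- pattern$K
  r <- pattern$r
  dwell_eff <- rep(pattern$dwell / r, r)          # K*r sub-dwells in scan order
  point_of <- rep(seq_len(K), r)
  duty <- if (!is.null(t_on)) t_on / (t_on + t_off) else 1
  # per sub-dwell expected counts for an always-on emitter, scaled to target N
  w <- (ec$f[point_of] + bg) * dwell_eff
  scale <- photons_per_loc / (sum(w) * duty)
  mu_on <- w * scale
  .with_seed(seed, {
    est <- matrix(NA_real_, n_loc, 3L)
    N <- integer(n_loc)
    if (is.null(t_on)) {
      cnt <- matrix(rpois(n_loc * K * r, rep(mu_on, each = n_loc)), n_loc)
      counts <- matrix(0L, n_loc, K)
      for (j in seq_len(K * r)) counts[, point_of[j]] <- counts[, point_of[j]] + cnt[, j]
      N <- rowSums(counts)
      for (i in seq_len(n_loc)) {
        if (N[i] == 0L) next
        e <- estimator(counts[i, ], pattern)
        est[i, ] <- .as_pos3(e$x_est)
      }
    } else {
      starts <- cumsum(c(0, head(dwell_eff + dead_time_fast, -1L)))
      ends <- starts + dwell_eff
      scan_T <- max(ends)
      for (i in seq_len(n_loc)) {
        tr <- sample_switching_trace(t_on, t_off, scan_T)
        frac <- .on_fraction_vec(tr, starts, ends)
        cnt <- rpois(K * r, mu_on * frac)
        counts <- integer(K)
        for (j in seq_len(K * r)) counts[point_of[j]] <- counts[point_of[j]] + cnt[j]
        N[i] <- sum(counts)
        if (N[i] == 0L) next
        e <- estimator(counts, pattern)
        est[i, ] <- .as_pos3(e$x_est)
      }
    }
    list(est = est, N = N, mean_N = mean(N), p_model = ec$p, pattern = pattern)
  })
}
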