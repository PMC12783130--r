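#' Brownian diffusion track
#'
#' Samples a diffusing trajectory on a regular time grid: per-coordinate
#' jumps are i.i.d. normal with variance `2 D dt` and the position is the
#' cumulative sum of the jumps. With D in um^2/s and dt in us the jump
#' standard deviation in nm is `sqrt(2 D dt)` because 1 um^2/s equals
#' 1 nm^2/us.
#'
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param dt sampling interval (us), `> 0`.
#' @param duration track duration (us).
#' @param dims number of diffusing coordinates (1, 2 or 3); remaining
#'   coordinates stay 0.
#' @param x0 start position (nm).
#' @param seed optional RNG seed (locally scoped).
#' @return a `fl_track`: data.frame with columns `t_us`, `x`, `y`, `z` (nm)
#'   and attribute `dt_us`.
#' @export
make_diffusion_track <- function(D, dt, duration, dims = 2, x0 = c(0, 0, 0),
                                 seed = NULL) {
  if (!is.numeric(D) || D < 0) stop("D must be >= 0", call. = FALSE)
  .assert_scalar_pos(dt, "dt")
  n <- max(1L, floor(duration / dt))
  x0 <- .as_pos3(x0)
  .with_seed(seed, {
    jumps <- matrix(0, n, 3L)
    if (D > 0)
      jumps[, seq_len(dims)] <- rnorm(n * dims, sd = sqrt(2 * D * dt))
    pos <- apply(jumps, 2L, cumsum)
    if (n == 1L) pos <- matrix(pos, 1L)
    tr <- data.frame(t_us = seq_len(n) * dt,
                     x = x0[1L] + pos[, 1L],
                     y = x0[2L] + pos[, 2L],
                     z = x0[3L] + pos[, 3L])
    tr <- rbind(data.frame(t_us = 0, x = x0[1L], y = x0[2L], z = x0[3L]), tr)
    structure(tr, dt_us = dt, class = c("fl_track", "data.frame"))
  })
}

#' Stepping (motor-like) track
#'
#' Models processive stepping: waiting times between steps are i.i.d.
#' exponential with mean `t_step`, each step advances the position along x
#' by `step_size`. The sampled position at time `t` is the cumulative sum of
#' the steps taken up to `t`.
#'
#' @param step_size step length (nm).
#' @param t_step mean dwell between steps (us).
#' @param dt sampling interval (us); a warning is issued when `dt > t_step/5`
#'   since the dwell statistics would be aliased.
#' @param duration track duration (us).
#' @param seed optional RNG seed.
#' @return a `fl_track` data.frame (see [make_diffusion_track()]); step
#'   times are stored in attribute `step_times_us`.
#' @export
make_stepping_track <- function(step_size, t_step, dt, duration, seed = NULL) {
  .assert_scalar_pos(step_size, "step_size")
  .assert_scalar_pos(t_step, "t_step")
  .assert_scalar_pos(dt, "dt")
  .assert_scalar_pos(duration, "duration")
  if (dt > t_step / 5)
    warning("dt > t_step/5: step dwell statistics will be aliased")
  .with_seed(seed, {
    times <- numeric(0)
    t <- rexp(1, 1 / t_step)
    while (t <= duration) {
      times <- c(times, t)
      t <- t + rexp(1, 1 / t_step)
    }
    tg <- seq(0, duration, by = dt)
    nsteps <- findInterval(tg, times)
    tr <- data.frame(t_us = tg, x = step_size * nsteps, y = 0, z = 0)
    structure(tr, dt_us = dt, step_times_us = times,
              class = c("fl_track", "data.frame"))
  })
}

# Position lookup on a sampled track: previous-sample hold (each point
# measurement sees one frozen position).
.track_position <- function(track, t) {
  i <- findInterval(t, track$t_us)
  i[i < 1L] <- 1L
  i[i > nrow(track)] <- nrow(track)
  cbind(track$x[i], track$y[i], track$z[i])
}

#' Blinking trace of on/off switching events
#'
#' Draws alternating on and off dwell times from exponential distributions
#' with means `t_on` and `t_off`. The trace starts in the on state at a
#' uniformly random phase of an on-dwell (stationary start). After
#' `reactivations` returns from the off state the fluorophore stays off
#' permanently: `reactivations = 0` reproduces PALM-like one-shot emitters,
#' finite values dSTORM-like blinking buffers, `Inf` PAINT-like imaging.
#'
#' @param t_on,t_off mean on/off dwell times (us), `> 0`.
#' @param duration trace horizon (us); beyond it the final state persists.
#' @param reactivations allowed returns to the on state (count or `Inf`).
#' @param start `"on"` (default: the trace begins in an on-period),
#'   `"off"` (begins dark; the first switch-on is an activation), or
#'   `"stationary"` (the initial state is drawn with the equilibrium
#'   on-probability `t_on / (t_on + t_off)`, appropriate for ensembles at
#'   steady state). Dwells are exponential, hence memoryless, so no
#'   residual-time correction is needed.
#' @param seed optional RNG seed.
#' @return a `switching_trace`: list with `events` (strictly increasing
#'   transition times, us), `start_on` (logical) and `duration`.
#' @export
sample_switching_trace <- function(t_on, t_off, duration, reactivations = Inf,
                                   start = c("on", "off", "stationary"),
                                   seed = NULL) {
  .assert_scalar_pos(t_on, "t_on")
  .assert_scalar_pos(t_off, "t_off")
  start <- match.arg(start)
  .with_seed(seed, {
    on <- switch(start,
                 on = TRUE,
                 off = FALSE,
                 stationary = runif(1) < t_on / (t_on + t_off))
    start_on <- on
    events <- numeric(0)
    t <- 0
    n_on_periods <- if (on) 1L else 0L
    repeat {
      dwell <- rexp(1, 1 / if (on) t_on else t_off)
      t <- t + dwell
      if (t >= duration) break
      if (on) {
        events <- c(events, t)  # switch off
        on <- FALSE
        if (is.finite(reactivations) && n_on_periods > reactivations) break
      } else {
        if (is.finite(reactivations) && n_on_periods > reactivations) break
        events <- c(events, t)  # switch on
        on <- TRUE
        n_on_periods <- n_on_periods + 1L
      }
    }
    structure(list(events = events, start_on = start_on, duration = duration),
              class = "switching_trace")
  })
}

#' Fraction of a time window spent in the on state
#'
#' Computes the exact overlap of the on intervals of a switching trace with
#' the window `[t0, t1)`, divided by the window length. Outside the trace
#' horizon the final state is treated as persisting.
#'
#' @param trace a `switching_trace` (or `NULL`, treated as always on).
#' @param t0,t1 window bounds (us), `t1 > t0`.
#' @return fraction in `[0, 1]`.
#' @export
on_fraction <- function(trace, t0, t1) {
  as.numeric(.on_fraction_vec(trace, t0, t1))
}

# Vectorized over aligned windows t0[i], t1[i].
.on_fraction_vec <- function(trace, t0, t1) {
  if (any(t1 <= t0)) stop("t1 must exceed t0", call. = FALSE)
  if (is.null(trace)) return(rep(1, length(t0)))
  ev <- trace$events
  if (length(ev) == 0L) return(rep(as.numeric(trace$start_on), length(t0)))
  # cumulative on-time at the event boundaries
  bnd <- c(0, ev)
  state <- rep(c(trace$start_on, !trace$start_on), length.out = length(bnd))
  seg <- diff(bnd)
  cum_on <- c(0, cumsum(seg * as.numeric(state[seq_along(seg)])))
  on_time_at <- function(t) {
    i <- findInterval(t, bnd)
    cum_on[i] + as.numeric(state[i]) * (t - bnd[i])
  }
  (on_time_at(t1) - on_time_at(t0)) / (t1 - t0)
}
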