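seq_file <- system.file("extdata", "tracking_2d.json", package = "minfluxsim")

# Sequence files --------------------------------------------------------------

test_that("the packaged 2D tracking sequence parses to the documented parameters", {
  cfg <- parse_sequence(seq_file)
  last <- cfg$iterations[[length(cfg$iterations)]]
  expect_equal(last$L, 75)
  expect_equal(last$patRepeat, 3L)
  expect_equal(last$patDwellTime, 0.3)
  expect_equal(last$phtLimit, 500)
  expect_equal(last$ccrLimit, 0.9)
  expect_equal(cfg$globals$stickiness, 4L)
  expect_equal(cfg$dead_times$fast_us, 11)
  expect_equal(cfg$dead_times$estimator_us, 15)
  expect_equal(cfg$dead_times$slow_us, 40)
})

test_that("sequence files round-trip losslessly and tolerate unknown keys", {
  cfg <- parse_sequence(seq_file)
  tmp <- tempfile(fileext = ".json")
  write_sequence(cfg, tmp)
  expect_identical(parse_sequence(tmp), cfg)
  # YAML mirror round-trips too
  tmpy <- tempfile(fileext = ".yaml")
  write_sequence(cfg, tmpy)
  expect_identical(parse_sequence(tmpy), cfg)
  # unknown key: warning, not fatal
  raw <- jsonlite::read_json(seq_file)
  raw$itr[[1]]$frobnicate <- 7
  tmp2 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, tmp2, auto_unbox = TRUE)
  expect_warning(parse_sequence(tmp2), "frobnicate")
  # missing required key names the key
  raw2 <- jsonlite::read_json(seq_file)
  raw2$itr[[2]]$phtLimit <- NULL
  tmp3 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw2, tmp3, auto_unbox = TRUE)
  expect_error(parse_sequence(tmp3), "phtLimit")
})

test_that("the estimator companion file assigns per-iteration estimators", {
  est_file <- system.file("extdata", "default_estimators.json", package = "minfluxsim")
  cfg <- parse_sequence(seq_file, estimators = est_file)
  expect_equal(cfg$iterations[[1]]$estimator, "lsq_donut")
  expect_equal(cfg$iterations[[3]]$estimator, "iter_lsq")
})

# Scouting --------------------------------------------------------------------

test_that("the scouting grid is hexagonal with serpentine ordering", {
  pts <- make_scouting_pattern(c(1200, 1000), pitch = 100)
  # interior points have 6 neighbors at the pitch distance
  d <- as.matrix(stats::dist(pts))
  interior <- which(pts[, 1] > 150 & pts[, 1] < 1050 &
                    pts[, 2] > 150 & pts[, 2] < 850)
  for (i in interior[1:5]) {
    expect_equal(sum(abs(d[i, ] - 100) < 1e-6), 6L)
  }
  # lattice density: one point per pitch^2 sqrt(3)/2
  expected_n <- 1200 * 1000 / (100^2 * sqrt(3) / 2)
  expect_lt(abs(nrow(pts) - expected_n) / expected_n, 0.15)
  # degenerate cover
  expect_identical(nrow(make_scouting_pattern(50, 100)), 1L)
})

test_that("scouting flags bright emitters and nothing in an empty scene", {
  centers <- make_scouting_pattern(600, 150)
  empty <- scout_scene(fl_collection(list()), centers, threshold = 2, seed = 1)
  expect_identical(nrow(empty$candidates), 0L)
  scene <- fl_collection(list(fluorophore(position = c(300, 300, 0), brightness = 2)))
  sc <- scout_scene(scene, centers, threshold = 2, dwell = 20, seed = 2)
  expect_gte(nrow(sc$candidates), 1L)
  dmin <- min(sqrt((sc$candidates[, 1] - 300)^2 + (sc$candidates[, 2] - 300)^2))
  expect_lte(dmin, 150)
  # infinite threshold: no candidates
  scene2 <- fl_collection(list(fluorophore(position = c(300, 300, 0), brightness = 2)))
  none <- scout_scene(scene2, centers, threshold = Inf, dwell = 20, seed = 3)
  expect_identical(nrow(none$candidates), 0L)
})

# CFR -------------------------------------------------------------------------

test_that("the center-frequency ratio follows its definition", {
  pat <- define_pattern("orbit", L = 75, K_o = 3, dwell = 10, center_probed = TRUE)
  expect_equal(compute_cfr(c(10, 10, 10, 10), center_index = 4), 1)
  expect_equal(compute_cfr(c(10, 20, 30, 0), center_index = 4), 0)
  expect_equal(compute_cfr(c(10, 20, 30, 30), center_index = 4), 1.5)
  expect_identical(compute_cfr(c(0, 0, 0, 5), center_index = 4), Inf)
  expect_error(compute_cfr(c(1, 2, 3), center_index = NULL), "center")
})

# Candidate localization ------------------------------------------------------

test_that("a bright immobile emitter yields a stream of valid localizations", {
  cfg <- parse_sequence(seq_file)
  cfg$globals$loclimit <- 25
  fl <- fluorophore(position = c(20, -10, 0), brightness = 0.3)
  locs <- localize_candidate(c(0, 0), fl, cfg, psf_donut2d(150), seed = 4)
  expect_identical(nrow(locs), 25L)
  expect_true(all(locs$valid))
  # validity invariant: valid implies the photon limit was reached and,
  # where checked, the CFR bound holds
  for (i in seq_len(nrow(locs))) {
    it <- cfg$iterations[[locs$iteration_id[i]]]
    expect_gte(locs$N_photons[i], it$phtLimit)
    if (it$ccrLimit > 0) expect_lte(locs$cfr[i], it$ccrLimit)
  }
  # estimates converge onto the truth within a few iterations
  tail_err <- sqrt((locs$est_x_nm - locs$true_x_nm)^2 +
                   (locs$est_y_nm - locs$true_y_nm)^2)[10:25]
  expect_lt(median(tail_err), 5)
})

test_that("losing the emitter triggers stickiness countdown and abandonment", {
  cfg <- parse_sequence(seq_file)
  cfg$globals$loclimit <- 60
  for (it in seq_along(cfg$iterations)) cfg$iterations[[it]]$maxOffTime <- 1e9
  # small budget: the emitter bleaches mid-run, then every check fails
  fl <- fluorophore(position = c(0, 0, 0), brightness = 0.3, budget_mean = 4000,
                    seed = 5)
  locs <- localize_candidate(c(0, 0), fl, cfg, psf_donut2d(150), seed = 6)
  expect_lt(nrow(locs), 60L)
  n <- nrow(locs)
  # the run ends with exactly `stickiness` consecutive failures
  expect_true(all(!locs$valid[(n - 3):n]))
  if (n > 4) expect_true(locs$valid[n - 4])
})

test_that("a nearby second emitter raises the final-iteration CFR", {
  cfg <- parse_sequence(seq_file)
  cfg$globals$loclimit <- 6
  cfg$iterations[[3]]$ccrLimit <- -1   # record CFR without rejecting
  worse <- 0
  n_trial <- 40
  for (s in seq_len(n_trial)) {
    one <- fl_collection(list(fluorophore(position = c(0, 0, 0), brightness = 0.3)))
    two <- fl_collection(list(fluorophore(position = c(0, 0, 0), brightness = 0.3),
                              fluorophore(position = c(30, 0, 0), brightness = 0.3)))
    l1 <- localize_candidate(c(0, 0), one, cfg, psf_donut2d(150), seed = 100 + s)
    l2 <- localize_candidate(c(0, 0), two, cfg, psf_donut2d(150), seed = 100 + s)
    c1 <- utils::tail(l1$cfr[l1$iteration_id == 3], 1)
    c2 <- utils::tail(l2$cfr[l2$iteration_id == 3], 1)
    if (length(c1) && length(c2) && is.finite(c1) && is.finite(c2) && c2 > c1)
      worse <- worse + 1
  }
  expect_gte(worse / n_trial, 0.9)
})

# Tracking and D_max ----------------------------------------------------------

test_that("static targets are always tracked and faster diffusion is harder", {
  cfg <- parse_sequence(seq_file)
  res0 <- run_tracking(cfg, D = 0, n_tracks = 4, seed = 7)
  expect_equal(res0$success_rate, 1)
  rates <- vapply(c(0.02, 0.2, 1), function(D)
    run_tracking(cfg, D = D, n_tracks = 8, seed = 8)$success_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("D_max interpolates the 50% crossing of the success curve", {
  out <- minfluxsim:::.dmax_from_curve(c(1, 2, 3, 4), c(1.0, 0.75, 0.25, 0.0))
  expect_equal(out$D_max, 2.5)
  expect_false(out$open_ended)
  open <- minfluxsim:::.dmax_from_curve(c(1, 2, 3), c(1, 1, 0.9))
  expect_true(open$open_ended)
  expect_equal(open$D_max, 3)
})

# Imaging ---------------------------------------------------------------------

test_that("imaging an empty scene spends the budget scouting without localizations", {
  cfg <- parse_sequence(system.file("extdata", "imaging_2d.json",
                                    package = "minfluxsim"))
  res <- run_imaging(fl_collection(list()), cfg, fov = 400, time_budget_us = 5e4,
                     scout_pitch = 100, seed = 9)
  expect_identical(res$summary$n_valid, 0L)
  expect_gte(res$n_scout_rounds, 1L)
})

test_that("imaging localizes a bright emitter and reports labeling efficiency", {
  cfg <- parse_sequence(system.file("extdata", "imaging_2d.json",
                                    package = "minfluxsim"))
  scene <- fl_collection(list(fluorophore(position = c(200, 250, 0),
                                          brightness = 0.4)))
  res <- run_imaging(scene, cfg, fov = 400, time_budget_us = 3e5,
                     scout_pitch = 100, seed = 10)
  expect_gt(res$summary$n_valid, 0L)
  expect_equal(res$summary$effective_labeling_efficiency, 1)
})
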