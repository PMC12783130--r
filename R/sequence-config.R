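# Abberior-style sequence files: a JSON (or YAML mirror) object with an
# "itr" list of per-iteration acquisition parameters and a "field" block of
# global parameters. A companion estimator-assignment JSON maps iteration
# indices to estimator registry names, standing in for the proprietary
# on-instrument estimators.

.itr_keys <- c("pattern", "L", "patDwellTime", "patRepeat", "pwrFactor",
               "phtLimit", "ccrLimit", "maxOffTime", "wavelength", "estimator")
.field_keys <- c("algo", "bgcThreshold", "ctrDwellFactor", "damping",
                 "headstart", "id", "loclimit", "stickiness", "fieldGeoFactor")
.pattern_k <- c(triangle = 3L, square = 4L, hexagon = 6L, line = 2L)

#' Parse an Abberior-style sequence file
#'
#' Reads a JSON sequence file (or its annotated YAML mirror, selected by
#' file extension) into a normalized `sequence_config`. Recognized
#' per-iteration keys: `pattern`, `L` (nm), `patDwellTime` (ms, per
#' pattern point), `patRepeat`, `pwrFactor`, `phtLimit`, `ccrLimit`
#' (disabled when `< 0`), `maxOffTime` (ms), `wavelength` (nm). Recognized
#' global (`field`) keys: `algo`, `bgcThreshold` (counts/ms),
#' `ctrDwellFactor`, `damping`, `headstart`, `id`, `loclimit`,
#' `stickiness`, `fieldGeoFactor`. Unrecognized keys are reported with a
#' warning and ignored (tolerant-reader policy). `phtLimit` and
#' `patDwellTime` are required per iteration.
#'
#' Estimator assignments come from a companion JSON
#' (`{"default": name, "itr": [name, ...]}`) or default to `iter_lsq`.
#'
#' @param file path to the sequence file.
#' @param estimators path to the companion estimator-assignment JSON, a
#'   character vector of registry names (recycled), or `NULL`.
#' @return a `sequence_config` list with `id`, `globals`, `dead_times`
#'   (us) and `iterations`.
#' @export
parse_sequence <- function(file, estimators = NULL) {
  ext <- tolower(tools::file_ext(file))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(file)
         else jsonlite::read_json(file, simplifyVector = FALSE)
  itr <- raw$itr
  if (is.null(itr) || !length(itr)) stop("sequence file has no 'itr' list", call. = FALSE)
  field <- raw$field %||% list()
  unknown <- setdiff(names(field), .field_keys)
  for (it in itr) unknown <- union(unknown, setdiff(names(it), .itr_keys))
  unknown <- union(unknown, setdiff(names(raw), c("itr", "field", "id", "deadtimes")))
  if (length(unknown))
    warning(sprintf("ignoring unrecognized sequence key(s): %s",
                    paste(unknown, collapse = ", ")))
  est_names <- NULL
  if (is.character(estimators) && length(estimators) >= 1L && !file.exists(estimators[1L])) {
    est_names <- rep_len(estimators, length(itr))
  } else if (!is.null(estimators)) {
    ej <- jsonlite::read_json(estimators, simplifyVector = TRUE)
    est_names <- rep_len(ej$default %||% "iter_lsq", length(itr))
    if (!is.null(ej$itr)) est_names[seq_along(ej$itr)] <- ej$itr
  }
  iterations <- lapply(seq_along(itr), function(i) {
    it <- itr[[i]]
    for (k in c("phtLimit", "patDwellTime")) {
      if (is.null(it[[k]]))
        stop(sprintf("iteration %d lacks required key '%s'", i, k), call. = FALSE)
    }
    pat <- it$pattern %||% "triangle"
    list(pattern = pat,
         K_o = if (pat %in% names(.pattern_k)) .pattern_k[[pat]] else 3L,
         L = as.numeric(it$L %||% 75),
         patDwellTime = as.numeric(it$patDwellTime),
         patRepeat = as.integer(it$patRepeat %||% 1L),
         pwrFactor = as.numeric(it$pwrFactor %||% 1),
         phtLimit = as.numeric(it$phtLimit),
         ccrLimit = as.numeric(it$ccrLimit %||% -1),
         maxOffTime = as.numeric(it$maxOffTime %||% 3),
         wavelength = as.numeric(it$wavelength %||% 640),
         estimator = (if (!is.null(est_names)) est_names[i]
                      else it$estimator %||% "iter_lsq"))
  })
  dt <- raw$deadtimes %||% list()
  cfg <- list(
    id = raw$id %||% field$id %||% "sequence",
    globals = list(
      algo = field$algo %||% "hexgrid",
      bgcThreshold = as.numeric(field$bgcThreshold %||% 15),
      ctrDwellFactor = as.numeric(field$ctrDwellFactor %||% 1),
      damping = as.numeric(field$damping %||% 0),
      headstart = as.integer(field$headstart %||% 0L),
      loclimit = as.numeric(field$loclimit %||% -1),
      stickiness = as.integer(field$stickiness %||% 4L),
      fieldGeoFactor = as.numeric(field$fieldGeoFactor %||% 1)),
    dead_times = list(
      fast_us = 1000 * as.numeric(dt$fast_ms %||% 0.011),
      estimator_us = 1000 * as.numeric(dt$estimator_ms %||% 0.015),
      slow_us = 1000 * as.numeric(dt$slow_ms %||% 0.04)),
    iterations = iterations)
  class(cfg) <- "sequence_config"
  cfg
}

#' Write a sequence configuration back to file
#'
#' Serializes a `sequence_config` to the JSON dialect read by
#' [parse_sequence()] (or YAML, by extension), such that
#' parse -> write -> parse round-trips to an identical configuration.
#'
#' @param config a `sequence_config`.
#' @param file output path (.json, .yaml or .yml).
#' @return `file`, invisibly.
#' @export
write_sequence <- function(config, file) {
  stopifnot(inherits(config, "sequence_config"))
  g <- config$globals
  out <- list(
    id = config$id,
    field = list(algo = g$algo, bgcThreshold = g$bgcThreshold,
                 ctrDwellFactor = g$ctrDwellFactor, damping = g$damping,
                 headstart = g$headstart, loclimit = g$loclimit,
                 stickiness = g$stickiness, fieldGeoFactor = g$fieldGeoFactor),
    deadtimes = list(fast_ms = config$dead_times$fast_us / 1000,
                     estimator_ms = config$dead_times$estimator_us / 1000,
                     slow_ms = config$dead_times$slow_us / 1000),
    itr = lapply(config$iterations, function(it) {
      it[c("pattern", "L", "patDwellTime", "patRepeat", "pwrFactor",
           "phtLimit", "ccrLimit", "maxOffTime", "wavelength", "estimator")]
    }))
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(out, file)
  else jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @export
print.sequence_config <- function(x, ...) {
  cat(sprintf("<sequence_config> '%s': %d iteration(s), stickiness=%d, bgcThreshold=%g/ms\n",
              x$id, length(x$iterations), x$globals$stickiness, x$globals$bgcThreshold))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("  itr %d: %s L=%g nm dwell=%g ms x%d pht=%g ccr=%g est=%s\n",
                i, it$pattern, it$L, it$patDwellTime, it$patRepeat,
                it$phtLimit, it$ccrLimit, it$estimator))
  }
  invisible(x)
}

# Build the probing pattern of one sequence iteration.
.itr_pattern <- function(it, ctr_dwell_factor = 1) {
  if (it$pattern == "line") {
    define_pattern("line_1d", L = it$L, dwell = it$patDwellTime * 1000,
                   r = it$patRepeat, center_probed = TRUE,
                   ctr_dwell_factor = ctr_dwell_factor)
  } else {
    define_pattern("orbit", L = it$L, K_o = it$K_o,
                   dwell = it$patDwellTime * 1000, r = it$patRepeat,
                   center_probed = TRUE, ctr_dwell_factor = ctr_dwell_factor)
  }
}

#' Hexagonal scouting grid
#'
#' Probe centers for the coarse scouting scan that searches for candidate
#' fluorophores: a hexagonal lattice with nearest-neighbor distance
#' `pitch` covering the box `[0, fov_x] x [0, fov_y]`, ordered row-major
#' with serpentine (boustrophedon) traversal. A field of view smaller than
#' the pitch yields the single center point.
#'
#' @param fov field of view: scalar (square) or `c(width, height)` (nm).
#' @param pitch lattice constant (nm), `> 0`.
#' @return matrix of probe centers (n x 2, nm).
#' @export
make_scouting_pattern <- function(fov, pitch) {
  .assert_scalar_pos(pitch, "pitch")
  fov <- rep(as.numeric(fov), length.out = 2L)
  if (all(fov < pitch)) return(matrix(fov / 2, 1L, 2L))
  dy <- pitch * sqrt(3) / 2
  ys <- seq(0, fov[2L], by = dy)
  pts <- list()
  for (j in seq_along(ys)) {
    x0 <- if (j %% 2L == 0L) pitch / 2 else 0
    xs <- seq(x0, fov[1L], by = pitch)
    if (j %% 2L == 0L) xs <- rev(xs)      # serpentine
    pts[[j]] <- cbind(xs, ys[j])
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Center-frequency ratio of a measurement record
#'
#' The CFR is the photon count collected at the pattern center divided by
#' the mean count over the orbit points. Values near the configured
#' `ccrLimit` or above flag background, nearby active fluorophores or a
#' large offset between fluorophore and pattern center; the quality check
#' fails when `cfr > ccrLimit`.
#'
#' @param record a `measurement_record` (or a raw count vector with
#'   `center_index` supplied).
#' @param center_index index of the center probe point.
#' @return the CFR (0 when the center count is 0; `Inf` when the orbit
#'   mean is 0).
#' @export
compute_cfr <- function(record, center_index = NULL) {
  counts <- if (inherits(record, "measurement_record")) record$counts else record
  ci <- center_index %||%
    (if (inherits(record, "measurement_record")) record$center_index else NULL)
  if (is.null(ci) || is.na(ci))
    stop("pattern did not probe its center; CFR undefined", call. = FALSE)
  orbit <- counts[-ci]
  if (mean(orbit) == 0) return(Inf)
  counts[ci] / mean(orbit)
}
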