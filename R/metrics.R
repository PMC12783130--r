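#' Numerical Cramer-Rao bound for a pattern scan
#'
#' Computes the information-theoretic lower bound on the localization
#' standard deviation for a given pattern, effective PSF, fluorophore
#' position, photon count and background. The measurement probabilities
#' `p_i(x)` are differentiated by central finite differences
#' (`x +- eps/2` per axis), the Fisher information matrix is
#' `F_ab = N sum_i (dp_i/da)(dp_i/db) / p_i`, and the per-axis bound is
#' `sigma_a = sqrt((F^-1)_aa)`. Because the probabilities come from the
#' full simulation model, the bound automatically reflects background,
#' aberrated or misaligned PSFs and (via `scene_bg`) nearby fluorophores.
#'
#' @param pattern an [define_pattern()] pattern.
#' @param psf a `psf` object.
#' @param x evaluation position, pattern frame (nm).
#' @param N total photon count.
#' @param bg dimensionless background (see [expected_counts()]).
#' @param eps finite-difference step (nm); halving it should change the
#'   result by well under 0.1 % (Richardson check).
#' @param axes axes to include (subset of 1:2 for lateral patterns).
#' @return named vector `sigma_crb` per axis (nm, `Inf` for a singular
#'   Fisher matrix), with the Fisher matrix as attribute `fisher`.
#' @export
compute_crb <- function(pattern, psf, x = c(0, 0, 0), N = 500, bg = 0,
                        eps = 0.5, axes = 1:2) {
  .assert_scalar_pos(eps, "eps")
  x <- .as_pos3(x)
  p0 <- expected_counts(pattern, psf, x, bg = bg)$p
  p0 <- pmax(p0, 1e-12)
  d <- matrix(0, pattern$K, length(axes))
  for (j in seq_along(axes)) {
    h <- c(0, 0, 0); h[axes[j]] <- eps / 2
    pp <- expected_counts(pattern, psf, x + h, bg = bg)$p
    pm <- expected_counts(pattern, psf, x - h, bg = bg)$p
    d[, j] <- (pp - pm) / eps
  }
  FI <- N * crossprod(d / sqrt(p0))
  out <- rep(Inf, length(axes))
  ok <- is.finite(det(FI)) && det(FI) > 1e-300
  if (ok) {
    inv <- tryCatch(solve(FI), error = function(e) NULL)
    if (!is.null(inv)) out <- sqrt(pmax(diag(inv), 0))
  }
  names(out) <- c("x", "y", "z")[axes]
  attr(out, "fisher") <- FI
  out
}

#' Localization error summary: RMSE, STD and bias
#'
#' Per-axis error decomposition over paired estimates and truths:
#' `bias = mean(xhat - x)`, `STD = sqrt(mean((xhat - x - bias)^2))` and
#' `RMSE = sqrt(mean((xhat - x)^2))`, so that `RMSE^2 = STD^2 + bias^2`
#' holds as an algebraic identity on the same sample (population
#' normalization `1/Q` throughout).
#'
#' @param estimates Q x d matrix (or vector) of estimated positions (nm).
#' @param truths matching matrix/vector of true positions (nm).
#' @return a `performance_summary` list with per-axis `rmse`, `std`,
#'   `bias`, and `q` (sample count). Rows with non-finite estimates are
#'   dropped (count reported as `q_dropped`).
#' @export
compute_errors <- function(estimates, truths) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1L)
  if (is.null(dim(truths))) truths <- matrix(truths, ncol = 1L)
  if (nrow(truths) == 1L && nrow(estimates) > 1L)
    truths <- truths[rep(1L, nrow(estimates)), , drop = FALSE]
  stopifnot(nrow(estimates) == nrow(truths))
  err <- as.matrix(estimates) - as.matrix(truths[, seq_len(ncol(estimates)), drop = FALSE])
  keep <- apply(is.finite(err), 1L, all)
  err <- err[keep, , drop = FALSE]
  Q <- nrow(err)
  if (Q < 1L) stop("no valid estimate/truth pairs", call. = FALSE)
  bias <- colMeans(err)
  std <- sqrt(colMeans(sweep(err, 2L, bias)^2))
  rmse <- sqrt(colMeans(err^2))
  structure(list(rmse = rmse, std = std, bias = bias, q = Q,
                 q_dropped = sum(!keep)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> Q=%d%s\n", x$q,
              if (x$q_dropped > 0) sprintf(" (+%d dropped)", x$q_dropped) else ""))
  m <- rbind(rmse = x$rmse, std = x$std, bias = x$bias)
  print(round(m, 3))
  invisible(x)
}

#' Flicker-induced excess localization error
#'
#' Fluorophore flickering during a pattern scan violates the
#' constant-brightness assumption and adds an error component that is
#' independent of the photon count: `STD(r, N)^2 = sigma_fl(r)^2 +
#' sigma_CRB(N)^2`. This helper inverts that decomposition:
#' `sigma_fl = sqrt(max(STD^2 - sigma_CRB^2, 0))`, with a `clipped`
#' attribute when the measured STD fell below the bound.
#'
#' @param std_measured measured localization STD (nm).
#' @param sigma_crb CRB standard deviation at the same photon count (nm).
#' @return `sigma_fl` (nm) with attribute `clipped`.
#' @export
flicker_excess <- function(std_measured, sigma_crb) {
  stopifnot(all(std_measured >= 0), all(sigma_crb >= 0))
  d <- std_measured^2 - sigma_crb^2
  out <- sqrt(pmax(d, 0))
  attr(out, "clipped") <- any(d < 0)
  out
}

#' Mean square displacement and diffusion coefficient fit
#'
#' Computes the time-averaged MSD of a track over lag times and estimates
#' the diffusion coefficient from a linear fit `MSD(tau) = 2 d D tau + c`
#' over the configured lags. Lag 1 is excluded by default because it is
#' dominated by localization noise in measured tracks; the full curve is
#' returned so its nonlinearity (a hallmark of feedback-limited tracking)
#' can be inspected.
#'
#' @param track an `fl_track` or a matrix/data.frame with columns x, y (nm)
#'   sampled at a constant interval.
#' @param dt sampling interval (us); inferred from an `fl_track`.
#' @param max_lag largest lag (samples).
#' @param fit_lags lags used in the linear fit (samples).
#' @param dims dimensionality d of the motion.
#' @return list with `D_est` (um^2/s), `msd` data.frame (`tau_us`,
#'   `msd_nm2`) and `fit`.
#' @export
msd_fit <- function(track, dt = NULL, max_lag = 20, fit_lags = 2:5, dims = 2) {
  if (inherits(track, "fl_track")) {
    dt <- dt %||% attr(track, "dt_us")
    pos <- as.matrix(track[, c("x", "y", "z")])[, seq_len(dims), drop = FALSE]
  } else {
    pos <- as.matrix(track)[, seq_len(dims), drop = FALSE]
  }
  if (is.null(dt)) stop("dt must be supplied for plain matrices", call. = FALSE)
  n <- nrow(pos)
  if (n <= max(3L, max_lag)) stop("track shorter than the requested lags", call. = FALSE)
  lags <- seq_len(min(max_lag, n - 1L))
  msd <- vapply(lags, function(l) {
    d <- pos[(l + 1L):n, , drop = FALSE] - pos[1L:(n - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  fit_lags <- fit_lags[fit_lags <= max(lags)]
  fit <- stats::lm(msd[fit_lags] ~ I(lags[fit_lags] * dt))
  slope <- stats::coef(fit)[[2L]]          # nm^2 per us
  D_est <- max(slope / (2 * dims), 0)      # nm^2/us == um^2/s
  list(D_est = D_est,
       msd = data.frame(tau_us = c(0, lags * dt), msd_nm2 = c(0, msd)),
       fit = fit)
}

#' Localization performance report
#'
#' Joins a localization table (as produced by [run_sequence()],
#' [run_imaging()] or [run_tracking()]) to ground truth, computes the
#' error summary over the valid localizations and optionally writes the
#' per-localization CSV, a summary JSON and a 2D histogram image.
#'
#' @param localizations data.frame with `est_x_nm`, `est_y_nm`,
#'   `true_x_nm`, `true_y_nm`, `N_photons`, `valid`.
#' @param sigma_crb optional CRB (nm) to include and decompose against.
#' @param csv,json,png optional output paths.
#' @param binwidth_nm histogram bin width for the rendered image.
#' @return a `performance_summary` extended with `sigma_crb`, `sigma_fl`,
#'   `mean_photons`, `n_valid`, `n_invalid`.
#' @export
localization_report <- function(localizations, sigma_crb = NULL,
                                csv = NULL, json = NULL, png = NULL,
                                binwidth_nm = 2) {
  loc <- localizations
  ok <- loc$valid & is.finite(loc$est_x_nm) & is.finite(loc$true_x_nm)
  if (!any(ok)) stop("no valid localizations to summarize", call. = FALSE)
  s <- compute_errors(cbind(loc$est_x_nm[ok], loc$est_y_nm[ok]),
                      cbind(loc$true_x_nm[ok], loc$true_y_nm[ok]))
  s$mean_photons <- mean(loc$N_photons[ok])
  s$n_valid <- sum(loc$valid)
  s$n_invalid <- sum(!loc$valid)
  if (!is.null(sigma_crb)) {
    s$sigma_crb <- sigma_crb
    s$sigma_fl <- flicker_excess(s$std[seq_along(sigma_crb)], sigma_crb)
  }
  if (!is.null(csv)) write.csv(loc, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(rmse_nm = s$rmse, std_nm = s$std, bias_nm = s$bias,
                              sigma_crb_nm = s$sigma_crb, sigma_fl_nm = s$sigma_fl,
                              q = s$q, mean_photons = s$mean_photons,
                              n_valid = s$n_valid, n_invalid = s$n_invalid),
                         json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(png)) {
    grDevices::png(png, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    xs <- loc$est_x_nm[ok]; ys <- loc$est_y_nm[ok]
    bx <- seq(min(xs) - binwidth_nm, max(xs) + binwidth_nm, by = binwidth_nm)
    by <- seq(min(ys) - binwidth_nm, max(ys) + binwidth_nm, by = binwidth_nm)
    h <- table(cut(xs, bx), cut(ys, by))
    graphics::image(bx[-1L], by[-1L], unclass(h), xlab = "x (nm)", ylab = "y (nm)",
                    main = "localization histogram", useRaster = TRUE)
  }
  s
}
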