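#' Background subtraction for photon counts
#'
#' Subtracts the expected background counts per pattern point from the
#' measured counts so that downstream estimators can use the
#' background-free count model. Negative adjusted counts are floored at 0
#' (flagged in the `floored` attribute) to keep the derived probabilities
#' valid.
#'
#' @param counts per-point photon counts.
#' @param bg_counts expected background counts per point (scalar or
#'   per-point vector), `>= 0`.
#' @return adjusted counts with attribute `floored`.
#' @examples
#' subtract_background(c(10, 10, 10), 4)   # 6 6 6
#' @export
subtract_background <- function(counts, bg_counts) {
  if (any(bg_counts < 0)) stop("bg_counts must be >= 0", call. = FALSE)
  adj <- counts - bg_counts
  floored <- adj < 0
  adj[floored] <- 0
  attr(adj, "floored") <- any(floored)
  adj
}

# Normalize raw counts to probabilities; returns NULL for a zero total.
.phat <- function(counts) {
  N <- sum(counts)
  if (N <= 0) return(NULL)
  counts / N
}

.new_estimate <- function(x_est, ...) {
  x_est <- .as_pos3(x_est)
  structure(c(list(x_est = x_est), list(...)), class = "position_estimate")
}

#' Linearized least-squares estimators
#'
#' Closed-form first-order least-squares position estimators obtained by
#' linearizing the measurement probabilities `p_i(x)` around `x = 0`. With
#' `L_sigma^2 = L^2 / (8 sigma^2)`:
#' \itemize{
#'   \item donut model: `x_est = 1/(L_sigma^2 - 1) * sum p_i b_i`;
#'   \item quadratic model: `x_est = -sum p_i b_i` (parameter free);
#'   \item Gaussian model: `x_est = 1/L_sigma^2 * sum p_i b_i` without a
#'     center probe and
#'     `x_est = (K_o + exp(L_sigma^2)) / (K_o L_sigma^2) * sum p_i b_i`
#'     with one.
#' }
#' These estimators are exact at the pattern center and increasingly
#' biased away from it; see [est_iterative_lsq()] for the extended-range
#' variant.
#'
#' @param p_hat measured probabilities (`counts / sum(counts)`), one per
#'   pattern point.
#' @param offsets K x 2/3 matrix of probe offsets `b_i` (nm); or pass a
#'   `pattern`.
#' @param L orbit diameter (nm).
#' @param sigma PSF length scale (nm).
#' @param center_probed does the last point probe the pattern center
#'   (Gaussian estimator only)?
#' @param K_o number of orbit points (Gaussian with center).
#' @return a `position_estimate` with field `x_est` (pattern-center frame).
#' @export
est_lsq_donut <- function(p_hat, offsets, L, sigma) {
  offsets <- .as_pos3_mat(offsets)
  Ls2 <- L^2 / (8 * sigma^2)
  if (abs(Ls2 - 1) < 1e-12)
    stop("singular configuration: L^2/(8 sigma^2) = 1", call. = FALSE)
  .new_estimate(colSums(p_hat * offsets) / (Ls2 - 1))
}

#' @rdname est_lsq_donut
#' @export
est_lsq_quadratic <- function(p_hat, offsets) {
  offsets <- .as_pos3_mat(offsets)
  .new_estimate(-colSums(p_hat * offsets))
}

#' @rdname est_lsq_donut
#' @export
est_lsq_gauss <- function(p_hat, offsets, L, sigma, center_probed = FALSE,
                          K_o = if (center_probed) length(p_hat) - 1L else length(p_hat)) {
  offsets <- .as_pos3_mat(offsets)
  Ls2 <- L^2 / (8 * sigma^2)
  if (Ls2 == 0) stop("singular configuration: L_sigma^2 = 0", call. = FALSE)
  s <- colSums(p_hat * offsets)
  if (center_probed) {
    .new_estimate((K_o + exp(Ls2)) / (K_o * Ls2) * s)
  } else {
    .new_estimate(s / Ls2)
  }
}

# Model probabilities p(x) and their Jacobian (K x 2) for the analytic
# models. The Jacobian has the closed form
#   dp_i/dx = (grad f_i * S - f_i * sum_j grad f_j) / S^2,  S = sum_j f_j,
# valid for any probe offset set.
.model_p <- function(model, x, offsets, sigma) {
  rel <- sweep(-offsets, 2L, .as_pos3(x), "+")
  f <- switch(model,
    donut = eval_donut2d(rel, sigma),
    quadratic = eval_quadratic(rel, sigma),
    gaussian = eval_gauss2d(rel, sigma))
  S <- sum(f)
  list(f = f, S = S, p = if (S > 0) f / S else rep(NA_real_, length(f)))
}

.model_jacobian <- function(model, x, offsets, sigma) {
  rel <- sweep(-offsets, 2L, .as_pos3(x), "+")
  f <- switch(model,
    donut = eval_donut2d(rel, sigma),
    quadratic = eval_quadratic(rel, sigma),
    gaussian = eval_gauss2d(rel, sigma))
  g <- switch(model,
    donut = .grad_donut2d(rel, sigma),
    quadratic = .grad_quadratic(rel, sigma),
    gaussian = .grad_gauss2d(rel, sigma))
  S <- sum(f)
  gs <- colSums(g)
  (g * S - outer(f, gs)) / S^2
}

#' Iterative least-squares estimator
#'
#' Extends the linearized least-squares estimators to a larger field of
#' view by re-linearizing the probability model around the current
#' estimate: each iteration computes the Jacobian `J` of `p(x)` at `x0`
#' and updates `x0 <- x0 + (J^T J)^-1 J^T (p_hat - p(x0))`. Starting from
#' `x0 = 0`, the first iteration reproduces the corresponding linearized
#' estimator exactly; convergence typically takes a handful of iterations.
#' Iterates are clamped to `|x| <= clamp_radius` (default `L`), beyond
#' which the model linearization is meaningless.
#'
#' @inheritParams est_lsq_donut
#' @param spec list with `model` (`"donut"`, `"quadratic"`, `"gaussian"`),
#'   `L`, `sigma`, and optionally `max_iterations` (default 30),
#'   `tolerance` (nm, default 0.1), `clamp_radius` (default `L`).
#' @return a `position_estimate` with `iterations_used`, `converged`,
#'   `clamped`.
#' @export
est_iterative_lsq <- function(p_hat, offsets, spec) {
  offsets <- .as_pos3_mat(offsets)
  model <- spec$model %||% "donut"
  sigma <- spec$sigma %||% 150
  maxit <- spec$max_iterations %||% 30L
  tol <- spec$tolerance %||% 0.1
  clamp <- spec$clamp_radius %||% spec$L
  x0 <- c(0, 0)
  converged <- FALSE
  clamped <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mp <- .model_p(model, c(x0, 0), offsets, sigma)
    J <- .model_jacobian(model, c(x0, 0), offsets, sigma)
    JtJ <- crossprod(J)
    if (!all(is.finite(JtJ)) || abs(det(JtJ)) < 1e-30) {
      return(.new_estimate(c(x0, 0), iterations_used = it, converged = FALSE,
                           clamped = clamped))
    }
    dx <- solve(JtJ, crossprod(J, p_hat - mp$p))[, 1L]
    x0 <- x0 + dx
    nrm <- sqrt(sum(x0^2))
    if (is.finite(clamp) && nrm > clamp) {
      x0 <- x0 * clamp / nrm
      clamped <- TRUE
    }
    if (sqrt(sum(dx^2)) < tol) { converged <- TRUE; break }
  }
  .new_estimate(c(x0, 0), iterations_used = it, converged = converged,
                clamped = clamped)
}

#' 1D maximum-likelihood estimator for the quadratic PSF
#'
#' For probing points at `-L/2` and `+L/2` the likelihood under the
#' quadratic count model has two stationary solutions,
#' `x1 = (L/2) (sqrt(n1) - sqrt(n2)) / (sqrt(n1) + sqrt(n2))` (inside the
#' pattern) and its reciprocal companion
#' `x2 = (L/2) (sqrt(n1) + sqrt(n2)) / (sqrt(n1) - sqrt(n2))` (outside).
#' When a center count `n0` is available the multinomial likelihood of the
#' three counts under the quadratic model decides between the two roots;
#' without it the bounded root `x1` is returned.
#'
#' @param n_hat counts `c(n1, n2)` at `-L/2, +L/2`, optionally `c(n0, n1,
#'   n2)` when `center = TRUE`.
#' @param L probe separation (nm).
#' @param center is a center count included (first element)?
#' @return a `position_estimate` with `root_used`.
#' @export
est_mle_quad_1d <- function(n_hat, L, center = length(n_hat) == 3L) {
  if (center) { n0 <- n_hat[1L]; n1 <- n_hat[2L]; n2 <- n_hat[3L] }
  else { n0 <- NULL; n1 <- n_hat[1L]; n2 <- n_hat[2L] }
  if (n1 + n2 <= 0) stop("n1 + n2 must be positive", call. = FALSE)
  s1 <- sqrt(n1); s2 <- sqrt(n2)
  x1 <- L / 2 * (s1 - s2) / (s1 + s2)
  if (s1 == s2) return(.new_estimate(c(0, 0, 0), root_used = 1L))
  x2 <- L / 2 * (s1 + s2) / (s1 - s2)
  if (is.null(n0)) return(.new_estimate(c(x1, 0, 0), root_used = 1L))
  loglik <- function(x) {
    f <- c(x^2, (x + L / 2)^2, (x - L / 2)^2)
    p <- f / sum(f)
    p[p <= 0] <- 1e-300
    sum(c(n0, n1, n2) * log(p))
  }
  if (loglik(x2) > loglik(x1)) .new_estimate(c(x2, 0, 0), root_used = 2L)
  else .new_estimate(c(x1, 0, 0), root_used = 1L)
}

#' Direct 1D estimator with background as a free parameter
#'
#' With three probing points at `0, -L/2, +L/2` the quadratic count model
#' with unknown position, brightness and flat background can be solved
#' exactly:
#' `x_est = (L/4) (n2 - n1) / (2 n0 - n1 - n2)`.
#' A uniform count offset cancels, which is precisely the background
#' invariance this estimator is built for. Brightness and background are
#' back-solved from the same equations and returned.
#'
#' @param n_hat counts `c(n0, n1, n2)` at probes `0, -L/2, +L/2`.
#' @param L probe separation (nm).
#' @param sigma PSF length scale used to convert the fitted quadratic
#'   coefficients to `I0` / dimensionless `bg` (optional).
#' @return a `position_estimate` with `I0_est`, `bg_est` and `valid`.
#' @export
est_direct_bg_1d <- function(n_hat, L, sigma = 150) {
  stopifnot(length(n_hat) == 3L)
  n0 <- n_hat[1L]; n1 <- n_hat[2L]; n2 <- n_hat[3L]
  den <- 2 * n0 - n1 - n2
  if (den == 0) {
    return(.new_estimate(c(NA_real_, 0, 0), I0_est = NA_real_,
                         bg_est = NA_real_, valid = FALSE))
  }
  x <- L / 4 * (n2 - n1) / den
  # n_i = a ((x - b_i)^2 + B): a from the curvature, B from the center count
  a <- -2 * den / L^2
  B <- if (a != 0) n0 / a - x^2 else NA_real_
  c_quad <- 1 / (4 * pi * sigma^4)
  .new_estimate(c(x, 0, 0), I0_est = a / c_quad, bg_est = B * c_quad,
                valid = TRUE)
}

# ---------------------------------------------------------------------------

.estimator_registry <- new.env(parent = emptyenv())

.register_estimators <- function() {
  reg <- .estimator_registry
  reg$lsq_donut <- function(spec) function(counts, pattern) {
    p <- .phat(subtract_background(counts, spec$bg_counts %||% 0))
    if (is.null(p)) return(.new_estimate(c(NA, NA, NA)))
    est_lsq_donut(p, pattern$offsets, spec$L %||% pattern$L, spec$sigma %||% 150)
  }
  reg$lsq_quadratic <- function(spec) function(counts, pattern) {
    p <- .phat(subtract_background(counts, spec$bg_counts %||% 0))
    if (is.null(p)) return(.new_estimate(c(NA, NA, NA)))
    est_lsq_quadratic(p, pattern$offsets)
  }
  reg$lsq_gauss <- function(spec) function(counts, pattern) {
    p <- .phat(counts)
    if (is.null(p)) return(.new_estimate(c(NA, NA, NA)))
    est_lsq_gauss(p, pattern$offsets, spec$L %||% pattern$L,
                  spec$sigma %||% 150, pattern$center_probed, pattern$K_o)
  }
  reg$iter_lsq <- function(spec) function(counts, pattern) {
    p <- .phat(subtract_background(counts, spec$bg_counts %||% 0))
    if (is.null(p)) return(.new_estimate(c(NA, NA, NA)))
    spec$L <- spec$L %||% pattern$L
    est_iterative_lsq(p, pattern$offsets, spec)
  }
  # 1D estimators expect counts ordered (n0, n1, n2); line patterns store
  # the center probe last, so reorder when present.
  reg$mle_quad_1d <- function(spec) function(counts, pattern) {
    if (isTRUE(pattern$center_probed)) counts <- counts[c(3L, 1L, 2L)]
    est_mle_quad_1d(counts, spec$L %||% pattern$L)
  }
  reg$direct_bg_1d <- function(spec) function(counts, pattern) {
    if (isTRUE(pattern$center_probed)) counts <- counts[c(3L, 1L, 2L)]
    est_direct_bg_1d(counts, spec$L %||% pattern$L, spec$sigma %||% 150)
  }
}

#' Estimator registry
#'
#' Returns a configured estimator function `function(counts, pattern)` by
#' registry name; these names are also what sequence estimator-assignment
#' files refer to. Registered: `lsq_donut`, `lsq_quadratic`, `lsq_gauss`,
#' `iter_lsq`, `mle_quad_1d`, `direct_bg_1d`.
#'
#' @param name registry name.
#' @param spec estimator parameters (`model`, `L`, `sigma`, `bg_counts`,
#'   `max_iterations`, `tolerance`, ... as applicable).
#' @return a function `(counts, pattern) -> position_estimate`.
#' @export
select_estimator <- function(name, spec = list()) {
  if (!length(ls(.estimator_registry))) .register_estimators()
  f <- get0(name, envir = .estimator_registry)
  if (is.null(f))
    stop(sprintf("unknown estimator '%s'; registered: %s", name,
                 paste(sort(ls(.estimator_registry)), collapse = ", ")),
         call. = FALSE)
  f(spec)
}
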