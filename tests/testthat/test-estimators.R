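# Background subtraction -----------------------------------------------------

test_that("background subtraction is exact, floored and flagged", {
  expect_equal(as.numeric(subtract_background(c(10, 10, 10), 0)), c(10, 10, 10))
  expect_equal(as.numeric(subtract_background(c(10, 10, 10), 4)), c(6, 6, 6))
  adj <- subtract_background(c(2, 10, 10), 4)
  expect_equal(as.numeric(adj), c(0, 6, 6))
  expect_true(attr(adj, "floored"))
  expect_error(subtract_background(c(1, 2), -1), "bg")
})

# Linearized estimators -------------------------------------------------------

test_that("the linearized donut estimator inverts the forward model near the center", {
  pat <- pat_orbit(L = 50, K_o = 4)
  psf <- psf_donut2d(100)
  # symmetric probabilities map to the origin
  e0 <- est_lsq_donut(rep(0.25, 4), pat$offsets, 50, 100)
  expect_equal(e0$x_est, c(0, 0, 0), tolerance = 1e-12)
  # noiseless model inversion at small offset
  p <- model_p(pat, psf, c(2, 0, 0))
  e <- est_lsq_donut(p, pat$offsets, 50, 100)
  expect_equal(e$x_est[1:2], c(2, 0), tolerance = 0.1)
  # linearity: doubling (p - 1/K) doubles the estimate
  dp <- p - 0.25
  e2 <- est_lsq_donut(0.25 + 2 * dp, pat$offsets, 50, 100)
  expect_equal(e2$x_est, 2 * e$x_est, tolerance = 1e-9)
  # singular configuration L_sigma^2 = 1
  expect_error(est_lsq_donut(p, pat$offsets, sqrt(8) * 100, 100), "singular")
})

test_that("the quadratic estimator is parameter-free", {
  pat <- pat_orbit(L = 60, K_o = 3)
  expect_equal(est_lsq_quadratic(rep(1 / 3, 3), pat$offsets)$x_est, c(0, 0, 0))
  e <- est_lsq_quadratic(c(1, 0, 0), pat$offsets)
  expect_equal(e$x_est, -pat$offsets[1, ], tolerance = 1e-12)
})

test_that("the gaussian estimators recover small offsets with and without center", {
  psf <- psf_gauss2d(150)
  pat <- pat_orbit(L = 100, K_o = 6)
  expect_equal(est_lsq_gauss(rep(1 / 6, 6), pat$offsets, 100, 150)$x_est, c(0, 0, 0))
  patc <- define_pattern("orbit", L = 100, K_o = 6, dwell = 1, center_probed = TRUE)
  expect_equal(est_lsq_gauss(rep(1 / 7, 7), patc$offsets, 100, 150,
                             center_probed = TRUE, K_o = 6)$x_est, c(0, 0, 0))
  for (x1 in c(3, 6, 10)) {
    p <- model_p(pat, psf, c(x1, 0, 0))
    e <- est_lsq_gauss(p, pat$offsets, 100, 150)
    expect_equal(e$x_est[1], x1, tolerance = 0.01 * x1 + 0.02)
    pc <- model_p(patc, psf, c(x1, 0, 0))
    ec <- est_lsq_gauss(pc, patc$offsets, 100, 150, center_probed = TRUE, K_o = 6)
    expect_equal(ec$x_est[1], x1, tolerance = 0.02 * x1 + 0.02)
  }
  # with-center prefactor dominates for large L_sigma^2
  Ls2 <- 3
  L <- sqrt(8 * Ls2) * 150
  pre_nc <- 1 / Ls2
  pre_c <- (6 + exp(Ls2)) / (6 * Ls2)
  expect_gt(pre_c, 3 * pre_nc)
})

# Iterative estimator ---------------------------------------------------------

test_that("one iteration from the origin reproduces each linearized estimator", {
  set.seed(10)
  for (model in c("donut", "quadratic", "gaussian")) {
    pat <- pat_orbit(L = 60, K_o = 4)
    p <- runif(4); p <- p / sum(p)
    spec <- list(model = model, L = 60, sigma = 120,
                 max_iterations = 1, tolerance = 1e-12, clamp_radius = Inf)
    it <- est_iterative_lsq(p, pat$offsets, spec)
    lin <- switch(model,
      donut = est_lsq_donut(p, pat$offsets, 60, 120),
      quadratic = est_lsq_quadratic(p, pat$offsets),
      gaussian = est_lsq_gauss(p, pat$offsets, 60, 120))
    expect_equal(it$x_est, lin$x_est, tolerance = 1e-8)
  }
})

test_that("the iterative estimator converges to the true position on noiseless input", {
  psf <- psf_donut2d(100)
  pat <- pat_orbit(L = 50, K_o = 4)
  p <- model_p(pat, psf, c(15, 0, 0))
  e <- est_iterative_lsq(p, pat$offsets, list(model = "donut", L = 50, sigma = 100))
  expect_true(e$converged)
  expect_equal(e$x_est[1:2], c(15, 0), tolerance = 0.1)
  # contraction over a grid |x| <= L/2, <= 10 iterations
  for (x1 in seq(-25, 25, by = 5)) {
    p <- model_p(pat, psf, c(x1, 7, 0))
    e <- est_iterative_lsq(p, pat$offsets,
                           list(model = "donut", L = 50, sigma = 100,
                                max_iterations = 10, tolerance = 0.1))
    expect_true(e$converged)
    expect_equal(e$x_est[1], x1, tolerance = 0.2)
  }
})

test_that("iterative LSQ has lower bias than linearized LSQ across the field of view", {
  psf <- psf_donut2d(150)
  pat <- pat_orbit(L = 75, K_o = 4)
  for (x1 in seq(-37.5, 37.5, length.out = 11)) {
    p <- model_p(pat, psf, c(x1, 0, 0))
    lin <- est_lsq_donut(p, pat$offsets, 75, 150)$x_est[1]
    it <- est_iterative_lsq(p, pat$offsets,
                            list(model = "donut", L = 75, sigma = 150))$x_est[1]
    expect_lte(abs(it - x1), abs(lin - x1) + 1e-6)
  }
})

# 1D estimators ---------------------------------------------------------------

test_that("the 1D MLE returns the bounded root and resolves ambiguity via the center", {
  expect_equal(est_mle_quad_1d(c(100, 100), L = 80)$x_est[1], 0)
  expect_equal(est_mle_quad_1d(c(100, 0), L = 80)$x_est[1], 40)
  # likelihood-based root selection with a center count
  set.seed(11)
  L <- 75
  x_true <- -10
  f <- c(x_true^2, (x_true + L / 2)^2, (x_true - L / 2)^2)
  p <- f / sum(f)
  n <- as.numeric(stats::rmultinom(1, 1e4, p))
  e <- est_mle_quad_1d(n, L = L)
  expect_equal(e$x_est[1], x_true, tolerance = 1)
})

test_that("the K = 2 direct solution coincides with the MLE root", {
  # solving p_hat = p(b_i) for the quadratic model numerically must give Eq.-14
  set.seed(12)
  L <- 100
  for (i in 1:100) {
    n <- c(rpois(1, runif(1, 10, 500)) + 1, rpois(1, runif(1, 10, 500)) + 1)
    phat1 <- n[1] / sum(n)
    g <- function(x) (x + L / 2)^2 / ((x + L / 2)^2 + (x - L / 2)^2) - phat1
    direct <- stats::uniroot(g, lower = -L / 2 + 1e-9, upper = L / 2 - 1e-9,
                             tol = 1e-12)$root
    mle <- est_mle_quad_1d(n, L = L)$x_est[1]
    expect_equal(direct, mle, tolerance = 1e-6)
  }
})

test_that("the direct background-fitting estimator is exact and offset invariant", {
  e <- est_direct_bg_1d(c(300, 100, 200), L = 100)
  expect_equal(e$x_est[1], 25 * 100 / 300, tolerance = 1e-12)
  expect_equal(est_direct_bg_1d(c(50, 80, 80), L = 100)$x_est[1], 0)
  # adding a constant to all counts cancels
  e2 <- est_direct_bg_1d(c(300, 100, 200) + 57, L = 100)
  expect_equal(e2$x_est[1], e$x_est[1], tolerance = 1e-12)
  # indistinguishable from flat background
  flat <- est_direct_bg_1d(c(100, 100, 100), L = 100)
  expect_false(flat$valid)
  # back-solved brightness/background reproduce a constructed model
  L <- 100; sigma <- 150
  x <- 12; I0 <- 4e5; bg <- 3e-5
  cq <- 1 / (4 * pi * sigma^4)
  n <- I0 * (cq * c(x^2, (x + L / 2)^2, (x - L / 2)^2) + bg)
  eb <- est_direct_bg_1d(n, L = L, sigma = sigma)
  expect_equal(eb$x_est[1], x, tolerance = 1e-9)
  expect_equal(eb$I0_est, I0, tolerance = 1e-6)
  expect_equal(eb$bg_est, bg, tolerance = 1e-6)
})

test_that("background biases the LSQ estimator; subtraction and fitting remove it", {
  # 200 signal + 200 background photons; emitter off-center so the flat
  # background pulls the linearized estimate toward the pattern center
  set.seed(13)
  L <- 75
  x_true <- 10
  pat <- define_pattern("line_1d", L = L, dwell = 100, center_probed = TRUE)
  psf <- psf_quadratic2d(150)
  ec <- expected_counts(pat, psf, c(x_true, 0, 0), bg = 0)
  # background-free value of the linearized quadratic estimator at x_true
  # (the linearization itself is biased off-center; background adds to that)
  e0 <- est_lsq_quadratic(ec$p, pat$offsets)$x_est[1]
  n_rep <- 3000
  sig_mu <- 200 * ec$p
  bg_per_point <- 200 / 3
  est_raw <- est_sub <- est_fit <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    n <- rpois(3, sig_mu) + rpois(3, bg_per_point)
    est_raw[i] <- est_lsq_quadratic(n / sum(n), pat$offsets)$x_est[1]
    adj <- subtract_background(n, bg_per_point)
    est_sub[i] <- est_lsq_quadratic(adj / max(sum(adj), 1), pat$offsets)$x_est[1]
    est_fit[i] <- est_direct_bg_1d(n[c(3, 1, 2)], L = L)$x_est[1]
  }
  se <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  # uncorrected estimator is pulled well away from its background-free value
  expect_lt(mean(est_raw) + 4 * se(est_raw), e0)
  # exact background subtraction restores the background-free estimator
  expect_lt(abs(mean(est_sub) - e0), 4 * se(est_sub) + 0.5)
  # fitting the background recovers the true position itself
  est_fit <- est_fit[is.finite(est_fit) & abs(est_fit) < L]
  expect_lt(abs(mean(est_fit) - x_true), 4 * se(est_fit) + 0.5)
})

# Registry --------------------------------------------------------------------

test_that("the estimator registry binds names to configured estimators", {
  pat <- pat_orbit(L = 75, K_o = 4)
  fn <- select_estimator("lsq_donut", list(L = 75, sigma = 150))
  counts <- c(30, 20, 25, 25)
  direct <- est_lsq_donut(counts / sum(counts), pat$offsets, 75, 150)
  expect_equal(fn(counts, pat)$x_est, direct$x_est)
  it1 <- select_estimator("iter_lsq", list(model = "donut", L = 75, sigma = 150,
                                           max_iterations = 1, tolerance = 1e-12))
  expect_equal(it1(counts, pat)$x_est, direct$x_est, tolerance = 1e-8)
  expect_error(select_estimator("foo"), "lsq_donut")
})
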