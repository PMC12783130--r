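# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a %s numeric scalar", name,
                 if (allow_zero) "nonnegative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

# Coerce a position to a length-3 numeric (z = 0 if absent).
.as_pos3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 2L) x <- c(x, 0)
  if (length(x) != 3L) stop("positions must have 2 or 3 coordinates", call. = FALSE)
  x
}

# Rows of a matrix coerced to n x 3.
.as_pos3_mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) == 2L) x <- cbind(x, 0)
  if (ncol(x) != 3L) stop("position matrix must have 2 or 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Seed scoping: run `expr` under a locally set seed, restoring the caller's
# RNG state afterwards. seed = NULL uses (and advances) the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a run seed and an index, staying inside 32-bit
# integer range so that set.seed() accepts it.
.child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69069 + 12345 * as.double(i)) %% 2147483647)
}

# --- Catmull-Rom (interpolating cubic) kernel -------------------------------
# Separable cubic interpolation with linear precision: reproduces stored
# values exactly at the nodes and linear ramps exactly between them.

.cr_weights <- function(t) {
  # t in [0,1); returns weights for samples at offsets -1, 0, 1, 2
  t2 <- t * t
  t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
        1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
        0.5 * t3 - 0.5 * t2)
}

# Per-axis index/weight preparation. grid: strictly increasing, uniform.
.cr_axis <- function(q, grid) {
  n <- length(grid)
  h <- if (n > 1L) grid[2L] - grid[1L] else 1
  u <- (q - grid[1L]) / h
  inside <- u >= 0 & u <= n - 1L
  i0 <- floor(u)
  i0[i0 > n - 2L] <- n - 2L   # right edge: interpolate in last cell
  i0[i0 < 0] <- 0
  t <- u - i0
  w <- .cr_weights(pmin(pmax(t, 0), 1))
  # clamp the 4-point stencil to the support (replicate edge samples)
  idx <- cbind(i0 - 1L, i0, i0 + 1L, i0 + 2L)
  idx[idx < 0L] <- 0L
  idx[idx > n - 1L] <- n - 1L
  list(idx = idx + 1L, w = w, inside = inside)
}

# Evaluate a 3D array field on query points (n x 3); zero outside support.
# grid: list(x =, y =, z =) of axis coordinate vectors matching dim(field).
.interp_cubic3 <- function(field, grid, pts) {
  pts <- .as_pos3_mat(pts)
  ax <- .cr_axis(pts[, 1L], grid$x)
  ay <- .cr_axis(pts[, 2L], grid$y)
  nz <- length(grid$z)
  if (nz == 1L) {
    az <- list(idx = matrix(1L, nrow(pts), 4L),
               w = cbind(0, 1, 0, 0), inside = rep(TRUE, nrow(pts)))
  } else {
    az <- .cr_axis(pts[, 3L], grid$z)
  }
  out <- numeric(nrow(pts))
  dmx <- dim(field)[1L]; dmy <- dim(field)[2L]
  for (a in 1:4) for (b in 1:4) {
    wab <- ax$w[, a] * ay$w[, b]
    lin_xy <- ax$idx[, a] + (ay$idx[, b] - 1L) * dmx
    if (nz == 1L) {
      out <- out + wab * field[lin_xy]
    } else {
      for (cc in 1:4) {
        lin <- lin_xy + (az$idx[, cc] - 1L) * (dmx * dmy)
        out <- out + wab * az$w[, cc] * field[lin]
      }
    }
  }
  inside <- ax$inside & ay$inside & az$inside
  out[!inside] <- 0
  attr(out, "out_of_range") <- !inside
  out
}

# Same-size 2D convolution of matrix `m` with kernel `k` (odd-ish sizes fine)
# via zero-padded FFT. Used for pinhole disks on PSF planes.
.conv2_same <- function(m, k) {
  nr <- nrow(m) + nrow(k) - 1L
  nc <- ncol(m) + ncol(k) - 1L
  pm <- matrix(0, nr, nc); pm[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(fft(fft(pm) * fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L
  c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))]
}
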