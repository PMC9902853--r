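# Fine-grid numerics shared by the forward model, basis construction and
# the simulator: exact exponential-kernel convolution of a piecewise-linear
# curve, interpolation of framewise data onto the fine grid, and
# frame-averaging of fine-grid curves.

# Uniform fine grid covering [0, end of last frame].
fine_times <- function(schedule, fine_dt) {
  if (!is.numeric(fine_dt) || length(fine_dt) != 1L || fine_dt <= 0)
    stop("'fine_dt' must be a positive step in minutes")
  n <- ceiling(max(schedule$end) / fine_dt - 1e-9)
  (0:n) * fine_dt
}

# Convolution (y * exp(-rate t))(t_i) on a uniform grid, treating y as
# piecewise linear.  The per-step integral is exact, so the only error is
# the linear representation of y.  The first-order recursion
# r_i = E r_{i-1} + inc_i is evaluated as a scaled cumulative sum, chunked
# so the scaling factors stay within double range.
exp_conv <- function(y, rate, dt) {
  n <- length(y)
  if (n < 2L) stop("need at least two grid points")
  a <- rate
  one_mE <- -expm1(-a * dt)
  g2 <- 1 / a - one_mE / (a * a * dt)   # weight of the right-hand node
  g1 <- one_mE / a - g2                 # weight of the left-hand node
  inc <- g1 * y[-n] + g2 * y[-1L]
  m <- n - 1L
  step <- a * dt
  blk <- max(1L, min(m, as.integer(floor(500 / step))))
  out <- numeric(n)
  carry <- 0
  i0 <- 1L
  while (i0 <= m) {
    i1 <- min(m, i0 + blk - 1L)
    w <- exp(step * seq_len(i1 - i0 + 1L))
    r <- (cumsum(inc[i0:i1] * w) + carry) / w
    out[(i0 + 1L):(i1 + 1L)] <- r
    carry <- r[length(r)]  # r at block end seeds the next block
    i0 <- i1 + 1L
  }
  out
}

# Interpolate framewise activity onto the fine grid: linear through the
# frame midpoints, anchored at (0, 0), constant beyond the last midpoint.
interp_fine <- function(x, t_fine) {
  stopifnot(inherits(x, "tac"))
  xs <- x$schedule$mid
  ys <- x$activity
  if (xs[1L] > 0) { xs <- c(0, xs); ys <- c(0, ys) }
  stats::approx(xs, ys, xout = t_fine, rule = 2)$y
}

# Sparse matrix W such that W %*% y_fine gives exact frame means of the
# piecewise-linear interpolant of y_fine over [start, end) of each frame.
frame_weight_matrix <- function(schedule, t_fine, sparse = TRUE) {
  dt <- t_fine[2L] - t_fine[1L]
  nn <- length(t_fine)
  nf <- n_frames(schedule)
  ii <- jj <- xx <- vector("list", nf)
  for (f in seq_len(nf)) {
    s <- schedule$start[f]; e <- schedule$end[f]
    j0 <- max(1L, as.integer(floor(s / dt + 1e-9)) + 1L)
    j1 <- min(nn - 1L, as.integer(ceiling(e / dt - 1e-9)))
    idx <- j0:j1
    a <- pmax(t_fine[idx], s)
    b <- pmin(t_fine[idx + 1L], e)
    len <- pmax(0, b - a)
    mfrac <- ((a + b) / 2 - t_fine[idx]) / dt
    w <- numeric(nn)
    w[idx] <- w[idx] + len * (1 - mfrac)
    w[idx + 1L] <- w[idx + 1L] + len * mfrac
    keep <- which(w != 0)
    ii[[f]] <- rep.int(f, length(keep))
    jj[[f]] <- keep
    xx[[f]] <- w[keep] / (e - s)
  }
  if (sparse)
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(nf, nn))
  else {
    W <- matrix(0, nf, nn)
    W[cbind(unlist(ii), unlist(jj))] <- unlist(xx)
    W
  }
}

frame_average <- function(W, y_fine) as.numeric(W %*% y_fine)

# Batched exp_conv over a vector of rates: returns length(y) x length(rates)
# matrix of node values.  Falls back to the chunked scalar path when the
# scaling factors would overflow.
.conv_cache <- new.env(parent = emptyenv())

exp_conv_grid <- function(y, rates, dt) {
  n <- length(y)
  m <- n - 1L
  a <- rates
  if (max(a) * dt * m > 500)
    return(vapply(a, function(ai) exp_conv(y, ai, dt), numeric(n)))
  one_mE <- -expm1(-a * dt)
  g2 <- 1 / a - one_mE / (a * a * dt)
  g1 <- one_mE / a - g2
  # the scaling matrix depends only on (grid, dt, n); reuse it across fits
  key <- paste(c(n, dt, a), collapse = ",")
  Wm <- .conv_cache[[key]]
  if (is.null(Wm)) {
    if (length(ls(.conv_cache)) > 8L)
      rm(list = ls(.conv_cache), envir = .conv_cache)
    Wm <- exp(outer(seq_len(m) * dt, a))
    assign(key, Wm, envir = .conv_cache)
  }
  M <- (outer(y[-n], g1) + outer(y[-1L], g2)) * Wm
  for (j in seq_along(a)) M[, j] <- cumsum(M[, j])
  out <- matrix(0, n, length(a))
  out[-1L, ] <- M / Wm
  out
}

# Exact frame means of (y * exp(-a t)) over [starts, ends], with y piecewise
# linear on the uniform grid.  Uses d/dt conv = y - a conv, so the running
# integral of conv is (int y - conv)/a; both factors are evaluated in closed
# form at arbitrary times inside a grid cell.  No quadrature error beyond
# the piecewise-linear representation of y itself.
exp_conv_framemean <- function(y, a, dt, starts, ends) {
  n <- length(y)
  conv <- exp_conv(y, a, dt)
  intC <- c(0, cumsum((y[-n] + y[-1L]) / 2) * dt)
  cum_at <- function(tt) {
    j <- pmin(pmax(floor(tt / dt + 1e-9), 0), n - 2)  # cell index, 0-based
    u <- tt - j * dt
    Cj <- y[j + 1L]
    slope <- (y[j + 2L] - Cj) / dt
    one_mE <- -expm1(-a * u)
    conv_t <- conv[j + 1L] * exp(-a * u) + Cj * one_mE / a +
      slope * (u / a - one_mE / (a * a))
    intC_t <- intC[j + 1L] + Cj * u + slope * u^2 / 2
    (intC_t - conv_t) / a
  }
  (cum_at(ends) - cum_at(starts)) / (ends - starts)
}

# Batched exp_conv_framemean over a vector of rates: frame-by-rate matrix.
exp_conv_framemean_grid <- function(y, rates, dt, starts, ends) {
  n <- length(y)
  J <- length(rates)
  CV <- exp_conv_grid(y, rates, dt)
  intC <- c(0, cumsum((y[-n] + y[-1L]) / 2) * dt)
  cum_at <- function(tt) {
    j <- pmin(pmax(floor(tt / dt + 1e-9), 0), n - 2)
    u <- tt - j * dt
    Cj <- y[j + 1L]
    slope <- (y[j + 2L] - Cj) / dt
    A <- matrix(rates, length(tt), J, byrow = TRUE)
    U <- outer(u, rates)
    one_mE <- -expm1(-U)
    conv_t <- CV[j + 1L, , drop = FALSE] * exp(-U) + (Cj / A) * one_mE +
      slope * (u / A - one_mE / (A * A))
    intC_t <- intC[j + 1L] + Cj * u + slope * u^2 / 2  # recycles by column
    (intC_t - conv_t) / A
  }
  (cum_at(ends) - cum_at(starts)) / (ends - starts)
}
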