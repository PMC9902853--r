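#' SRTM parameter set
#'
#' The simplified reference tissue model (SRTM) describes a target-region
#' time-activity curve in terms of the reference-region curve with three
#' parameters: relative delivery `R1` (target K1 over reference K1,
#' a proxy for relative cerebral blood flow), target efflux rate `k2`
#' (1/min) and the nondisplaceable binding potential `BPND`.  Derived
#' quantities are the distribution volume ratio `DVR = BPND + 1` and the
#' apparent efflux rate `k2a = k2 / (1 + BPND)`.
#'
#' @param R1 Relative delivery (> 0, unitless).
#' @param k2 Target efflux rate (> 0, 1/min).
#' @param BPND Binding potential (>= 0, unitless).
#' @param check Validate ranges (`TRUE` for true simulation parameters;
#'   fitted values, which may be slightly negative under noise, are stored
#'   unvalidated).
#' @return An object of class `srtm_params` with elements `R1`, `k2`,
#'   `BPND`, `DVR`, `k2a`.
#' @examples
#' srtm_params(R1 = 0.85, k2 = 0.0425, BPND = 0.6)
#' @export
srtm_params <- function(R1, k2, BPND, check = TRUE) {
  stopifnot(is.numeric(R1), is.numeric(k2), is.numeric(BPND),
            length(R1) == 1L, length(k2) == 1L, length(BPND) == 1L)
  if (check) {
    if (!is.finite(R1) || R1 <= 0) stop("R1 must be positive")
    if (!is.finite(k2) || k2 <= 0) stop("k2 must be positive")
    if (!is.finite(BPND) || BPND < 0) stop("BPND must be non-negative")
  }
  structure(list(R1 = as.numeric(R1), k2 = as.numeric(k2),
                 BPND = as.numeric(BPND), DVR = as.numeric(BPND) + 1,
                 k2a = as.numeric(k2) / (1 + as.numeric(BPND))),
            class = "srtm_params")
}

#' @export
print.srtm_params <- function(x, digits = 4, ...) {
  cat("SRTM parameters: R1 =", format(x$R1, digits = digits),
      " k2 =", format(x$k2, digits = digits), "min^-1",
      " BPND =", format(x$BPND, digits = digits),
      " (DVR =", format(x$DVR, digits = digits),
      ", k2a =", format(x$k2a, digits = digits), "min^-1)\n")
  invisible(x)
}

# Fine-grid SRTM operational equation:
# C_T = R1 C_R + (k2 - R1 k2a) [C_R * exp(-k2a t)].
srtm_fine <- function(params, ref_fine, dt) {
  conv <- exp_conv(ref_fine, params$k2a, dt)
  params$R1 * ref_fine + (params$k2 - params$R1 * params$k2a) * conv
}

#' Forward SRTM model: generate a target TAC from a reference TAC
#'
#' Evaluates the SRTM operational equation
#' `C_T(t) = R1 C_R(t) + (k2 - R1 k2a) (C_R * exp(-k2a t))(t)`.
#' The delivery term `R1 C_R` is exact on the frames; the convolution term
#' is computed on a fine uniform grid (reference frames interpolated
#' linearly through their midpoints, anchored at zero) and averaged over
#' each frame.  With `R1 = 1`, `BPND = 0` the output is therefore exactly
#' the reference curve.  Deterministic.
#'
#' @param params An [srtm_params()] object (validated: R1, k2 > 0,
#'   BPND >= 0).
#' @param ref Reference-region `tac` with at least 2 frames.
#' @param fine_dt Fine grid step in minutes (default 0.05; must be <= 0.1
#'   for the discretization error to be negligible on standard schedules).
#' @return A `tac` on the reference schedule.
#' @examples
#' sch <- default_schedule()
#' cr <- reference_tac(sch)
#' ct <- srtm_tac(srtm_params(0.85, 0.0425, 0.6), cr)
#' @export
srtm_tac <- function(params, ref, fine_dt = 0.05) {
  stopifnot(inherits(params, "srtm_params"), inherits(ref, "tac"))
  if (!is.finite(params$R1) || params$R1 <= 0 ||
      !is.finite(params$k2) || params$k2 <= 0 ||
      !is.finite(params$BPND) || params$BPND < 0)
    stop("invalid SRTM parameters for forward simulation")
  if (n_frames(ref) < 2L) stop("reference TAC needs at least 2 frames")
  if (!is.numeric(fine_dt) || fine_dt <= 0) stop("'fine_dt' must be > 0")
  t_fine <- fine_times(ref$schedule, fine_dt)
  ref_fine <- interp_fine(ref, t_fine)
  conv <- exp_conv_framemean(ref_fine, params$k2a, fine_dt,
                             ref$schedule$start, ref$schedule$end)
  tac(ref$schedule,
      params$R1 * ref$activity +
        (params$k2 - params$R1 * params$k2a) * conv)
}

#' RPM basis set
#'
#' Receptor parametric mapping (RPM) linearizes SRTM over a log-spaced grid
#' of apparent efflux rates `k2a`; each basis curve is the frame-averaged
#' convolution of the reference TAC with `exp(-k2a t)`.
#'
#' @param ref Reference-region `tac`.
#' @param k2a_range Numeric length-2 vector, grid bounds in 1/min
#'   (default `c(0.006, 0.6)`, spanning physiological tau-tracer kinetics).
#' @param n_basis Number of log-spaced grid points (default 64; >= 2).
#' @param fine_dt Fine grid step in minutes.
#' @return An object of class `srtm_basis`: list with `k2a` (grid),
#'   `frames` (frame-by-basis matrix), `ref`, `fine_dt`.
#' @export
srtm_basis <- function(ref, k2a_range = c(0.006, 0.6), n_basis = 64,
                       fine_dt = 0.05) {
  stopifnot(inherits(ref, "tac"))
  if (length(k2a_range) != 2L || !all(is.finite(k2a_range)) ||
      k2a_range[1] <= 0 || k2a_range[2] <= k2a_range[1])
    stop("'k2a_range' must satisfy 0 < min < max")
  if (n_basis < 2L) stop("'n_basis' must be at least 2")
  t_fine <- fine_times(ref$schedule, fine_dt)
  ref_fine <- interp_fine(ref, t_fine)
  grid <- exp(seq(log(k2a_range[1]), log(k2a_range[2]),
                  length.out = n_basis))
  basis_from_fine(ref, ref_fine, grid, fine_dt)
}

# Shared constructor used by srtm_basis() and the cohort/bias engines,
# which hold the fine reference curve already.  The fine curve is kept for
# the continuous k2a refinement step of fit_srtm().
basis_from_fine <- function(ref, ref_fine, grid, fine_dt) {
  s <- ref$schedule
  B <- exp_conv_framemean_grid(ref_fine, grid, fine_dt, s$start, s$end)
  structure(list(k2a = grid, frames = B, ref = ref, fine_dt = fine_dt,
                 ref_fine = ref_fine),
            class = "srtm_basis")
}

#' @export
print.srtm_basis <- function(x, ...) {
  cat("RPM basis set:", length(x$k2a), "log-spaced k2a values in [",
      format(min(x$k2a), digits = 4), ",", format(max(x$k2a), digits = 4),
      "] min^-1 over", n_frames(x$ref), "frames\n")
  invisible(x)
}

#' Fit SRTM by basis-function receptor parametric mapping
#'
#' For every `k2a` on the basis grid the model
#' `C_T ~ theta1 C_R + theta2 B(k2a)` is solved by weighted linear least
#' squares; the grid point minimizing the weighted residual sum of squares
#' is selected and mapped back to the SRTM parameters
#' (`R1 = theta1`, `k2 = theta2 + R1 k2a`, `BPND = k2/k2a - 1`).
#'
#' Fits whose selected `k2a` sits on the edge of the grid are flagged
#' (`boundary`), as are fits with negative `BPND` (`negative_bp`); neither
#' is clamped, so cohort-level means remain unbiased.
#'
#' @param target Target-region `tac`.
#' @param ref Reference-region `tac` on the same schedule as `target`.
#' @param basis Optional precomputed [srtm_basis()] for `ref`; built on the
#'   fly otherwise.
#' @param weights Optional non-negative per-frame weights (default
#'   uniform).  `weights = "duration"` uses frame durations;
#'   `weights = "ivar"` uses `duration / max(C_ref, floor)^2`, the
#'   inverse-variance weighting for proportional noise whose SD scales
#'   with `1/sqrt(duration)` (the reference curve serves as the variance
#'   proxy, floored at 5% of its peak).
#' @param refine After grid selection, polish `k2a` continuously by
#'   parabolic interpolation of the WRSS over the selected grid point and
#'   its two neighbours (default `TRUE`); this removes the grid-quantization
#'   error from `k2` and `BPND` at the cost of one extra basis evaluation.
#' @param ... Passed to [srtm_basis()] when `basis` is `NULL`
#'   (`k2a_range`, `n_basis`, `fine_dt`).
#' @return An object of class `srtm_fit`: `params` (`srtm_params`,
#'   unvalidated), `wrss`, `basis_index`, `boundary`, `negative_bp`,
#'   `fitted` (vector), `target`, `ref`, `weights`, `k2a_grid`.
#' @examples
#' sch <- default_schedule()
#' cr <- reference_tac(sch)
#' ct <- srtm_tac(srtm_params(0.85, 0.0425, 0.6), cr)
#' fit <- fit_srtm(ct, cr)
#' coef(fit)
#' @export
fit_srtm <- function(target, ref, basis = NULL, weights = NULL,
                     refine = TRUE, ...) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target, ref))
    stop("target and reference must share one frame schedule")
  if (is.null(basis)) basis <- srtm_basis(ref, ...)
  stopifnot(inherits(basis, "srtm_basis"))
  if (!same_schedule(basis$ref, target))
    stop("basis was built on a different frame schedule")
  n <- n_frames(target)
  if (is.null(weights)) weights <- rep(1, n)
  else if (identical(weights, "duration")) weights <- target$schedule$duration
  else if (identical(weights, "ivar")) {
    cref <- pmax(abs(ref$activity), 0.05 * max(abs(ref$activity)))
    weights <- target$schedule$duration / cref^2
  }
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be non-negative, finite, one per frame")
  if (all(weights == 0)) stop("all frame weights are zero")

  y <- target$activity
  x1 <- ref$activity
  B <- basis$frames
  wx1 <- weights * x1
  a11 <- sum(wx1 * x1)
  b1 <- sum(wx1 * y)
  swy2 <- sum(weights * y^2)

  # 2-parameter WLS against one basis column; wrss = y'Wy - theta'b at the
  # solution.  Returns c(theta1, theta2, wrss), or Inf wrss if degenerate.
  solve_col <- function(b) {
    a12 <- sum(wx1 * b)
    a22 <- sum(weights * b^2)
    det <- a11 * a22 - a12^2
    if (!(det > .Machine$double.eps * a11 * max(a22, 1)))
      return(c(NA_real_, NA_real_, Inf))
    t1 <- (a22 * b1 - a12 * sum(weights * b * y)) / det
    t2 <- (a11 * sum(weights * b * y) - a12 * b1) / det
    c(t1, t2, max(0, swy2 - (t1 * b1 + t2 * sum(weights * b * y))))
  }

  a12 <- as.numeric(crossprod(B, wx1))
  a22 <- as.numeric(crossprod(B^2, weights))
  b2 <- as.numeric(crossprod(B, weights * y))
  det <- a11 * a22 - a12^2
  ok <- det > .Machine$double.eps * a11 * pmax(a22, 1)
  if (!any(ok)) stop("design matrix rank-deficient at every basis point")
  th1 <- th2 <- wrss <- rep(NA_real_, length(a12))
  th1[ok] <- (a22[ok] * b1 - a12[ok] * b2[ok]) / det[ok]
  th2[ok] <- (a11 * b2[ok] - a12[ok] * b1) / det[ok]
  wrss[ok] <- swy2 - (th1[ok] * b1 + th2[ok] * b2[ok])
  wrss[!ok] <- Inf
  wrss <- pmax(wrss, 0)  # guard tiny negative round-off

  j <- which.min(wrss)
  k2a <- basis$k2a[j]
  sel <- c(th1[j], th2[j], wrss[j])
  bcol <- B[, j]

  J <- length(basis$k2a)
  if (isTRUE(refine) && !is.null(basis$ref_fine) && j > 1L && j < J &&
      all(is.finite(wrss[(j - 1L):(j + 1L)]))) {
    # WRSS is locally parabolic in log(k2a); interpolate the vertex from
    # the selected grid point and its neighbours, then refit there once.
    lx <- log(basis$k2a[(j - 1L):(j + 1L)])
    wv <- wrss[(j - 1L):(j + 1L)]
    denom <- wv[1L] - 2 * wv[2L] + wv[3L]
    if (denom > 0) {
      h <- (lx[3L] - lx[1L]) / 2
      shift <- h / 2 * (wv[1L] - wv[3L]) / denom
      shift <- max(min(shift, h), -h)  # stay inside the bracket
      cand <- exp(lx[2L] + shift)
      sref <- basis$ref$schedule
      cand_col <- exp_conv_framemean(basis$ref_fine, cand, basis$fine_dt,
                                     sref$start, sref$end)
      cand_sol <- solve_col(cand_col)
      if (is.finite(cand_sol[3L]) && cand_sol[3L] <= sel[3L]) {
        k2a <- cand
        sel <- cand_sol
        bcol <- cand_col
      }
    }
  }

  R1 <- sel[1L]
  k2 <- sel[2L] + R1 * k2a
  BP <- k2 / k2a - 1
  structure(list(
    params = srtm_params(R1, k2, BP, check = FALSE),
    wrss = sel[3L],
    wrss_grid = wrss,
    basis_index = j,
    boundary = j == 1L || j == J,
    negative_bp = BP < 0,
    fitted = sel[1L] * x1 + sel[2L] * bcol,
    target = target, ref = ref,
    weights = weights,
    k2a_grid = basis$k2a),
    class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, digits = 4, ...) {
  cat("SRTM fit (basis-function RPM)\n")
  cat("  R1   =", format(x$params$R1, digits = digits), "\n")
  cat("  k2   =", format(x$params$k2, digits = digits), "min^-1\n")
  cat("  BPND =", format(x$params$BPND, digits = digits),
      " (DVR =", format(x$params$DVR, digits = digits), ")\n")
  cat("  WRSS =", format(x$wrss, digits = digits),
      " at k2a =", format(x$params$k2a, digits = digits),
      "min^-1 (grid point", x$basis_index, "of", length(x$k2a_grid), ")\n")
  if (x$boundary) cat("  note: selected k2a on the grid boundary\n")
  if (x$negative_bp) cat("  note: fitted BPND is negative\n")
  invisible(x)
}

#' @export
summary.srtm_fit <- function(object, window = c(80, 100), ...) {
  s <- list(coef = coef(object), wrss = object$wrss,
            boundary = object$boundary, negative_bp = object$negative_bp,
            n = n_frames(object$target),
            suvr = tryCatch(suvr(object$target, object$ref, window),
                            error = function(e) NA_real_),
            window = window)
  class(s) <- "summary.srtm_fit"
  s
}

#' @export
print.summary.srtm_fit <- function(x, digits = 4, ...) {
  cat("SRTM fit over", x$n, "frames\n")
  print(round(x$coef, digits))
  cat("SUVr(", x$window[1], "-", x$window[2], " min) = ",
      format(x$suvr, digits = digits), "; WRSS = ",
      format(x$wrss, digits = digits), "\n", sep = "")
  if (x$boundary) cat("k2a on grid boundary\n")
  if (x$negative_bp) cat("fitted BPND negative\n")
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) {
  c(R1 = object$params$R1, k2 = object$params$k2,
    BPND = object$params$BPND, DVR = object$params$DVR)
}

#' @export
fitted.srtm_fit <- function(object, ...) object$fitted

#' @export
residuals.srtm_fit <- function(object, ...)
  object$target$activity - object$fitted

#' @export
predict.srtm_fit <- function(object, ...)
  tac(object$target$schedule, object$fitted)

#' @export
plot.srtm_fit <- function(x, ..., xlab = "Time (min)",
                          ylab = "Activity (kBq/mL)") {
  mid <- x$target$schedule$mid
  graphics::plot(mid, x$target$activity, pch = 16, xlab = xlab,
                 ylab = ylab, ...)
  graphics::lines(mid, x$fitted, col = 2, lwd = 2)
  graphics::points(mid, x$ref$activity, pch = 1, col = "grey40")
  graphics::legend("topright", bty = "n",
                   legend = c("target", "SRTM fit", "reference"),
                   pch = c(16, NA, 1), lty = c(NA, 1, NA),
                   col = c(1, 2, "grey40"))
  invisible(x)
}

#' @export
simulate.srtm_fit <- function(object, nsim = 1, seed = NULL, cov = 0.05,
                              ...) {
  fit_tac <- predict(object)
  with_seed(seed, lapply(seq_len(nsim),
                         function(i) add_noise(fit_tac, cov)))
}

#' @export
as.data.frame.srtm_fit <- function(x, ..., window = c(80, 100)) {
  data.frame(R1 = x$params$R1, k2_per_min = x$params$k2,
             BPND = x$params$BPND, DVR = x$params$DVR,
             SUVr = tryCatch(suvr(x$target, x$ref, window),
                             error = function(e) NA_real_),
             wrss = x$wrss, boundary = x$boundary,
             negative_bp = x$negative_bp)
}
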