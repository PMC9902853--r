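# Grid experiments: percentage bias of SUVr and of RPM-fitted DVR relative
# to true DVR, across binding conditions, flow changes, noise levels and
# SUVr scan windows.

#' Default SUVr scan windows
#'
#' Five 20-min windows bracketing the conventional 80--100 min interval.
#' @return List of `c(start, end)` pairs (minutes).
#' @export
default_windows <- function()
  list(c(40, 60), c(60, 80), c(80, 100), c(100, 120), c(110, 130))

window_label <- function(w) paste0(w[1], "-", w[2])

#' Bias of SUVr and fitted DVR across binding, flow and noise
#'
#' For every (binding condition, flow delta) cell, simulates `n_rep`
#' target/reference TAC pairs at noise level `cov`, fits SRTM by RPM,
#' computes SUVr for every window, and aggregates the percentage biases
#' `(SUVr / DVR_true - 1) * 100` and `(DVR_fit / DVR_true - 1) * 100`
#' over replicates.  Deterministic given `seed`.
#'
#' @param conditions Named list of [srtm_params()] (default
#'   [binding_conditions()]).
#' @param deltas Fractional flow changes (default `seq(-0.3, 0.3, 0.1)`).
#' @param windows List of SUVr windows (default [default_windows()]).
#' @param cov Noise coefficient of variation.
#' @param n_rep Replicates per cell (>= 1).
#' @param seed Integer seed.
#' @param schedule Frame schedule.
#' @param scope Flow-change scope, see [simulate_condition()].
#' @param k2a_range,n_basis Basis grid, see [srtm_basis()].
#' @param plasma,K1_ref,k2_ref,fine_dt Simulator settings.
#' @return A `data.frame` of class `bias_table`: one row per
#'   (condition, delta, cov, window) with `n_rep`, `bias_suvr_mean`,
#'   `bias_suvr_sd`, `bias_dvr_mean`, `bias_dvr_sd`, `dvr_true`.
#' @export
run_bias_grid <- function(conditions = binding_conditions(),
                          deltas = seq(-0.3, 0.3, by = 0.1),
                          windows = default_windows(),
                          cov = 0.05, n_rep = 200, seed = NULL,
                          schedule = default_schedule(),
                          scope = "target_only",
                          k2a_range = c(0.006, 0.6), n_basis = 64,
                          plasma = plasma_params(), K1_ref = 0.35,
                          k2_ref = 0.05, fine_dt = 0.05) {
  if (!is.list(conditions) || is.null(names(conditions)))
    stop("'conditions' must be a named list of srtm_params")
  if (!is.list(windows)) windows <- list(windows)
  if (n_rep < 1L) stop("'n_rep' must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  basis_grid <- exp(seq(log(k2a_range[1]), log(k2a_range[2]),
                        length.out = n_basis))
  out <- vector("list", length(conditions) * length(deltas))
  cell <- 0L
  for (ci in seq_along(conditions)) for (delta in deltas) {
    sim0 <- simulate_condition(conditions[[ci]], delta = delta, cov = 0,
                               scope = scope, schedule = schedule,
                               plasma = plasma, K1_ref = K1_ref,
                               k2_ref = k2_ref, fine_dt = fine_dt)
    dvr_true <- sim0$truth$DVR
    dvr_fit <- numeric(n_rep)
    suvr_rep <- matrix(0, n_rep, length(windows))
    t_fine <- fine_times(schedule, fine_dt)
    for (r in seq_len(n_rep)) {
      tgt <- add_noise(sim0$target, cov)
      refn <- add_noise(sim0$reference, cov)
      basis <- basis_from_fine(refn, interp_fine(refn, t_fine),
                               basis_grid, fine_dt)
      fit <- fit_srtm(tgt, refn, basis = basis)
      dvr_fit[r] <- fit$params$DVR
      for (wi in seq_along(windows))
        suvr_rep[r, wi] <- suvr(tgt, refn, windows[[wi]])
    }
    bias_dvr <- (dvr_fit / dvr_true - 1) * 100
    cell <- cell + 1L
    out[[cell]] <- data.frame(
      condition = names(conditions)[ci],
      delta = delta,
      cov = cov,
      window = vapply(windows, window_label, character(1)),
      n_rep = n_rep,
      bias_suvr_mean = colMeans(suvr_rep / dvr_true - 1) * 100,
      bias_suvr_sd = apply((suvr_rep / dvr_true - 1) * 100, 2, stats::sd),
      bias_dvr_mean = mean(bias_dvr),
      bias_dvr_sd = stats::sd(bias_dvr),
      dvr_true = dvr_true,
      row.names = NULL)
  }
  res <- do.call(rbind, out[seq_len(cell)])
  class(res) <- c("bias_table", "data.frame")
  res
}

#' SUVr bias as a function of the scan window
#'
#' Slice of the bias grid at one binding condition and one flow change:
#' bias per SUVr window, with its sign.
#'
#' @inheritParams run_bias_grid
#' @param condition A single [srtm_params()] or condition name.
#' @param delta One fractional flow change.
#' @return A `bias_table` with one row per window.
#' @export
window_sensitivity <- function(condition, delta = 0,
                               windows = default_windows(), cov = 0.05,
                               n_rep = 200, seed = NULL, ...) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  if (is.character(condition)) {
    conds <- binding_conditions()
    condition <- conds[condition]
  } else condition <- stats::setNames(list(condition), "condition")
  res <- run_bias_grid(conditions = condition, deltas = delta,
                       windows = windows, cov = cov, n_rep = n_rep,
                       seed = seed, ...)
  res$bias_sign <- sign(res$bias_suvr_mean)
  res
}

#' Compare mean SUVr bias between two noise levels
#'
#' Runs the same bias grid at `cov_a` and `cov_b` (same seed for both runs)
#' and tabulates the absolute difference in mean SUVr bias per cell.
#'
#' @inheritParams run_bias_grid
#' @param cov_a,cov_b Noise levels to compare (fractions, >= 0).
#' @return `data.frame` with the grid keys and `abs_diff_bias_suvr`
#'   (percentage points).
#' @export
compare_noise_levels <- function(cov_a, cov_b,
                                 conditions = binding_conditions(),
                                 deltas = c(-0.2, 0, 0.2),
                                 windows = list(c(80, 100)),
                                 n_rep = 200, seed = 1, ...) {
  stopifnot(cov_a >= 0, cov_b >= 0)
  ta <- run_bias_grid(conditions, deltas, windows, cov = cov_a,
                      n_rep = n_rep, seed = seed, ...)
  tb <- run_bias_grid(conditions, deltas, windows, cov = cov_b,
                      n_rep = n_rep, seed = seed, ...)
  key <- c("condition", "delta", "window")
  m <- merge(ta[c(key, "bias_suvr_mean")], tb[c(key, "bias_suvr_mean")],
             by = key, suffixes = c("_a", "_b"))
  m$abs_diff_bias_suvr <- abs(m$bias_suvr_mean_a - m$bias_suvr_mean_b)
  m[order(m$condition, m$delta, m$window), ]
}

#' @export
print.bias_table <- function(x, digits = 3, ...) {
  cat("SUVr/DVR bias table:", nrow(x), "rows (",
      length(unique(x$condition)), "conditions x",
      length(unique(x$delta)), "flow deltas x",
      length(unique(x$window)), "windows ), n_rep =",
      unique(x$n_rep)[1], ", cov =", unique(x$cov)[1], "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bias_table <- function(x, what = c("delta", "window"), ...) {
  what <- match.arg(what)
  conds <- unique(x$condition)
  cols <- seq_along(conds)
  if (what == "delta") {
    w <- x$window[1]
    xx <- x[x$window == w, ]
    graphics::plot(range(xx$delta), range(xx$bias_suvr_mean), type = "n",
                   xlab = "Fractional flow change",
                   ylab = paste0("SUVr(", w, ") bias vs true DVR (%)"), ...)
    for (i in seq_along(conds)) {
      sub <- xx[xx$condition == conds[i], ]
      graphics::lines(sub$delta, sub$bias_suvr_mean, col = cols[i],
                      type = "b", pch = 16)
    }
  } else {
    d <- x$delta[1]
    xx <- x[x$delta == d, ]
    ww <- unique(xx$window)
    graphics::plot(c(1, length(ww)), range(xx$bias_suvr_mean), type = "n",
                   xaxt = "n", xlab = "SUVr window (min)",
                   ylab = "SUVr bias vs true DVR (%)", ...)
    graphics::axis(1, at = seq_along(ww), labels = ww)
    for (i in seq_along(conds)) {
      sub <- xx[xx$condition == conds[i], ]
      graphics::lines(match(sub$window, ww), sub$bias_suvr_mean,
                      col = cols[i], type = "b", pch = 16)
    }
  }
  graphics::legend("topright", legend = conds, col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(x)
}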