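# TAC simulator: plasma input function, one-tissue reference region,
# flow perturbations and proportional frame noise.

# Evaluate code under a temporary RNG state when seed is given; the
# caller's RNG stream is untouched.  seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Plasma input function parameters
#'
#' A linear-rise / tri-exponential-decay arterial input model:
#' the curve rises linearly from 0 at injection to `sum(A)` at `t_peak`,
#' then decays as `sum(A_i exp(-lambda_i (t - t_peak)))`.  Amplitudes are
#' nominal kBq/mL (only ratios matter downstream), rate constants 1/min
#' with `lambda1 > lambda2 > lambda3 > 0`.
#'
#' @param A Numeric length-3 amplitudes (kBq/mL).
#' @param lambda Numeric length-3 decay constants (1/min), strictly
#'   decreasing, all positive.
#' @param t_peak Peak time (min, > 0).
#' @return An object of class `plasma_params`.
#' @export
plasma_params <- function(A = c(800, 80, 30), lambda = c(3, 0.08, 0.005),
                          t_peak = 1) {
  stopifnot(is.numeric(A), length(A) == 3L, all(is.finite(A)), all(A >= 0),
            is.numeric(lambda), length(lambda) == 3L, all(is.finite(lambda)))
  if (!(lambda[1] > lambda[2] && lambda[2] > lambda[3] && lambda[3] > 0))
    stop("decay constants must satisfy lambda1 > lambda2 > lambda3 > 0")
  if (!is.numeric(t_peak) || t_peak <= 0) stop("'t_peak' must be positive")
  structure(list(A = A, lambda = lambda, t_peak = t_peak),
            class = "plasma_params")
}

#' @export
print.plasma_params <- function(x, ...) {
  cat("Plasma input: peak", format(sum(x$A), digits = 4), "kBq/mL at",
      x$t_peak, "min; decay constants",
      paste(format(x$lambda, digits = 3), collapse = ", "), "min^-1\n")
  invisible(x)
}

#' Evaluate the plasma input function
#'
#' @param t Times (min, >= 0); vectorized.
#' @param p A [plasma_params()] object.
#' @return Plasma activity concentration at `t` (kBq/mL); 0 at `t = 0`,
#'   single early peak near `t_peak`, monotone decay afterwards.
#' @export
plasma_input <- function(t, p = plasma_params()) {
  stopifnot(inherits(p, "plasma_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  peak <- sum(p$A)
  out <- ifelse(t < p$t_peak, t / p$t_peak * peak,
                p$A[1] * exp(-p$lambda[1] * (t - p$t_peak)) +
                p$A[2] * exp(-p$lambda[2] * (t - p$t_peak)) +
                p$A[3] * exp(-p$lambda[3] * (t - p$t_peak)))
  out
}

# Fine-grid reference curve: one-tissue model
# C_R = K1_ref [C_p * exp(-k2_ref t)].
reference_fine <- function(t_fine, K1_ref, k2_ref, plasma, fine_dt) {
  cp <- plasma_input(t_fine, plasma)
  K1_ref * exp_conv(cp, k2_ref, fine_dt)
}

#' Simulate a reference-region TAC
#'
#' One-tissue compartment model for the reference region:
#' `C_R(t) = K1_ref (C_p * exp(-k2_ref t))(t)`, frame-averaged over the
#' schedule.
#'
#' @param schedule A [frame_schedule()].
#' @param K1_ref Delivery rate (mL cm^-3 min^-1; >= 0 -- zero gives the
#'   all-zero TAC).
#' @param k2_ref Reference efflux rate (1/min, > 0; default 0.05).
#' @param plasma A [plasma_params()] object.
#' @param fine_dt Fine grid step (min).
#' @return A `tac` on `schedule`.
#' @export
reference_tac <- function(schedule, K1_ref = 0.35, k2_ref = 0.05,
                          plasma = plasma_params(), fine_dt = 0.05) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.numeric(K1_ref) || K1_ref < 0) stop("'K1_ref' must be >= 0")
  if (!is.numeric(k2_ref) || k2_ref <= 0) stop("'k2_ref' must be positive")
  t_fine <- fine_times(schedule, fine_dt)
  W <- frame_weight_matrix(schedule, t_fine)
  tac(schedule,
      frame_average(W, reference_fine(t_fine, K1_ref, k2_ref, plasma,
                                      fine_dt)))
}

#' Named binding conditions
#'
#' Default true SRTM parameter sets for the four simulated binding levels:
#' almost no binding (as in subjective cognitive decline), and low, medium
#' and high tau load (as in Alzheimer disease).  BPND defaults bracket the
#' observed cohort DVR range and extend to high focal load; baseline
#' delivery `R1 = 0.9` and reference efflux `k2' = 0.05` 1/min give
#' `k2 = R1 k2'`.
#'
#' @param bpnd Named numeric vector of BPND values per condition.
#' @param R1 Baseline relative delivery.
#' @param k2_ref Reference efflux rate `k2'` (1/min).
#' @return Named list of [srtm_params()].
#' @export
binding_conditions <- function(bpnd = c(SCD_no_binding = 0.05,
                                        AD_low = 0.25,
                                        AD_medium = 0.6,
                                        AD_high = 1.2),
                               R1 = 0.9, k2_ref = 0.05) {
  if (is.unsorted(bpnd, strictly = TRUE))
    stop("binding conditions must be ordered by increasing BPND")
  lapply(bpnd, function(b) srtm_params(R1 = R1, k2 = R1 * k2_ref, BPND = b))
}

#' Apply a fractional flow change to SRTM parameters
#'
#' A flow (perfusion) change of fraction `delta` scales delivery and efflux
#' together: `R1 -> R1 (1 + delta)`, `k2 -> k2 (1 + delta)`, leaving `BPND`
#' -- and hence the true DVR -- unchanged.  This is what isolates perfusion
#' effects on semiquantitative measures: true binding is constant by
#' construction.
#'
#' @param params An [srtm_params()] object.
#' @param delta Fractional flow change (> -1), e.g. `0.2` for +20%.
#' @return New `srtm_params` with scaled `R1`, `k2`.
#' @examples
#' apply_flow_change(srtm_params(0.9, 0.045, 0.6), 0.2)  # R1 1.08, k2 0.054
#' @export
apply_flow_change <- function(params, delta) {
  stopifnot(inherits(params, "srtm_params"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= -1)
    stop("'delta' must be a finite fraction > -1")
  srtm_params(R1 = params$R1 * (1 + delta), k2 = params$k2 * (1 + delta),
              BPND = params$BPND)
}

#' Add proportional measurement noise to a TAC
#'
#' Independent Gaussian noise per frame with
#' `SD_i = cov * |C(t_i)| * sqrt(mean(dt) / dt_i)`, where `dt_i` is the
#' frame duration -- short frames are noisier, emulating count statistics.
#' `cov = 0` returns the input unchanged.  Negative noisy frames are kept
#' (flag with [has_negative()]), never clipped.
#'
#' @param x A `tac`.
#' @param cov Coefficient of variation (fraction, >= 0), e.g. `0.05` for
#'   realistic ROI noise or `0.0005` for near-noiseless curves.
#' @param seed Optional integer; when given, output is reproducible and the
#'   caller's RNG stream is untouched.
#' @return A `tac` with perturbed activity.
#' @export
add_noise <- function(x, cov, seed = NULL) {
  stopifnot(inherits(x, "tac"))
  if (!is.numeric(cov) || length(cov) != 1L || !is.finite(cov) || cov < 0)
    stop("'cov' must be a non-negative fraction")
  if (cov == 0) return(x)
  dur <- x$schedule$duration
  sdv <- cov * abs(x$activity) * sqrt(mean(dur) / dur)
  with_seed(seed,
            tac(x$schedule, x$activity + stats::rnorm(length(sdv), 0, sdv)))
}

#' Simulate one binding condition under a flow scenario
#'
#' Composes the simulator: reference TAC from the one-tissue model,
#' flow-adjusted true parameters via [apply_flow_change()], target TAC from
#' the forward SRTM model, then proportional noise on target and reference
#' independently (when `cov > 0`).  With `scope = "global"` the flow change
#' also rescales the reference-region kinetics (`K1_ref`, `k2_ref`);
#' the default `"target_only"` models a regional flow change.
#'
#' @param condition An [srtm_params()] object, or the name of one of the
#'   default [binding_conditions()].
#' @param delta Fractional flow change (> -1).
#' @param cov Noise coefficient of variation (fraction).
#' @param scope `"target_only"` or `"global"`.
#' @param schedule Frame schedule (default [default_schedule()]).
#' @param seed Optional seed for the noise draws.
#' @param plasma,K1_ref,k2_ref,fine_dt Simulator settings, see
#'   [reference_tac()].
#' @return List with elements `target`, `reference` (noisy `tac`s),
#'   `truth` (flow-adjusted `srtm_params`; its DVR equals the pre-change
#'   DVR by construction), `delta`, `cov`, `scope`.
#' @export
simulate_condition <- function(condition, delta = 0, cov = 0,
                               scope = c("target_only", "global"),
                               schedule = default_schedule(), seed = NULL,
                               plasma = plasma_params(), K1_ref = 0.35,
                               k2_ref = 0.05, fine_dt = 0.05) {
  scope <- match.arg(scope)
  if (is.character(condition)) {
    conds <- binding_conditions(k2_ref = k2_ref)
    if (!condition %in% names(conds))
      stop("unknown binding condition '", condition, "'")
    condition <- conds[[condition]]
  }
  stopifnot(inherits(condition, "srtm_params"))
  truth <- apply_flow_change(condition, delta)
  g <- if (scope == "global") 1 + delta else 1
  t_fine <- fine_times(schedule, fine_dt)
  W <- frame_weight_matrix(schedule, t_fine)
  ref_fine <- reference_fine(t_fine, K1_ref * g, k2_ref * g, plasma,
                             fine_dt)
  ref <- tac(schedule, frame_average(W, ref_fine))
  conv <- exp_conv_framemean(ref_fine, truth$k2a, fine_dt,
                             schedule$start, schedule$end)
  target <- tac(schedule,
                truth$R1 * ref$activity +
                  (truth$k2 - truth$R1 * truth$k2a) * conv)
  with_seed(seed, {
    target <- add_noise(target, cov)
    ref <- add_noise(ref, cov)
    list(target = target, reference = ref, truth = truth, delta = delta,
         cov = cov, scope = scope)
  })
}
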