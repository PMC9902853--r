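test_that("plasma input starts at zero, peaks near t_peak, then decays", {
  p <- plasma_params()
  expect_identical(plasma_input(0, p), 0)
  tt <- seq(0, 130, by = 0.01)
  v <- plasma_input(tt, p)
  expect_true(all(v >= 0))
  expect_lt(abs(tt[which.max(v)] - p$t_peak), 0.5)
  after10 <- v[tt >= 10]
  expect_true(all(diff(after10) <= 1e-12))
  # finite positive integral
  expect_gt(sum(v) * 0.01, 0)
  expect_true(is.finite(sum(v) * 0.01))
  expect_error(plasma_input(-1, p), "non-negative")
  expect_error(plasma_params(lambda = c(0.1, 3, 0.01)), "lambda1 > lambda2")
})

test_that("reference TAC is linear in K1 and washes out by the late window", {
  r1 <- reference_tac(canon_schedule, K1_ref = 0.35)
  r2 <- reference_tac(canon_schedule, K1_ref = 0.175)
  expect_equal(r2$activity, r1$activity / 2, tolerance = 1e-12)
  r0 <- reference_tac(canon_schedule, K1_ref = 0)
  expect_true(all(r0$activity == 0))
  late <- mean(r1$activity[canon_schedule$start >= 80 &
                             canon_schedule$end <= 100])
  expect_lt(late, max(r1$activity))
})

test_that("apply_flow_change scales delivery and efflux, never binding", {
  p <- srtm_params(0.9, 0.045, 0.6)
  expect_equal(apply_flow_change(p, 0), p)
  q <- apply_flow_change(p, 0.2)
  expect_equal(q$R1, 1.08)
  expect_equal(q$k2, 0.054)
  expect_equal(q$BPND, 0.6)
  expect_equal(q$DVR, 1.6)
  expect_error(apply_flow_change(p, -1), "> -1")
  # DVR invariance holds for arbitrary deltas by construction
  for (d in c(-0.5, -0.1, 0.07, 0.45))
    expect_identical(apply_flow_change(p, d)$DVR, p$DVR)
})

test_that("proportional noise has the specified per-frame SD", {
  sim <- simulate_condition("AD_medium")
  x <- sim$target
  expect_identical(add_noise(x, 0), x)
  dur <- x$schedule$duration
  sd_target <- 0.05 * abs(x$activity) * sqrt(mean(dur) / dur)
  set.seed(2)
  draws <- replicate(1000, add_noise(x, 0.05)$activity)
  sd_emp <- apply(draws, 1, sd)
  expect_true(all(rel_dev(sd_emp, sd_target) < 0.10))
})

test_that("noise is reproducible by seed and leaves the caller's RNG alone", {
  sim <- simulate_condition("AD_low")
  a <- add_noise(sim$target, 0.05, seed = 99)
  b <- add_noise(sim$target, 0.05, seed = 99)
  expect_identical(a$activity, b$activity)
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(add_noise(sim$target, 0.05, seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("simulated conditions round-trip through the fitter", {
  s <- simulate_condition("SCD_no_binding", delta = 0, cov = 0)
  expect_lt(fit_srtm(s$target, s$reference)$params$BPND, 0.07)
  s <- simulate_condition("AD_high", delta = 0, cov = 0)
  expect_lt(rel_dev(fit_srtm(s$target, s$reference)$params$DVR,
                    s$truth$DVR), 0.01)
})

test_that("fitted DVR ignores simulated flow changes on noiseless data", {
  f0 <- fit_srtm2 <- NULL
  s0 <- simulate_condition("AD_medium", delta = 0, cov = 0)
  s2 <- simulate_condition("AD_medium", delta = 0.2, cov = 0)
  d0 <- fit_srtm(s0$target, s0$reference)$params$DVR
  d2 <- fit_srtm(s2$target, s2$reference)$params$DVR
  expect_lt(rel_dev(d2, d0), 0.01)
  expect_identical(s0$truth$DVR, s2$truth$DVR)
})

test_that("noiseless TACs are non-negative; noisy ones flag negatives", {
  for (cn in names(binding_conditions())) {
    s <- simulate_condition(cn, delta = -0.3, cov = 0)
    expect_false(has_negative(s$target))
    expect_false(has_negative(s$reference))
  }
  set.seed(5)
  s <- simulate_condition("SCD_no_binding", cov = 0.3)
  expect_true(has_negative(s$target) || has_negative(s$reference))
})

test_that("simulation is reproducible from seed, global scope scales ref", {
  a <- simulate_condition("AD_low", delta = 0.1, cov = 0.05, seed = 11)
  b <- simulate_condition("AD_low", delta = 0.1, cov = 0.05, seed = 11)
  expect_identical(a$target$activity, b$target$activity)
  expect_identical(a$reference$activity, b$reference$activity)
  tg <- simulate_condition("AD_low", delta = 0.2, cov = 0, scope = "global")
  to <- simulate_condition("AD_low", delta = 0.2, cov = 0,
                           scope = "target_only")
  expect_false(isTRUE(all.equal(tg$reference$activity,
                                to$reference$activity)))
})
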