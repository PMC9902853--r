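test_that("forward model reduces to the reference when R1=1, BPND=0", {
  p <- srtm_params(R1 = 1, k2 = 0.05, BPND = 0)
  out <- srtm_tac(p, canon_ref)
  expect_lt(max(rel_dev(out$activity, canon_ref$activity)), 0.001)
})

test_that("forward model converges under fine-grid refinement", {
  a <- srtm_tac(canon_params, canon_ref, fine_dt = 0.05)
  b <- srtm_tac(canon_params, canon_ref, fine_dt = 0.1)
  expect_lt(max(rel_dev(b$activity, a$activity)), 5e-4)
})

test_that("forward model rejects invalid inputs", {
  expect_error(srtm_tac(canon_params, canon_ref, fine_dt = 0),
               "'fine_dt'")
  small <- tac(frame_schedule(0, 1), 1)
  expect_error(srtm_tac(canon_params, small, fine_dt = 0.05),
               "at least 2 frames")
  bad <- srtm_params(0.9, 0.045, 0.5)
  bad$BPND <- -0.2
  expect_error(srtm_tac(bad, canon_ref), "invalid SRTM parameters")
})

test_that("basis grid endpoints and closed-form constant-reference limit", {
  b2 <- srtm_basis(canon_ref, k2a_range = c(0.01, 0.2), n_basis = 2)
  expect_equal(b2$k2a, c(0.01, 0.2))
  expect_error(srtm_basis(canon_ref, k2a_range = c(0.2, 0.01)),
               "min < max")

  # constant C_R = c: convolution tends to c/k2a at large t
  cst <- tac(canon_schedule, rep(10, n_frames(canon_schedule)))
  b <- srtm_basis(cst, n_basis = 8)
  last <- n_frames(cst)
  for (j in seq_along(b$k2a)) {
    lim <- 10 / b$k2a[j]
    if (b$k2a[j] * canon_schedule$start[last] > 8)  # settled frames only
      expect_lt(rel_dev(b$frames[last, j], lim), 0.01)
  }
})

test_that("basis curves decrease in k2a at fixed late time", {
  b <- srtm_basis(canon_ref, n_basis = 16)
  late <- which(canon_schedule$mid > 10)
  for (i in late)
    expect_true(all(diff(b$frames[i, ]) <= 1e-10))
})

test_that("noiseless round trip recovers R1, k2, BPND within 1%", {
  cases <- list(c(0.85, 0.0425, 0.6), c(1.1, 0.055, 0.05),
                c(0.7, 0.035, 1.2), c(0.95, 0.06, 0.25))
  for (cs in cases) {
    p <- srtm_params(cs[1], cs[2], cs[3])
    ct <- srtm_tac(p, canon_ref)
    fit <- fit_srtm(ct, canon_ref)
    expect_lt(rel_dev(fit$params$R1, p$R1), 0.01)
    expect_lt(rel_dev(fit$params$k2, p$k2), 0.01)
    expect_lt(abs(fit$params$BPND - p$BPND) / max(p$BPND, 0.05), 0.01)
    expect_lt(rel_dev(fit$params$DVR, p$DVR), 0.01)
  }
})

test_that("fitting the reference against itself gives R1=1, BPND=0", {
  fit <- fit_srtm(canon_ref, canon_ref)
  expect_lt(abs(fit$params$R1 - 1), 0.01)
  expect_lt(abs(fit$params$BPND), 0.01)
})

test_that("selected basis point minimizes WRSS over the whole grid", {
  ct <- srtm_tac(canon_params, canon_ref)
  fit <- fit_srtm(ct, canon_ref, refine = FALSE)
  expect_true(all(fit$wrss <= fit$wrss_grid + 1e-9))
  # with refinement the polished WRSS can only improve on the grid optimum
  fitr <- fit_srtm(ct, canon_ref)
  expect_lte(fitr$wrss, min(fit$wrss_grid) + 1e-9)
})

test_that("fitted DVR is invariant under joint (R1, k2) flow scaling", {
  base <- fit_srtm(srtm_tac(canon_params, canon_ref), canon_ref)
  for (f in c(0.7, 0.85, 1.15, 1.3)) {
    p <- srtm_params(canon_params$R1 * f, canon_params$k2 * f,
                     canon_params$BPND)
    fit <- fit_srtm(srtm_tac(p, canon_ref), canon_ref)
    expect_lt(rel_dev(fit$params$DVR, base$params$DVR), 0.01)
  }
})

test_that("Monte-Carlo fits are unbiased for DVR at realistic noise", {
  sim <- simulate_condition("AD_medium", delta = 0, cov = 0)
  set.seed(31)
  dvr <- replicate(100, {
    fit_srtm(add_noise(sim$target, 0.05), add_noise(sim$reference, 0.05))$params$DVR
  })
  expect_lt(rel_dev(mean(dvr), sim$truth$DVR), 0.02)
})

test_that("fit flags boundary solutions and rejects degenerate weights", {
  ct <- srtm_tac(canon_params, canon_ref)
  # grid excluding the true k2a (~0.027) forces a boundary selection
  fit <- fit_srtm(ct, canon_ref, k2a_range = c(0.1, 0.6), n_basis = 8)
  expect_true(fit$boundary)
  expect_error(fit_srtm(ct, canon_ref, weights = rep(0, n_frames(ct))),
               "all frame weights are zero")
  expect_error(fit_srtm(ct, canon_ref, weights = rep(1, 3)),
               "one per frame")
})

test_that("fit methods are mutually consistent", {
  ct <- srtm_tac(canon_params, canon_ref)
  fit <- fit_srtm(ct, canon_ref)
  expect_named(coef(fit), c("R1", "k2", "BPND", "DVR"))
  expect_equal(fitted(fit) + residuals(fit), ct$activity)
  expect_s3_class(predict(fit), "tac")
  expect_equal(predict(fit)$activity, fitted(fit))
  df <- as.data.frame(fit)
  expect_equal(df$DVR, fit$params$DVR)
  expect_equal(df$SUVr, suvr(ct, canon_ref, c(80, 100)))
  sims <- simulate(fit, nsim = 2, seed = 4, cov = 0.05)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "tac")
  # duration and ivar weightings run and stay close to truth (noiseless)
  for (w in list("duration", "ivar")) {
    fw <- fit_srtm(ct, canon_ref, weights = w)
    expect_lt(rel_dev(fw$params$DVR, canon_params$DVR), 0.01)
  }
})
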