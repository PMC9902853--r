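test_that("percentage change and annualization follow their definitions", {
  expect_identical(percentage_change(1, 1), 0)
  expect_identical(percentage_change(2, 1), -50)
  expect_equal(percentage_change(1.045, 1.075), 2.870813, tolerance = 1e-6)
  expect_error(percentage_change(0, 1), "positive")
  expect_identical(annualized_change(4.2, 2.1), 2)
  expect_identical(annualized_change(0, 3), 0)
  expect_equal(annualized_change(2.82, 2.1), 1.342857, tolerance = 1e-6)
  expect_error(annualized_change(1, 0), "positive")
})

test_that("paired t matches the closed form and its symmetries", {
  out <- paired_t(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(out$t_stat, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(out$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(out$df, 2)
  flip <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flip$t_stat, -out$t_stat)
  expect_equal(flip$p_value, out$p_value)
  same <- paired_t(1:5, 1:5)
  expect_identical(same$t_stat, 0)
  expect_identical(same$p_value, 1)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("paired t agrees with exhaustive sign-flip permutation", {
  set.seed(6)
  d <- rnorm(8, 0.6, 1)
  x <- rnorm(8, 5, 1)
  y <- x - d
  tobs <- paired_t(x, y)
  # enumerate all 2^8 sign assignments of the differences
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  tstat <- apply(signs, 1, function(s) {
    ds <- d * s
    mean(ds) / (sd(ds) / sqrt(length(ds)))
  })
  p_perm <- mean(abs(tstat) >= abs(tobs$t_stat) - 1e-12)
  expect_lt(abs(p_perm - tobs$p_value), 0.05)
})

test_that("pearson reproduces hand-computed correlations", {
  expect_equal(pearson(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson(rep(1, 4), 1:4), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman recovers identity and limit-of-agreement algebra", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba$bias, 0)
  expect_identical(c(ba$loa_low, ba$loa_high), c(0, 0))
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  ba <- bland_altman(a, b)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("pooled bias equals the mean of per-ROI biases at equal n", {
  set.seed(10)
  a <- matrix(rnorm(30), 10, 3)  # 10 subjects x 3 ROIs, method A
  b <- matrix(rnorm(30), 10, 3)
  pooled <- bland_altman(as.vector(a), as.vector(b))$bias
  per_roi <- vapply(1:3, function(j) bland_altman(a[, j], b[, j])$bias,
                    numeric(1))
  expect_equal(pooled, mean(per_roi))
})

test_that("sample size matches the noncentral-t oracle and power.t.test", {
  expect_identical(sample_size_paired(1, 1)$n_required, 10L)
  expect_identical(sample_size_paired(0.5, 1)$n_required, 34L)
  # brute-force scan oracle + recommended-package cross-check
  for (dz in c(0.3, 0.7, 1.4)) {
    n_scan <- 2
    while (power_paired(n_scan, dz) < 0.80) n_scan <- n_scan + 1
    res <- sample_size_paired(dz * 4, 4)
    expect_identical(res$n_required, as.integer(n_scan))
    n_ptt <- ceiling(stats::power.t.test(delta = dz, sd = 1, power = 0.8,
                                         type = "paired")$n)
    expect_identical(res$n_required, as.integer(n_ptt))
  }
  expect_error(sample_size_paired(0, 5), "zero expected change")
  # doubling the SD never decreases n
  expect_gte(sample_size_paired(2, 8)$n_required,
             sample_size_paired(2, 4)$n_required)
})

test_that("power and sample size are mutually consistent across effects", {
  for (dz in c(0.2, 0.5, 0.8, 1.2, 2)) {
    n <- sample_size_paired(dz * 10, 10)$n_required
    expect_gte(power_paired(n, dz), 0.80)
    if (n > 2) expect_lt(power_paired(n - 1, dz), 0.80)
  }
})

test_that("power behaves as alpha at null and approaches the normal limit", {
  expect_equal(power_paired(50, 0), 0.05, tolerance = 1e-10)
  pw <- vapply(c(5, 10, 20, 80), power_paired, numeric(1), dz = 0.5)
  expect_true(all(diff(pw) > 0))
  n <- 200; dz <- 0.2
  zcrit <- qnorm(0.975)
  approx_pw <- pnorm(-zcrit + dz * sqrt(n)) + pnorm(-zcrit - dz * sqrt(n))
  expect_lt(abs(power_paired(n, dz) - approx_pw), 0.005)
})

test_that("sample-size curves are monotone and consistent", {
  cur <- sample_size_curve(seq(0.5, 10, by = 0.5), sd_change = 5)
  expect_true(all(diff(cur$n_required) <= 0))
  expect_identical(cur$n_required[cur$expected_pct_change == 10],
                   sample_size_paired(10, 5)$n_required)
  lo <- sample_size_curve(c(1, 2, 4), sd_change = 2)$n_required
  hi <- sample_size_curve(c(1, 2, 4), sd_change = 6)$n_required
  expect_true(all(lo <= hi))
})
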