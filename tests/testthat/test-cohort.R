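test_that("cohort spec loads, validates and carries both groups", {
  spec <- cohort_spec()
  expect_s3_class(spec, "cohort_spec")
  expect_equal(nrow(spec), 6L)
  expect_setequal(unique(spec$group), c("SCD", "AD"))
  expect_equal(unique(spec$n_subjects[spec$group == "SCD"]), 38)
  expect_equal(unique(spec$n_subjects[spec$group == "AD"]), 24)
  expect_error(cohort_spec("no/such/file.csv"), "not found")
})

test_that("zero-SD specs collapse every subject onto the group means", {
  spec <- spec_subset(cohort_spec(), "AD", "BraakV_VI")
  spec[grep("_sd$", names(spec))] <- 0
  truth <- sample_cohort(spec, seed = 1)
  expect_equal(unique(truth$dvr_bl), spec$dvr_base_mean)
  expect_equal(unique(truth$r1_bl), spec$r1_base_mean)
  expect_equal(unique(truth$interval), spec$interval_mean)
  expect_equal(unique(round(truth$pct_dvr_true, 10)),
               spec$pct_change_dvr_mean)
})

test_that("cohort sampling is reproducible and respects truncation", {
  spec <- cohort_spec()
  a <- sample_cohort(spec, seed = 42)
  b <- sample_cohort(spec, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$dvr_bl >= 1))
  expect_true(all(a$dvr_fu >= 1))
  expect_true(all(a$r1_bl >= 0.3))
  expect_true(all(a$interval >= 0.5))
  expect_equal(nrow(a), (38 + 24) * 3)
})

test_that("sampled percentage changes converge to the spec means", {
  spec <- spec_subset(cohort_spec(), "SCD", "BraakIII_IV")
  set.seed(77)
  grand <- replicate(500, mean(sample_cohort(spec)$pct_dvr_true))
  expect_lt(abs(mean(grand) - spec$pct_change_dvr_mean), 0.5)
})

test_that("baseline DVRs are correlated across ROIs within subject", {
  spec <- spec_subset(cohort_spec(), "SCD")
  set.seed(8)
  rs <- replicate(40, {
    truth <- sample_cohort(spec, rho = 0.7)
    wide <- reshape(truth[c("subject", "roi", "dvr_bl")],
                    idvar = "subject", timevar = "roi",
                    direction = "wide")
    cor(wide[[2]], wide[[3]])
  })
  expect_gt(mean(rs), 0.4)
})

test_that("noiseless realization round-trips the truth at both visits", {
  spec <- spec_subset(cohort_spec(), "AD", "BraakV_VI")
  spec$n_subjects <- 3
  run <- run_cohort_pipeline(spec, cov = 0, seed = 5)
  expect_true(all(rel_dev(run$results$fit_dvr, run$results$true_dvr) < 0.01))
  expect_true(all(rel_dev(run$results$fit_r1, run$results$true_r1) < 0.01))
})

test_that("realize_subject_tacs produces reproducible per-visit TAC sets", {
  spec <- spec_subset(cohort_spec(), "SCD", c("BraakI_II", "BraakIII_IV"))
  truth <- sample_cohort(spec, seed = 3)
  one <- truth[truth$subject == truth$subject[1], ]
  a <- realize_subject_tacs(one, cov = 0.05, seed = 12)
  b <- realize_subject_tacs(one, cov = 0.05, seed = 12)
  expect_identical(a$baseline$reference$activity,
                   b$baseline$reference$activity)
  expect_setequal(names(a$baseline$targets),
                  c("BraakI_II", "BraakIII_IV"))
  # noiseless realization fits back to truth
  c0 <- realize_subject_tacs(one, cov = 0)
  fit <- fit_srtm(c0$baseline$targets$BraakI_II, c0$baseline$reference)
  expect_lt(rel_dev(fit$params$DVR,
                    one$dvr_bl[one$roi == "BraakI_II"]), 0.01)
})

test_that("the pipeline keeps truth immutable and its grid complete", {
  spec <- spec_subset(cohort_spec(), "AD", "BraakV_VI")
  spec$n_subjects <- 4
  seedled <- sample_cohort(spec, seed = 9)
  run <- run_cohort_pipeline(spec, cov = 0.05, seed = 9)
  expect_identical(run$truth, seedled)  # same seed, same truth, unmutated
  expect_equal(nrow(run$results), 4 * 2)
  expect_false(any(is.na(run$results$fit_dvr)))
  expect_setequal(unique(run$results$visit), c("baseline", "followup"))
  # stats cover every parameter
  expect_setequal(unique(run$stats$parameter), c("DVR", "SUVr", "R1"))
})

test_that("DVR and SUVr changes share subject-level truth when noiseless", {
  spec <- spec_subset(cohort_spec(), "SCD")
  spec$n_subjects <- 8
  run <- run_cohort_pipeline(spec, cov = 0, seed = 14)
  ch <- run$changes
  expect_gt(cor(ch$pct_dvr, ch$pct_suvr), 0.95)
  expect_gt(run$pooled$SCD$pearson$r, 0.95)
})

test_that("truth-passthrough measurement reproduces the truth exactly", {
  spec <- spec_subset(cohort_spec(), "SCD", "BraakIII_IV")
  run <- run_cohort_pipeline(spec, seed = 2, measure = "truth")
  expect_identical(run$changes$pct_dvr, run$changes$pct_dvr_true)
  expect_identical(run$changes$pct_r1, run$changes$pct_r1_true)
})
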