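# Shared fixtures, built once per test run.

canon_schedule <- default_schedule()
canon_ref <- reference_tac(canon_schedule)
canon_params <- srtm_params(R1 = 0.85, k2 = 0.0425, BPND = 0.6)

# Small utility: relative deviation
rel_dev <- function(a, b) abs(a / b - 1)

# A cohort spec restricted to selected group/ROI rows
spec_subset <- function(spec, group = NULL, roi = NULL) {
  keep <- rep(TRUE, nrow(spec))
  if (!is.null(group)) keep <- keep & spec$group %in% group
  if (!is.null(roi)) keep <- keep & spec$roi %in% roi
  out <- spec[keep, ]
  class(out) <- class(spec)
  out
}

# A null-change spec: zero mean and given sd for all %change fields.
# Baseline DVR is set well above the DVR >= 1 truncation bound so the
# follow-up guard never distorts the null change distribution (near the
# bound, rejection re-sampling shifts changes upward by design).
null_spec <- function(n = 38, sd_pct = 2.5) {
  spec <- cohort_spec()
  spec <- spec_subset(spec, "SCD", "BraakIII_IV")
  spec$n_subjects <- n
  spec$dvr_base_mean <- 1.3
  spec$dvr_base_sd <- 0.1
  spec$pct_change_dvr_mean <- 0
  spec$pct_change_dvr_sd <- sd_pct
  spec$pct_change_r1_mean <- 0
  spec$pct_change_r1_sd <- sd_pct
  spec
}
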