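# Synthetic two-timepoint cohort: sample subject-level truth from
# group x ROI distribution parameters, realize each subject-visit as noisy
# TACs, and run the full quantification pipeline end to end.

spec_cols <- c("group", "roi", "n_subjects",
               "dvr_base_mean", "dvr_base_sd",
               "pct_change_dvr_mean", "pct_change_dvr_sd",
               "suvr_base_mean", "suvr_base_sd",
               "pct_change_suvr_mean", "pct_change_suvr_sd",
               "r1_base_mean", "r1_base_sd",
               "pct_change_r1_mean", "pct_change_r1_sd",
               "interval_mean", "interval_sd")

#' Cohort distribution specification
#'
#' Reads a group x ROI table of truth-distribution parameters: baseline
#' DVR, SUVr and R1 means/SDs, percentage-change means/SDs, and scan
#' intervals.  The packaged default describes a two-group cohort
#' (subjective cognitive decline, n = 38; Alzheimer disease, n = 24) over
#' the three Braak composite ROIs, scanned twice about 2 years apart.
#'
#' @param file CSV path; default the packaged table.
#' @return `data.frame` of class `cohort_spec`.
#' @export
cohort_spec <- function(file = system.file("extdata", "cohort_groups.csv",
                                           package = "srtmsim")) {
  if (!nzchar(file) || !file.exists(file)) stop("spec file not found")
  spec <- utils::read.csv(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(spec_cols, names(spec))
  if (length(miss))
    stop("spec is missing columns: ", paste(miss, collapse = ", "))
  if (any(spec$n_subjects < 2)) stop("n_subjects must be >= 2")
  sds <- grep("_sd$", spec_cols, value = TRUE)
  if (any(as.matrix(spec[sds]) < 0)) stop("SDs must be non-negative")
  if (any(spec$interval_mean <= 0)) stop("interval_mean must be positive")
  if (any(spec$dvr_base_mean < 1 - 3 * spec$dvr_base_sd))
    stop("dvr_base_mean implausibly far below 1")
  class(spec) <- c("cohort_spec", "data.frame")
  spec
}

# Exact draws from a normal truncated below at `lower` (inverse-CDF on the
# upper tail; numerically safe however far the bound sits in the tail).
# Equivalent to re-sampling rejected draws, but never loops.
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (any(mean < lower)) stop("degenerate draw below truncation bound")
    return(rep(mean, n))
  }
  if (stats::pnorm(lower, mean, sd) > 0.99)
    stop("infeasible truncation: mean ", mean, " is far below bound ",
         lower)
  zmin <- (lower - mean) / sd
  tail <- stats::pnorm(zmin, lower.tail = FALSE)
  u <- stats::runif(n) * tail
  mean + sd * stats::qnorm(u, lower.tail = FALSE)
}

# Standard-normal draw truncated below at zmin (vectorized over zmin).
rtrunc_z <- function(zmin) {
  tail <- stats::pnorm(zmin, lower.tail = FALSE)
  stats::qnorm(stats::runif(length(zmin)) * tail, lower.tail = FALSE)
}

#' Sample subject-level truth for a two-timepoint cohort
#'
#' Per subject and ROI: baseline DVR from a normal truncated at 1 (BPND
#' cannot be negative in truth), subject-level DVR percentage change from
#' an untruncated normal (re-drawn only if the follow-up DVR would fall
#' below 1), baseline R1 truncated at 0.3, R1 percentage change likewise
#' guarded, and a per-subject scan interval truncated at 0.5 y.  Baseline
#' DVRs across ROIs of one subject share a subject-level random effect
#' with intra-subject correlation `rho` (Braak regions are biologically
#' coupled; pooled-ROI statistics are sensitive to this).  Truncated draws
#' are re-sampled, never clipped.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param rho Intra-subject correlation of baseline DVR across ROIs
#'   (default 0.7).
#' @return `data.frame` of class `cohort_truth`: one row per
#'   subject x ROI with true baseline/follow-up DVR and R1, the sampled
#'   percentage changes and the interval.
#' @export
sample_cohort <- function(spec, seed = NULL, rho = 0.7) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (g in unique(spec$group)) {
    rows <- spec[spec$group == g, ]
    n <- unique(rows$n_subjects)
    if (length(n) != 1L)
      stop("inconsistent n_subjects across ROIs within group ", g)
    ids <- sprintf("%s%02d", g, seq_len(n))
    interval <- rtrunc_norm(n, rows$interval_mean[1], rows$interval_sd[1],
                            0.5)
    z_subj <- stats::rnorm(n)
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      # correlated baseline DVR, rejection on the ROI-specific component
      if (r$dvr_base_sd == 0) dvr_bl <- rep(r$dvr_base_mean, n)
      else {
        if (stats::pnorm(1, r$dvr_base_mean, r$dvr_base_sd) > 0.99)
          stop("infeasible baseline DVR truncation for ", g, "/", r$roi)
        # ROI component drawn from its exact truncated conditional, so the
        # bound holds for any subject-level effect without looping
        zmin <- ((1 - r$dvr_base_mean) / r$dvr_base_sd -
                   sqrt(rho) * z_subj) / sqrt(1 - rho)
        dvr_bl <- r$dvr_base_mean + r$dvr_base_sd *
          (sqrt(rho) * z_subj + sqrt(1 - rho) * rtrunc_z(zmin))
        dvr_bl <- pmax(dvr_bl, 1)  # guard rounding at extreme bounds
      }
      # percentage changes truncated so follow-up stays above the bound
      if (r$pct_change_dvr_sd == 0) {
        pct_dvr <- rep(r$pct_change_dvr_mean, n)
        if (any(dvr_bl * (1 + pct_dvr / 100) < 1))
          stop("degenerate DVR change drives follow-up below 1")
      } else {
        pmin_dvr <- ((1 / dvr_bl - 1) * 100 - r$pct_change_dvr_mean) /
          r$pct_change_dvr_sd
        pct_dvr <- r$pct_change_dvr_mean +
          r$pct_change_dvr_sd * rtrunc_z(pmin_dvr)
      }
      r1_bl <- rtrunc_norm(n, r$r1_base_mean, r$r1_base_sd, 0.3)
      if (r$pct_change_r1_sd == 0) {
        pct_r1 <- rep(r$pct_change_r1_mean, n)
        if (any(r1_bl * (1 + pct_r1 / 100) < 0.3))
          stop("degenerate R1 change drives follow-up below 0.3")
      } else {
        pmin_r1 <- ((0.3 / r1_bl - 1) * 100 - r$pct_change_r1_mean) /
          r$pct_change_r1_sd
        pct_r1 <- r$pct_change_r1_mean +
          r$pct_change_r1_sd * rtrunc_z(pmin_r1)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, subject = ids, roi = r$roi, interval = interval,
        dvr_bl = dvr_bl, dvr_fu = dvr_bl * (1 + pct_dvr / 100),
        pct_dvr_true = pct_dvr,
        r1_bl = r1_bl, r1_fu = r1_bl * (1 + pct_r1 / 100),
        pct_r1_true = pct_r1,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$subject, res$roi), ]
  rownames(res) <- NULL
  class(res) <- c("cohort_truth", "data.frame")
  res
}

# Shared quantification engine: realize TACs for every subject-visit in a
# truth table and fit them.  The reference region is common to all ROIs of
# a subject-visit, so one noisy reference TAC (and one RPM basis) serves
# all three ROI fits of that visit.
cohort_engine <- function(truth, schedule, cov, window, k2_ref, plasma,
                          K1_ref, fine_dt, k2a_range, n_basis,
                          weights = "ivar") {
  t_fine <- fine_times(schedule, fine_dt)
  ref_fine <- reference_fine(t_fine, K1_ref, k2_ref, plasma, fine_dt)
  W <- frame_weight_matrix(schedule, t_fine)
  ref0 <- tac(schedule, frame_average(W, ref_fine))
  basis_grid <- exp(seq(log(k2a_range[1]), log(k2a_range[2]),
                        length.out = n_basis))
  subj <- unique(truth[c("group", "subject")])
  res <- vector("list", 2L * nrow(subj))
  i <- 0L
  for (s in seq_len(nrow(subj))) {
    rows <- truth[truth$group == subj$group[s] &
                    truth$subject == subj$subject[s], ]
    for (visit in c("baseline", "followup")) {
      refn <- add_noise(ref0, cov)
      basis <- basis_from_fine(refn, interp_fine(refn, t_fine),
                               basis_grid, fine_dt)
      dvr <- if (visit == "baseline") rows$dvr_bl else rows$dvr_fu
      r1 <- if (visit == "baseline") rows$r1_bl else rows$r1_fu
      nfit <- nrow(rows)
      fit_dvr <- fit_r1 <- suvr_v <- wrss <- numeric(nfit)
      boundary <- negbp <- logical(nfit)
      for (k in seq_len(nfit)) {
        pars <- srtm_params(R1 = r1[k], k2 = r1[k] * k2_ref,
                            BPND = dvr[k] - 1)
        conv <- exp_conv_framemean(ref_fine, pars$k2a, fine_dt,
                                   schedule$start, schedule$end)
        tgt <- tac(schedule,
                   pars$R1 * ref0$activity +
                     (pars$k2 - pars$R1 * pars$k2a) * conv)
        tgt <- add_noise(tgt, cov)
        fit <- fit_srtm(tgt, refn, basis = basis, weights = weights)
        fit_dvr[k] <- fit$params$DVR
        fit_r1[k] <- fit$params$R1
        suvr_v[k] <- suvr(tgt, refn, window)
        wrss[k] <- fit$wrss
        boundary[k] <- fit$boundary
        negbp[k] <- fit$negative_bp
      }
      i <- i + 1L
      res[[i]] <- data.frame(
        group = rows$group, subject = rows$subject, roi = rows$roi,
        visit = visit, interval = rows$interval,
        true_dvr = dvr, true_r1 = r1,
        fit_dvr = fit_dvr, fit_r1 = fit_r1, suvr = suvr_v,
        wrss = wrss, boundary = boundary, negative_bp = negbp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Realize one subject's TACs
#'
#' Bridges the truth table to the simulator: per ROI and visit, target
#' kinetics are `BPND = DVR - 1`, `R1` as drawn, `k2 = R1 k2'`; the
#' subject's flow trajectory is realized through the per-visit R1.  One
#' reference TAC per visit is shared across ROIs.
#'
#' @param truth Rows of a `cohort_truth` table for one subject.
#' @param schedule Frame schedule.
#' @param cov Noise level (fraction).
#' @param seed Optional seed.
#' @param k2_ref,plasma,K1_ref,fine_dt Simulator settings.
#' @return Nested list: per visit, a `reference` tac and a named list
#'   `targets` of ROI tacs, plus the truth rows.
#' @export
realize_subject_tacs <- function(truth, schedule = default_schedule(),
                                 cov = 0.05, seed = NULL, k2_ref = 0.05,
                                 plasma = plasma_params(), K1_ref = 0.35,
                                 fine_dt = 0.05) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) >= 1L)
  if (length(unique(truth$subject)) != 1L)
    stop("'truth' must describe a single subject")
  with_seed(seed, {
    t_fine <- fine_times(schedule, fine_dt)
    ref_fine <- reference_fine(t_fine, K1_ref, k2_ref, plasma, fine_dt)
    W <- frame_weight_matrix(schedule, t_fine)
    ref0 <- tac(schedule, frame_average(W, ref_fine))
    out <- list()
    for (visit in c("baseline", "followup")) {
      dvr <- if (visit == "baseline") truth$dvr_bl else truth$dvr_fu
      r1 <- if (visit == "baseline") truth$r1_bl else truth$r1_fu
      targets <- list()
      for (k in seq_len(nrow(truth))) {
        pars <- srtm_params(R1 = r1[k], k2 = r1[k] * k2_ref,
                            BPND = dvr[k] - 1)
        conv <- exp_conv_framemean(ref_fine, pars$k2a, fine_dt,
                                   schedule$start, schedule$end)
        tgt <- tac(schedule,
                   pars$R1 * ref0$activity +
                     (pars$k2 - pars$R1 * pars$k2a) * conv)
        targets[[truth$roi[k]]] <- add_noise(tgt, cov)
      }
      out[[visit]] <- list(reference = add_noise(ref0, cov),
                           targets = targets)
    }
    out$truth <- truth
    out
  })
}

#' Run the full cohort quantification pipeline
#'
#' Samples a cohort truth table, realizes every subject-visit as noisy
#' TACs, fits SRTM by RPM and computes SUVr, then aggregates the
#' longitudinal statistics: per-subject percentage changes, group x ROI
#' means/SDs and paired tests, and pooled-ROI Pearson and Bland-Altman
#' agreement between DVR and SUVr changes.  Truth records are carried
#' unchanged alongside the estimates for audit.
#'
#' @param spec A [cohort_spec()].
#' @param schedule Frame schedule.
#' @param cov TAC noise level (fraction; default 0.05).
#' @param seed Optional integer seed for the whole pipeline.
#' @param measure `"simulate"` (realize and fit TACs) or `"truth"`
#'   (pass true values through as measurements; fast path for calibrating
#'   the statistical layer).
#' @param window SUVr window (minutes).
#' @param rho Intra-subject baseline-DVR correlation, see
#'   [sample_cohort()].
#' @param k2_ref,plasma,K1_ref,fine_dt Simulator settings.
#' @param k2a_range,n_basis RPM basis grid.
#' @param weights Per-frame fit weights (default `"ivar"`: with noise
#'   SD proportional to `1/sqrt(duration)`, duration weights are the
#'   inverse-variance choice; pass `NULL` for uniform).
#' @return Object of class `cohort_run`: `truth`, `results` (per
#'   subject x ROI x visit), `changes` (per subject x ROI), `stats`
#'   (group x ROI x parameter summary), `pooled` (per-group Pearson +
#'   Bland-Altman over pooled ROIs).
#' @export
run_cohort_pipeline <- function(spec, schedule = default_schedule(),
                                cov = 0.05, seed = NULL,
                                measure = c("simulate", "truth"),
                                window = c(80, 100), rho = 0.7,
                                k2_ref = 0.05, plasma = plasma_params(),
                                K1_ref = 0.35, fine_dt = 0.05,
                                k2a_range = c(0.006, 0.6), n_basis = 64,
                                weights = "ivar") {
  measure <- match.arg(measure)
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_cohort(spec, rho = rho)
  if (measure == "simulate") {
    results <- cohort_engine(truth, schedule, cov, window, k2_ref, plasma,
                             K1_ref, fine_dt, k2a_range, n_basis, weights)
  } else {
    long <- rbind(
      data.frame(truth[c("group", "subject", "roi", "interval")],
                 visit = "baseline", true_dvr = truth$dvr_bl,
                 true_r1 = truth$r1_bl),
      data.frame(truth[c("group", "subject", "roi", "interval")],
                 visit = "followup", true_dvr = truth$dvr_fu,
                 true_r1 = truth$r1_fu))
    results <- data.frame(long[c("group", "subject", "roi", "visit",
                                 "interval", "true_dvr", "true_r1")],
                          fit_dvr = long$true_dvr, fit_r1 = long$true_r1,
                          suvr = long$true_dvr, wrss = 0,
                          boundary = FALSE, negative_bp = FALSE)
  }
  changes <- cohort_changes(results)
  structure(list(truth = truth, results = results, changes = changes,
                 stats = cohort_stats(results),
                 pooled = pooled_agreement(changes),
                 spec = spec, cov = cov, measure = measure,
                 window = window),
            class = "cohort_run")
}

# Per-subject x ROI percentage changes of the fitted parameters.
cohort_changes <- function(results) {
  bl <- results[results$visit == "baseline", ]
  fu <- results[results$visit == "followup", ]
  key <- c("group", "subject", "roi")
  m <- merge(bl, fu, by = key, suffixes = c("_bl", "_fu"))
  data.frame(m[key], interval = m$interval_bl,
             pct_dvr = percentage_change(m$fit_dvr_bl, m$fit_dvr_fu),
             pct_suvr = percentage_change(m$suvr_bl, m$suvr_fu),
             pct_r1 = percentage_change(m$fit_r1_bl, m$fit_r1_fu),
             pct_dvr_true = percentage_change(m$true_dvr_bl,
                                              m$true_dvr_fu),
             pct_r1_true = percentage_change(m$true_r1_bl, m$true_r1_fu),
             stringsAsFactors = FALSE)
}

#' Group-level longitudinal statistics from pipeline results
#'
#' Per group x ROI x parameter (DVR, SUVr, R1): mean and SD of the
#' per-subject percentage changes, annualized mean change, and the paired
#' t test between baseline and follow-up measurements.
#'
#' @param results The `results` table of a `cohort_run` (or a compatible
#'   data.frame).
#' @return `data.frame` with one row per group x ROI x parameter.
#' @export
cohort_stats <- function(results) {
  if (inherits(results, "cohort_run")) results <- results$results
  changes <- cohort_changes(results)
  out <- list()
  combos <- unique(results[c("group", "roi")])
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]
    roi <- combos$roi[i]
    bl <- results[results$group == g & results$roi == roi &
                    results$visit == "baseline", ]
    fu <- results[results$group == g & results$roi == roi &
                    results$visit == "followup", ]
    fu <- fu[match(bl$subject, fu$subject), ]
    ch <- changes[changes$group == g & changes$roi == roi, ]
    for (par in c("DVR", "SUVr", "R1")) {
      col <- switch(par, DVR = "fit_dvr", SUVr = "suvr", R1 = "fit_r1")
      pct <- switch(par, DVR = ch$pct_dvr, SUVr = ch$pct_suvr,
                    R1 = ch$pct_r1)
      tt <- paired_t(fu[[col]], bl[[col]])
      out[[length(out) + 1L]] <- data.frame(
        group = g, roi = roi, parameter = par, n = nrow(bl),
        mean_bl = mean(bl[[col]]), mean_fu = mean(fu[[col]]),
        mean_pct_change = mean(pct), sd_pct_change = stats::sd(pct),
        mean_annual_pct = mean(annualized_change(pct, ch$interval)),
        t_stat = tt$t_stat, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Pooled-ROI agreement between percentage change in DVR and in SUVr,
# per group: Pearson r and Bland-Altman (DVR minus SUVr, i.e.
# quantitative minus semiquantitative).
pooled_agreement <- function(changes) {
  out <- list()
  for (g in unique(changes$group)) {
    ch <- changes[changes$group == g, ]
    out[[g]] <- list(pearson = pearson(ch$pct_suvr, ch$pct_dvr),
                     bland_altman = bland_altman(ch$pct_dvr, ch$pct_suvr))
  }
  out
}

#' @export
print.cohort_run <- function(x, digits = 3, ...) {
  cat("Two-timepoint cohort pipeline (", x$measure, " measurement, cov = ",
      x$cov, ")\n", sep = "")
  cat(length(unique(x$truth$subject)), "subjects,",
      length(unique(x$truth$roi)), "ROIs\n\n")
  st <- x$stats
  st[5:9] <- lapply(st[5:9], round, digits)
  print.data.frame(st[c("group", "roi", "parameter", "n",
                        "mean_pct_change", "sd_pct_change", "p_value")],
                   digits = digits, row.names = FALSE)
  for (g in names(x$pooled)) {
    p <- x$pooled[[g]]
    cat("\n", g, ": pooled-ROI r(%change SUVr, %change DVR) = ",
        format(p$pearson$r, digits = digits),
        "; Bland-Altman bias = ",
        format(p$bland_altman$bias, digits = digits),
        " +/- ", format(p$bland_altman$sd_diff, digits = digits),
        "\n", sep = "")
  }
  invisible(x)
}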