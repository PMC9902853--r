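# Delimited-text I/O: TAC files (one target + one reference region on a
# shared frame schedule) and the run configuration.

#' Write a target/reference TAC pair to CSV
#'
#' Columns: `frame_start_min`, `frame_duration_min`, `target_kBq_per_mL`,
#' `reference_kBq_per_mL`.  Values are written with full precision so a
#' write/read round trip is bitwise exact.  Lines starting with `#` are
#' comments.
#'
#' @param target,ref `tac` objects on the same schedule.
#' @param path Output file path.
#' @param comment Optional character vector of comment lines (written
#'   prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_tac_file <- function(target, ref, path, comment = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target, ref))
    stop("target and reference must share one frame schedule")
  s <- target$schedule
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "frame_start_min,frame_duration_min,target_kBq_per_mL,reference_kBq_per_mL",
    sprintf("%.17g,%.17g,%.17g,%.17g", s$start, s$duration,
            target$activity, ref$activity))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target/reference TAC pair from CSV
#'
#' Expects the schema written by [write_tac_file()]; `#` comment lines are
#' ignored, the header row is mandatory.  Schema violations raise errors
#' naming the offending column or frame.
#'
#' @param path Input file path.
#' @return List with elements `target` and `ref` (`tac` objects).
#' @export
read_tac_file <- function(path) {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse TAC file ", path, ": ",
                             conditionMessage(e)))
  need <- c("frame_start_min", "frame_duration_min", "target_kBq_per_mL",
            "reference_kBq_per_mL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TAC file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", col, "', data row ",
           if (is.na(bad)) "?" else bad)
    }
    if (any(!is.finite(v)))
      stop("non-finite value in column '", col, "', data row ",
           which(!is.finite(v))[1L])
  }
  sched <- frame_schedule(df$frame_start_min, df$frame_duration_min)
  list(target = tac(sched, df$target_kBq_per_mL),
       ref = tac(sched, df$reference_kBq_per_mL))
}

#' Read and write a run configuration
#'
#' A run configuration is a plain YAML document with a versioned `schema`
#' field holding simulation settings (seed, schedule, basis grid, binding
#' conditions, flow grid, noise levels, SUVr windows, cohort spec path,
#' statistics options).  `read_run_config()` validates the schema field
#' and the seed; configurations round-trip load -> save -> load
#' identically.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema)) stop("config lacks a 'schema' version field")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config must carry an integer 'seed' for stochastic stages")
  for (f in c("cohort_spec", "tac_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config references missing file: ", cfg[[f]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config` (or plain named list with `schema` and
#'   `seed`).
#' @return `write_run_config()`: `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(is.list(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}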