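#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start time and duration (both in minutes) of
#' every frame of a dynamic scan.  Frames must be ordered, non-overlapping
#' and of positive duration; gaps between frames are allowed.
#'
#' @param start Numeric vector of frame start times (minutes post injection),
#'   strictly increasing.
#' @param duration Numeric vector of frame durations (minutes), same length
#'   as `start`, all positive.
#'
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration`, `mid` (frame midpoints) and `end`.
#' @examples
#' sch <- frame_schedule(start = c(0, 1, 2), duration = c(1, 1, 2))
#' n_frames(sch)
#' @export
frame_schedule <- function(start, duration) {
  if (!is.numeric(start) || !is.numeric(duration))
    stop("'start' and 'duration' must be numeric")
  if (length(start) != length(duration))
    stop("'start' and 'duration' must have the same length")
  if (length(start) < 1L)
    stop("a frame schedule needs at least one frame")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame times must be finite")
  if (any(duration <= 0))
    stop("frame durations must be positive (frame ",
         which(duration <= 0)[1L], ")")
  if (is.unsorted(start, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  end <- start + duration
  gap <- start[-1L] - end[-length(end)]
  if (any(gap < -1e-9))
    stop("frames ", which(gap < -1e-9)[1L], " and ",
         which(gap < -1e-9)[1L] + 1L, " overlap")
  structure(list(start = as.numeric(start),
                 duration = as.numeric(duration),
                 mid = as.numeric(start + duration / 2),
                 end = as.numeric(end)),
            class = "frame_schedule")
}

#' Number of frames in a schedule or time-activity curve
#' @param x A `frame_schedule` or `tac` object.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "tac")) x <- x$schedule
  length(x$start)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("Frame schedule:", n_frames(x), "frames,",
      format(min(x$start), digits = 4), "to",
      format(max(x$end), digits = 4), "min\n")
  invisible(x)
}

#' @export
as.data.frame.frame_schedule <- function(x, ...) {
  data.frame(frame_start_min = x$start, frame_duration_min = x$duration)
}

#' Default dynamic frame schedule
#'
#' Continuous 0--130 min sampling: 6 x 10 s, 2 x 30 s, 3 x 60 s, 2 x 150 s,
#' then 5-min frames out to 130 min (37 frames in total).
#'
#' @return A `frame_schedule`.
#' @export
default_schedule <- function() {
  dur <- c(rep(10 / 60, 6), rep(30 / 60, 2), rep(1, 3), rep(2.5, 2),
           rep(5, 24))
  frame_schedule(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' Time-activity curve
#'
#' Framewise activity concentration (nominally kBq/mL) of a region on a
#' frame schedule.  Activity may be negative after measurement noise has
#' been added; use [has_negative()] to flag such curves.
#'
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector of activity concentrations, one per frame.
#' @return An object of class `tac` with elements `schedule` and `activity`.
#' @export
tac <- function(schedule, activity) {
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  if (!is.numeric(activity))
    stop("'activity' must be numeric")
  if (length(activity) != n_frames(schedule))
    stop("'activity' must have one value per frame (",
         n_frames(schedule), " frames, ", length(activity), " values)")
  if (any(!is.finite(activity)))
    stop("activity values must be finite")
  structure(list(schedule = schedule, activity = as.numeric(activity)),
            class = "tac")
}

#' @rdname tac
#' @param x A `tac` object.
#' @return `has_negative()`: `TRUE` if any frame is negative.
#' @export
has_negative <- function(x) {
  stopifnot(inherits(x, "tac"))
  any(x$activity < 0)
}

#' @export
print.tac <- function(x, ...) {
  cat("Time-activity curve:", n_frames(x), "frames,",
      format(min(x$schedule$start), digits = 4), "to",
      format(max(x$schedule$end), digits = 4), "min; peak",
      format(max(x$activity), digits = 4), "at",
      format(x$schedule$mid[which.max(x$activity)], digits = 4), "min\n")
  if (has_negative(x)) cat("  (contains negative frames)\n")
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  cbind(as.data.frame(x$schedule), activity_kBq_per_mL = x$activity)
}

#' @export
plot.tac <- function(x, ..., xlab = "Time (min)",
                     ylab = "Activity (kBq/mL)", type = "b", pch = 16) {
  graphics::plot(x$schedule$mid, x$activity, xlab = xlab, ylab = ylab,
                 type = type, pch = pch, ...)
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-9) {
  sa <- if (inherits(a, "tac")) a$schedule else a
  sb <- if (inherits(b, "tac")) b$schedule else b
  n_frames(sa) == n_frames(sb) &&
    max(abs(sa$start - sb$start)) <= tol &&
    max(abs(sa$duration - sb$duration)) <= tol
}

#' Standardized uptake value ratio over a static window
#'
#' Duration-weighted mean of the target activity over the frames
#' intersecting `window`, divided by the same quantity for the reference
#' region.  Frames partially overlapping the window contribute in
#' proportion to their overlap, so the value does not depend on where frame
#' boundaries fall within the window.
#'
#' @param target,ref `tac` objects on the same frame schedule.
#' @param window Numeric length-2 vector `c(start, end)` in minutes; default
#'   the conventional 80--100 min late window.
#' @return The SUVr (unitless scalar).
#' @examples
#' sch <- default_schedule()
#' ct <- tac(sch, rep(2, n_frames(sch)))
#' cr <- tac(sch, rep(1, n_frames(sch)))
#' suvr(ct, cr)  # 2
#' @export
suvr <- function(target, ref, window = c(80, 100)) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target, ref))
    stop("target and reference must share one frame schedule")
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1])
    stop("'window' must be c(start, end) with end > start")
  s <- target$schedule
  ov <- pmax(0, pmin(s$end, window[2]) - pmax(s$start, window[1]))
  if (abs(sum(ov) - diff(window)) > 1e-6)
    stop("SUVr window [", window[1], ", ", window[2],
         "] min is not fully covered by the frame schedule")
  denom <- sum(ov * ref$activity)
  if (denom == 0) stop("reference activity integrates to zero over window")
  sum(ov * target$activity) / denom
}

#' Distribution volume ratio from binding potential
#'
#' DVR = BPND + 1.  Small negative fitted BPND values (a normal consequence
#' of noise at low binding) are passed through with a warning rather than
#' clamped, so that group means remain unbiased.
#'
#' @param bp Numeric vector of (fitted) BPND values.
#' @return `bp + 1`.
#' @export
bp_to_dvr <- function(bp) {
  if (!is.numeric(bp)) stop("'bp' must be numeric")
  if (any(bp < 0))
    warning("negative BPND passed through to DVR (noise-induced)")
  bp + 1
}
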