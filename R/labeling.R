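# Accelerometer-assisted labeling: assign one of the 25 codes to every MAV
# instance by combining the timed protocol script with detected ACC events.

#' Detect accelerometer activity events
#'
#' A grid step is evidence of motion when its summed-difference statistic
#' strictly exceeds twice the run-wide median. Consecutive above-threshold
#' steps separated by at most `gap` seconds are merged into one event. An
#' event's `start` is the left edge of its first above-threshold difference
#' interval and its `end` the right edge of its last, so the event brackets
#' the underlying motion to within one grid step on each side.
#'
#' @param summary An [summarize_acc()] object.
#' @param gap Maximum within-event silence, seconds.
#' @return Data frame with columns `start`, `end`, `peak` (max statistic),
#'   zero rows when nothing exceeds the threshold.
#' @export
detect_acc_events <- function(summary, gap = 0.15) {
  stopifnot(inherits(summary, "acc_summary"))
  thr <- 2 * summary$median
  above <- which(summary$stat > thr)
  if (length(above) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak = numeric(0)))
  times <- summary$time[above]
  new_event <- c(TRUE, diff(times) > gap)
  ev <- cumsum(new_event)
  starts <- tapply(times, ev, min) - summary$dt
  ends <- tapply(times, ev, max)
  peaks <- tapply(summary$stat[above], ev, max)
  data.frame(start = as.numeric(starts), end = as.numeric(ends),
             peak = as.numeric(peaks))
}

#' Movement onset times from accelerometer evidence
#'
#' @param summary An [summarize_acc()] object.
#' @param gap Event-merging gap, seconds (see [detect_acc_events()]).
#' @return Numeric vector of event start times (possibly empty).
#' @export
detect_movement_onsets <- function(summary, gap = 0.15) {
  detect_acc_events(summary, gap)$start
}

#' Match each ACC summary instant to its closest MAV instant
#'
#' The two streams live on different grids (about 21.1/s vs 20/s); each ACC
#' instant is mapped to the EMG/MAV instant with the smallest absolute time
#' difference. Exact ties go to the earlier instant.
#'
#' @param summary An [summarize_acc()] object.
#' @param mav A [compute_mav()] stream.
#' @return Integer vector: for each ACC instant, the index of the matched MAV
#'   instance. The attribute `"max_diff"` holds the largest time mismatch in
#'   seconds.
#' @export
align_acc_to_emg <- function(summary, mav) {
  stopifnot(inherits(summary, "acc_summary"), inherits(mav, "mav_stream"))
  if (length(summary$time) == 0L || length(mav$time) == 0L)
    stop("both streams must be nonempty", call. = FALSE)
  tt <- mav$time
  k_lo <- pmin(pmax(findInterval(summary$time, tt), 1L), length(tt))
  k_hi <- pmin(k_lo + 1L, length(tt))
  d_lo <- abs(summary$time - tt[k_lo])
  d_hi <- abs(summary$time - tt[k_hi])
  idx <- ifelse(d_lo <= d_hi, k_lo, k_hi)  # tie -> earlier
  structure(as.integer(idx),
            max_diff = max(pmin(d_lo, d_hi)))
}

# Internal: greedy nearest-event assignment. For each target time (in order),
# pick the unused event whose `key` time is nearest, within +/- tol; NA if none.
match_events <- function(targets, key_times, tol = 0.5) {
  used <- rep(FALSE, length(key_times))
  out <- rep(NA_integer_, length(targets))
  for (i in seq_along(targets)) {
    d <- abs(key_times - targets[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && is.finite(d[j]) && d[j] <= tol) {
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}

#' Label a MAV stream from the protocol script and ACC evidence
#'
#' Grips are assumed to start at their scheduled repetition times: the actual
#' start is taken as the end of the ACC event cluster nearest the scheduled
#' time (the end of the reach toward the object), never adjusted by more than
#' 500 ms; the grip label is sustained for up to 3 s or until the first
#' detected movement onset. Movements start at detected ACC onsets matched to
#' their scheduled times (again within 500 ms, falling back to the schedule
#' with a warning count when no event is near) and last until the next onset
#' or their scheduled duration. Everything else is neutral/rest.
#'
#' @param mav A [compute_mav()] stream for the run.
#' @param summary The run's [summarize_acc()] object.
#' @param schedule The run's [make_schedule()] script.
#' @param gap Event-merging gap, seconds.
#' @param max_adjust Largest permitted deviation from a scheduled onset, s.
#' @param grip_hold Maximum sustained grip duration, s.
#' @return The input stream with a `label` element (character, one of the 25
#'   codes per instance) and attribute `"fallbacks"` counting scheduled
#'   onsets that had no ACC event within `max_adjust`.
#' @export
label_run <- function(mav, summary, schedule, gap = 0.15,
                      max_adjust = 0.5, grip_hold = 3) {
  stopifnot(inherits(mav, "mav_stream"), inherits(summary, "acc_summary"),
            inherits(schedule, "grip_schedule"))
  events <- detect_acc_events(summary, gap)
  sched_grip <- schedule_grips(schedule)
  sched_mov <- schedule_movements(schedule)
  fallbacks <- 0L

  # grip starts: nearest event *end* to each scheduled grip time
  grip_idx <- match_events(sched_grip$onset, events$end, max_adjust)
  grip_on <- ifelse(is.na(grip_idx), sched_grip$onset,
                    events$end[grip_idx])
  fallbacks <- fallbacks + sum(is.na(grip_idx))
  grip_on <- pmin(pmax(grip_on, sched_grip$onset - max_adjust),
                  sched_grip$onset + max_adjust)

  # movement starts: nearest unused event *start* to each scheduled onset
  used_start <- events$start
  if (length(grip_idx) > 0L && any(!is.na(grip_idx)))
    used_start[stats::na.omit(grip_idx)] <- Inf  # grip reach events consumed
  mov_idx <- match_events(sched_mov$onset, used_start, max_adjust)
  mov_on <- ifelse(is.na(mov_idx), sched_mov$onset, events$start[mov_idx])
  fallbacks <- fallbacks + sum(is.na(mov_idx))

  labels <- rep("NR", length(mav$time))
  assign_interval <- function(code, from, to) {
    if (to <= from) return(invisible(NULL))
    sel <- mav$time >= from & mav$time < to
    labels[sel] <<- code
    invisible(NULL)
  }

  for (r in seq_len(schedule$rep_count)) {
    g <- which(sched_grip$rep == r)
    movs <- which(sched_mov$rep == r)
    first_mov <- if (length(movs) > 0L) min(mov_on[movs]) else Inf
    if (length(g) == 1L)
      assign_interval(sched_grip$code[g], grip_on[g],
                      min(grip_on[g] + grip_hold, first_mov))
    if (length(movs) > 0L) {
      ord <- movs[order(sched_mov$onset[movs])]
      for (i in seq_along(ord)) {
        m <- ord[i]
        dur <- sched_mov$offset[m] - sched_mov$onset[m]
        nxt <- if (i < length(ord)) mov_on[ord[i + 1L]] else Inf
        assign_interval(sched_mov$code[m], mov_on[m],
                        min(mov_on[m] + dur, nxt))
      }
    }
  }

  mav$label <- labels
  attr(mav, "fallbacks") <- fallbacks
  mav
}

#' Rebalance neutral/rest by keeping only run-start instances
#'
#' Rest dominates the raw label track (roughly 40 % of each run). Only the
#' NR instances from the run-start window — when the subject is certainly at
#' rest — are retained: by default seconds `[1, 4)`, i.e. 60 instances per
#' run at 20 instances/s, 480 over an eight-run session. Non-NR instances
#' are never touched.
#'
#' @param labeled A labeled `mav_stream` (from [label_run()]).
#' @param window Two-element numeric: the retained NR time window `[a, b)`.
#' @return The stream with the out-of-window NR instances dropped (its
#'   `time`, `values` and `label` filtered consistently).
#' @export
subsample_nr <- function(labeled, window = c(1, 4)) {
  stopifnot(inherits(labeled, "mav_stream"), !is.null(labeled$label))
  keep <- labeled$label != "NR" |
    (labeled$time >= window[1] & labeled$time < window[2])
  labeled$time <- labeled$time[keep]
  labeled$values <- labeled$values[keep, , drop = FALSE]
  labeled$label <- labeled$label[keep]
  labeled
}

#' Cut a labeled stream into activity segments
#'
#' Maximal runs of identical labels become segments; each is truncated to its
#' first `max_len` instances (40 by default, i.e. 4 s, covering every
#' movement and the significant part of every grip). The repetition index is
#' derived from the segment's start time relative to the protocol's
#' repetition grid; rest segments get `NA`.
#'
#' @param labeled A labeled `mav_stream`.
#' @param max_len Maximum segment length in instances.
#' @param run_id Optional identifier stored on each segment.
#' @return List of segments: each a list with `code`, `rep`, `idx` (instance
#'   indices into the stream, at most `max_len`), `full_length` (before
#'   truncation), `start` (seconds) and `run_id`.
#' @export
segment_activities <- function(labeled, max_len = 40, run_id = NULL) {
  stopifnot(inherits(labeled, "mav_stream"), !is.null(labeled$label))
  r <- rle(labeled$label)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(r$values), function(i) {
    idx <- starts[i]:ends[i]
    t0 <- labeled$time[starts[i]]
    rep_i <- if (r$values[i] == "NR") NA_integer_ else
      max(1L, min(12L, as.integer(floor((t0 - 5) / 10)) + 1L))
    list(code = r$values[i], rep = rep_i,
         idx = utils::head(idx, max_len),
         full_length = length(idx), start = t0, run_id = run_id)
  })
}
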