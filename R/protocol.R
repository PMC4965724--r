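#' Build the timed collection script for one action group
#'
#' Each 120 s run holds 12 ten-second repetitions starting at seconds
#' 5, 15, ..., 115; the run opens with 5 s of neutral/rest. Within a
#' repetition the base grip is engaged for 2-3 s, followed by the group's one
#' or two movements at the 3 s and 5 s marks, then neutral/rest until the next
#' repetition. Two slots are hybrid: the third grip second (grip or NR,
#' written `"HG/NR"` etc.) and, for four groups, the second after the first
#' movement (movement sustained or NR).
#'
#' @param group An action group name (see [action_groups()]) or its 1-based
#'   index in protocol order.
#' @return An object of class `grip_schedule`: a list with `group_no`,
#'   `group`, `rep_count` (12), `rep_duration` (10), `run_duration` (120),
#'   `rep_starts` (5, 15, ..., 115) and `codes`, a character vector of the ten
#'   per-second activity codes of one repetition (repetition seconds 5..14;
#'   hybrid slots rendered as `"CODE/NR"`).
#' @export
#' @examples
#' make_schedule("hammer")$codes
#' make_schedule(8)$codes  # ball group: no third action, second 10 is NR
make_schedule <- function(group) {
  groups <- action_groups()
  if (is.numeric(group)) {
    if (!(group %in% seq_along(groups))) {
      stop("unknown group index ", group, "; valid groups are 1..8: ",
           paste(groups, collapse = ", "), call. = FALSE)
    }
    group <- groups[group]
  }
  if (!is.character(group) || length(group) != 1L || !(group %in% groups)) {
    stop("unknown group '", paste(group, collapse = ","),
         "'; valid groups are: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }

  rows <- list(
    "hammer"      = c("HG", "HG", "HG/NR", "HR", "HGR", "HL"),
    "tip pinch"   = c("TPG", "TPG", "TPG/NR", "TPR", "TPR/NR", "TPL"),
    "3-jaw chuck" = c("3JCG", "3JCG", "3JCG/NR", "3JCR", "3JCR/NR", "3JCL"),
    "key"         = c("KG", "KG", "KG/NR", "KTS", "NR", "KTP"),
    "scissors"    = c("SCG", "SCG", "SCG/NR", "SCO", "SCO/NR", "SCC"),
    "door knob"   = c("DKG", "DKG", "DKG/NR", "DKS", "NR", "DKP"),
    "jar lid"     = c("JLG", "JLG", "JLG/NR", "JLP", "JLP/NR", "JLS"),
    "ball"        = c("BG", "BG", "BG/NR", "BSQ", "BSQ", "NR")
  )
  codes <- c(rows[[group]], rep("NR", 4L))
  names(codes) <- paste0("s", 5:14)

  structure(
    list(group_no = match(group, groups), group = group,
         rep_count = 12L, rep_duration = 10, run_duration = 120,
         rep_starts = seq(5, 115, by = 10), codes = codes),
    class = "grip_schedule"
  )
}

#' @export
print.grip_schedule <- function(x, ...) {
  cat("<grip_schedule> group ", x$group_no, " (", x$group, "): ",
      x$rep_count, " x ", x$rep_duration, " s repetitions in ",
      x$run_duration, " s\n", sep = "")
  cat("  repetition seconds 5-14: ", paste(x$codes, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Internal: split a possibly hybrid slot code into its two alternatives.
split_hybrid <- function(code) strsplit(code, "/", fixed = TRUE)[[1L]]

is_hybrid <- function(code) grepl("/", code, fixed = TRUE)

# Internal: one activity code per whole second of the run (length 120),
# plus the repetition index each second belongs to (NA outside repetitions).
schedule_seconds <- function(schedule, hybrid = c("activity", "nr")) {
  hybrid <- match.arg(hybrid)
  pick <- function(code) {
    if (!is_hybrid(code)) return(code)
    if (hybrid == "activity") split_hybrid(code)[1L] else "NR"
  }
  per_sec <- vapply(unname(schedule$codes), pick, character(1))
  n_sec <- as.integer(schedule$run_duration)
  codes <- rep("NR", n_sec)
  reps <- rep(NA_integer_, n_sec)
  for (r in seq_len(schedule$rep_count)) {
    t0 <- as.integer(schedule$rep_starts[r])
    for (off in 0:(length(per_sec) - 1L)) {
      s <- t0 + off
      if (s < n_sec) {
        codes[s + 1L] <- per_sec[off + 1L]
        reps[s + 1L] <- r
      }
    }
  }
  list(codes = codes, reps = reps)
}

#' Scheduled activity intervals of one run
#'
#' Expands a schedule into the ground-truth tiling of `[0, 120]` s: maximal
#' same-code intervals, with hybrid slots resolved either to their first-named
#' activity (default, matching how grips and sustained movements were scripted)
#' or to neutral/rest.
#'
#' @param schedule A [make_schedule()] object.
#' @param hybrid `"activity"` (default) or `"nr"`: how hybrid slots resolve.
#' @return Data frame with columns `code`, `onset`, `offset` (seconds) and
#'   `rep` (repetition index, `NA` for rest intervals); intervals are
#'   non-overlapping and tile `[0, run_duration]`.
#' @export
schedule_truth <- function(schedule, hybrid = c("activity", "nr")) {
  stopifnot(inherits(schedule, "grip_schedule"))
  sec <- schedule_seconds(schedule, hybrid)
  r <- rle(sec$codes)
  offset_end <- cumsum(r$lengths)
  onset <- c(0, offset_end[-length(offset_end)])
  out <- data.frame(code = r$values, onset = onset, offset = offset_end,
                    stringsAsFactors = FALSE)
  out$rep <- ifelse(out$code == "NR", NA_integer_, sec$reps[onset + 1L])
  rownames(out) <- NULL
  out
}

# Internal: scheduled movement intervals (non-grip, non-NR activity) of one
# run, hybrid sustains folded into the preceding activity's duration.
schedule_movements <- function(schedule) {
  truth <- schedule_truth(schedule, hybrid = "activity")
  grips <- activity_table()$code[activity_table()$is_grip]
  truth[!(truth$code %in% c("NR", grips)), , drop = FALSE]
}

# Internal: scheduled grip onset intervals (one per repetition).
schedule_grips <- function(schedule) {
  truth <- schedule_truth(schedule, hybrid = "activity")
  grips <- activity_table()$code[activity_table()$is_grip]
  truth[truth$code %in% grips, , drop = FALSE]
}
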