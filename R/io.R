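# CSV signal dialect: per-sensor time/value exports mimicking acquisition
# software output, labeled-instance tables, and model/config serialization.
# All files use dot decimal separators regardless of locale.

# Internal: per-sensor file names for a run directory.
sensor_files <- function() {
  st <- sensor_table()
  emg <- sprintf("sensor%02d_%s_emg.csv", st$sensor[1:8], st$abbrev[1:8])
  acc <- as.vector(t(outer(9:10, c("x", "y", "z"), function(s, ax)
    sprintf("sensor%02d_%s_acc_%s.csv", s, st$abbrev[s], ax))))
  list(emg = emg, acc = acc)
}

#' Write a run as per-sensor CSV files
#'
#' One file per channel with header `elapsed_time_s,value` (timestamps in
#' seconds, 6 decimal places), plus `labels_truth.csv` (`code`, `onset_s`,
#' `offset_s`) when the run carries ground truth, and `run_meta.json`.
#'
#' @param run An `emg_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "emg_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sensor_files()
  t_emg <- sprintf("%.6f", seq_len(nrow(run$emg)) / run$emg_rate)
  for (j in 1:8) {
    utils::write.csv(
      data.frame(elapsed_time_s = t_emg, value = run$emg[, j]),
      file.path(dir, files$emg[j]), row.names = FALSE, quote = FALSE)
  }
  t_acc <- sprintf("%.6f", seq_len(nrow(run$acc)) / run$acc_rate)
  for (j in 1:6) {
    utils::write.csv(
      data.frame(elapsed_time_s = t_acc, value = run$acc[, j]),
      file.path(dir, files$acc[j]), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$truth)) {
    utils::write.csv(
      data.frame(code = run$truth$code,
                 onset_s = sprintf("%.6f", run$truth$onset),
                 offset_s = sprintf("%.6f", run$truth$offset)),
      file.path(dir, "labels_truth.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(group = run$group, group_no = run$group_no,
         emg_rate = run$emg_rate, acc_rate = run$acc_rate,
         duration = run$duration, seed = run$seed),
    file.path(dir, "run_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

# Internal: read one time/value CSV, with structural checks.
read_channel_csv <- function(path, what) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  if (nrow(df) == 0L)
    stop("empty signal file: ", basename(path), call. = FALSE)
  if (!identical(names(df), c("elapsed_time_s", "value")))
    stop("bad header in ", basename(path),
         " (expected elapsed_time_s,value)", call. = FALSE)
  if (any(diff(df$elapsed_time_s) <= 0))
    stop("non-monotone timestamps in ", basename(path), call. = FALSE)
  if (any(!is.finite(df$value)))
    stop("non-finite values in ", basename(path), call. = FALSE)
  df
}

#' Read a run directory back into an `emg_run`
#'
#' Expects the per-sensor CSV layout written by [write_run()] (the montage
#' of [sensor_table()]: 8 EMG channels, two 3-axis hand accelerometers).
#' All EMG series must share rate and length, likewise the ACC series.
#'
#' @param dir Run directory.
#' @return An `emg_run` (with `truth` when `labels_truth.csv` is present).
#' @export
read_run <- function(dir) {
  files <- sensor_files()
  st <- sensor_table()
  missing_emg <- !file.exists(file.path(dir, files$emg))
  missing_acc <- !file.exists(file.path(dir, files$acc))
  if (any(missing_emg) || any(missing_acc)) {
    miss <- c(files$emg[missing_emg], files$acc[missing_acc])
    locs <- c(st$location[1:8][missing_emg],
              rep(st$location[9:10], each = 3)[missing_acc])
    stop("missing sensor file(s): ",
         paste0(miss, " (", locs, ")", collapse = ", "),
         "; expected the ten-sensor montage: ",
         paste(st$location, collapse = "; "), call. = FALSE)
  }
  emg_cols <- lapply(file.path(dir, files$emg), read_channel_csv)
  acc_cols <- lapply(file.path(dir, files$acc), read_channel_csv)
  lens <- vapply(emg_cols, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("EMG series lengths differ: ", paste(lens, collapse = ", "),
         call. = FALSE)
  lens_acc <- vapply(acc_cols, nrow, integer(1))
  if (length(unique(lens_acc)) != 1L)
    stop("ACC series lengths differ: ", paste(lens_acc, collapse = ", "),
         call. = FALSE)
  rate_of <- function(df) 1 / stats::median(diff(df$elapsed_time_s))
  emg <- do.call(cbind, lapply(emg_cols, `[[`, "value"))
  colnames(emg) <- st$abbrev[1:8]
  acc <- do.call(cbind, lapply(acc_cols, `[[`, "value"))
  colnames(acc) <- paste0(rep(c("thumb", "little"), each = 3), "_",
                          rep(c("x", "y", "z"), 2))

  meta_path <- file.path(dir, "run_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list()
  truth_path <- file.path(dir, "labels_truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    tdf <- utils::read.csv(truth_path)
    check_codes(tdf$code)
    truth <- data.frame(code = as.character(tdf$code),
                        onset = as.numeric(tdf$onset_s),
                        offset = as.numeric(tdf$offset_s),
                        stringsAsFactors = FALSE)
  }
  structure(
    list(emg = emg, acc = acc,
         emg_rate = round(rate_of(emg_cols[[1L]]), 3),
         acc_rate = round(rate_of(acc_cols[[1L]]), 3),
         duration = nrow(emg) / round(rate_of(emg_cols[[1L]]), 3),
         group = meta$group, group_no = meta$group_no,
         truth = truth, seed = meta$seed),
    class = "emg_run"
  )
}

#' Write / read labeled MAV instances
#'
#' Lossless CSV round trip of a labeled feature stream: timestamp, the 8 MAV
#' values (full precision) and the class code. Codes outside the 25-class
#' catalogue are rejected on both paths.
#'
#' @param stream A labeled `mav_stream`.
#' @param path CSV file path.
#' @return `path` invisibly (write); a labeled `mav_stream` (read).
#' @export
write_labeled_instances <- function(stream, path) {
  stopifnot(inherits(stream, "mav_stream"))
  if (!is.null(stream$label)) check_codes(stream$label)
  df <- data.frame(time_s = stream$time, stream$values)
  names(df) <- c("time_s", paste0("ch", 1:ncol(stream$values)))
  if (!is.null(stream$label)) df$label <- stream$label
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labeled_instances
#' @export
read_labeled_instances <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty instance file: ", path, call. = FALSE)
  if (!is.null(df$label)) check_codes(df$label)
  ch <- grep("^ch", names(df))
  out <- list(time = as.numeric(df$time_s),
              values = as.matrix(df[, ch, drop = FALSE]),
              step = stats::median(diff(as.numeric(df$time_s))))
  if (!is.null(df$label)) out$label <- as.character(df$label)
  structure(out, class = "mav_stream")
}
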